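.default_clades <- c("Deuterostomia", "Lophotrochozoa", "Ecdysozoa",
                     "non-Bilateria", "Fungi", "Cnidaria", "Ctenophora",
                     "Chelicerata", "Crustacea", "Myriapoda", "Insecta",
                     "Gnathostomata", "Bilateria", "Metazoa", "Arthropoda",
                     "Vertebrata")

#' Per-orthogroup clade composition
#'
#' Counts distinct species (not sequences) per clade for each
#' orthogroup. The pseudo-clade `"non-Bilateria"` counts metazoan
#' species outside Bilateria.
#'
#' @param groups Orthogroup tibble (`og_id`, `member_id`, `taxid`).
#' @param taxonomy A `taxonomy_tbl`.
#' @param clades Clade labels to count.
#' @return Tibble with `og_id`, `total_species` and one column per clade.
#' @export
orthogroup_composition <- function(groups, taxonomy, clades = .default_clades) {
  bad <- setdiff(unique(groups$taxid), taxonomy$taxid)
  if (length(bad) > 0) abort(paste0("unresolvable taxon: ", bad[1]))
  sp <- distinct(groups, .data$og_id, .data$taxid)
  member_sets <- list()
  for (cl in clades) {
    member_sets[[cl]] <- if (cl == "non-Bilateria") {
      setdiff(clade_taxids(taxonomy, "Metazoa"), clade_taxids(taxonomy, "Bilateria"))
    } else {
      clade_taxids(taxonomy, cl)
    }
  }
  out <- sp |>
    group_by(.data$og_id) |>
    summarise(total_species = n(), .groups = "drop")
  for (cl in clades) {
    cnt <- sp |>
      group_by(.data$og_id) |>
      summarise(n = sum(.data$taxid %in% member_sets[[cl]]), .groups = "drop")
    out[[cl]] <- cnt$n[match(out$og_id, cnt$og_id)]
  }
  out
}

cc <- function(counts, clade) {
  if (!clade %in% names(counts)) abort(paste0("composition lacks clade: ", clade))
  counts[[clade]]
}

#' Apply a built-in lineage-specificity rule to clade compositions
#'
#' Implements the published clade-composition rules. Minima scale with
#' `scale` (ceiling), since the printed minima presuppose the full
#' 273-species roster; maxima scale with flooring. "At least k or 0"
#' clauses mean the clade may be entirely absent but must meet the
#' minimum when present. Every rule additionally requires clade
#' exclusivity (no species outside the focal clade), which the rules
#' imply by construction.
#'
#' Rules: `bilaterian` (Deuterostomia >= 7, Lophotrochozoa >= 4 or 0,
#' Ecdysozoa >= 4 or 0, no non-bilaterians), `arthropod` (Chelicerata
#' >= 2, Crustacea >= 0, Myriapoda >= 1, Insecta >= 5, no
#' non-arthropods), `vertebrate` (>= 40 gnathostome species, no
#' non-vertebrates), `opisthokont` (Fungi >= 20, Metazoa >= 40,
#' Bilateria >= 30), `metazoan` (as opisthokont but no fungi allowed),
#' `eumetazoan` (Bilateria >= 30, Cnidaria >= 3, Ctenophora <= 2).
#'
#' @param counts Composition tibble from [orthogroup_composition()].
#' @param rule Rule name.
#' @param scale Scaling factor applied to the printed minima/maxima.
#' @return Logical vector, one element per row of `counts`.
#' @export
apply_lineage_filter <- function(counts, rule, scale = 1) {
  mn <- function(k) ceiling(k * scale)
  mx <- function(k) floor(k * scale)
  ge_or_zero <- function(x, k) x >= mn(k) | x == 0
  switch(rule,
    bilaterian = cc(counts, "Deuterostomia") >= mn(7) &
      ge_or_zero(cc(counts, "Lophotrochozoa"), 4) &
      ge_or_zero(cc(counts, "Ecdysozoa"), 4) &
      counts$total_species - cc(counts, "Bilateria") == 0,
    arthropod = cc(counts, "Chelicerata") >= mn(2) &
      cc(counts, "Crustacea") >= 0 &
      cc(counts, "Myriapoda") >= mn(1) &
      cc(counts, "Insecta") >= mn(5) &
      counts$total_species - cc(counts, "Arthropoda") == 0,
    vertebrate = cc(counts, "Gnathostomata") >= mn(40) &
      counts$total_species - cc(counts, "Vertebrata") == 0,
    opisthokont = cc(counts, "Fungi") >= mn(20) &
      cc(counts, "Metazoa") >= mn(40) &
      cc(counts, "Bilateria") >= mn(30),
    metazoan = cc(counts, "Fungi") == 0 &
      cc(counts, "Metazoa") >= mn(40) &
      cc(counts, "Bilateria") >= mn(30),
    eumetazoan = cc(counts, "Bilateria") >= mn(30) &
      cc(counts, "Cnidaria") >= mn(3) &
      cc(counts, "Ctenophora") <= mx(2),
    abort(paste0("unknown rule: ", rule))
  )
}

#' Assign each orthogroup its last common ancestor
#'
#' @param groups Orthogroup tibble.
#' @param taxonomy A `taxonomy_tbl`.
#' @return Tibble with `og_id`, `ancestor_taxid`, `ancestor_name`.
#' @export
assign_ancestors <- function(groups, taxonomy) {
  groups |>
    group_by(.data$og_id) |>
    summarise(ancestor_taxid = last_common_ancestor(unique(.data$taxid), taxonomy),
              .groups = "drop") |>
    mutate(ancestor_name = taxonomy$name[match(.data$ancestor_taxid, taxonomy$taxid)])
}

#' Extract lineage-specific orthogroups
#'
#' An orthogroup is called specific for the focal clade when its last
#' common ancestor is that clade's node and the composition rule holds.
#'
#' @param groups Orthogroup tibble.
#' @param taxonomy A `taxonomy_tbl`.
#' @param focal Focal clade label (e.g. "Bilateria").
#' @param rule Rule name for [apply_lineage_filter()].
#' @param scale Rule scaling factor.
#' @return Tibble of selected og_ids with ancestor and rule columns.
#' @export
lineage_specific_orthogroups <- function(groups, taxonomy, focal = "Bilateria",
                                         rule = "bilaterian", scale = 1) {
  counts <- orthogroup_composition(groups, taxonomy)
  anc <- assign_ancestors(groups, taxonomy)
  pass <- apply_lineage_filter(counts, rule, scale)
  tibble(og_id = counts$og_id, rule_pass = pass) |>
    left_join(anc, by = "og_id") |>
    filter(.data$rule_pass, .data$ancestor_name == focal) |>
    select("og_id", "ancestor_taxid", "ancestor_name")
}

#' Lineage-specific orthogroup counts under increasing coverage
#'
#' For a focal node, counts the orthogroups entirely contained in the
#' node's clade that have at least s member species, for every minimum
#' s up to the node's species total. The 50% mark is the count at
#' s = ceiling(total / 2).
#'
#' @param groups Orthogroup tibble.
#' @param node Clade label.
#' @param taxonomy A `taxonomy_tbl`.
#' @param node_species_total Number of species belonging to the node in
#'   the dataset; defaults to the number of node species seen in
#'   `groups`.
#' @return A tibble (`min_species`, `n_groups`) of class
#'   `coverage_sweep`, with attributes `mark50` (the 50% count) and
#'   `node`.
#' @export
coverage_sweep <- function(groups, node, taxonomy, node_species_total = NULL) {
  inside <- clade_taxids(taxonomy, node)
  node_species_total <- node_species_total %||%
    length(intersect(unique(groups$taxid), inside))
  per_og <- groups |>
    group_by(.data$og_id) |>
    summarise(specific = all(.data$taxid %in% inside),
              n_sp = n_distinct(.data$taxid), .groups = "drop") |>
    filter(.data$specific)
  s <- seq_len(max(node_species_total, 1))
  out <- tibble(min_species = s,
                n_groups = map_int(s, ~ sum(per_og$n_sp >= .x)))
  mark <- out$n_groups[ceiling(node_species_total / 2)]
  structure(out, mark50 = mark, node = node,
            node_species_total = node_species_total,
            class = c("coverage_sweep", class(out)))
}
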