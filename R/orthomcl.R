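# Canonical unordered pair key (lexicographic).
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Build the normalized ortholog/inparalog/coortholog graph
#'
#' Classifies sequence pairs from an all-vs-all similarity table into
#' the three classic edge classes and computes normalized weights:
#'
#' * ortholog: cross-species reciprocal best hits, per species pair
#'   (ties broken by smaller E, larger score, lexicographic id);
#' * inparalog: same-species mutual hits where each direction's E-value
#'   is at most that member's best cross-species E-value (genes more
#'   similar to each other than either is to any foreign gene);
#' * coortholog: cross-species pairs connecting a gene (or one of its
#'   inparalogs) to an ortholog partner's inparalogs, provided the pair
#'   itself shares a hit.
#'
#' Raw edge weight is the average of -log10(E) over the two directions
#' (E floored at 1e-180). Ortholog and coortholog weights are divided
#' by the mean ortholog-edge weight of their species pair; inparalog
#' weights by the mean weight of inparalog edges whose nodes have a
#' cross-species ortholog (falling back to all inparalog edges when
#' none qualify).
#'
#' @param hits Hit tibble from [all_vs_all_similarity()]; taxa are
#'   parsed from the `<taxid>|<source>|<uid>` identifiers.
#' @return Tibble with `a`, `b` (a < b), `edge_class`, `weight`.
#' @export
build_orthomcl_graph <- function(hits) {
  if (nrow(hits) == 0) {
    return(tibble(a = character(), b = character(),
                  edge_class = character(), weight = numeric()))
  }
  hits <- hits |>
    filter(.data$query != .data$subject) |>
    mutate(qtax = taxid_of(.data$query), stax = taxid_of(.data$subject))

  # best hit per query into each foreign species
  best <- hits |>
    filter(.data$qtax != .data$stax) |>
    arrange(.data$query, .data$stax, .data$e_value, desc(.data$score), .data$subject) |>
    distinct(.data$query, .data$stax, .keep_all = TRUE)

  # ortholog pairs: reciprocal best
  fwd <- best |> transmute(a = .data$query, b = .data$subject)
  orth <- fwd |>
    inner_join(fwd, by = c(a = "b", b = "a")) |>
    filter(.data$a < .data$b) |>
    distinct(.data$a, .data$b)

  # best cross-species E per gene (Inf when none)
  cross_best <- hits |>
    filter(.data$qtax != .data$stax) |>
    group_by(.data$query) |>
    summarise(best_e = min(.data$e_value, Inf), .groups = "drop")
  best_e_of <- stats::setNames(cross_best$best_e, cross_best$query)
  get_best_e <- function(g) {
    v <- unname(best_e_of[g]); v[is.na(v)] <- Inf; v
  }

  # inparalog pairs: same-species mutual hits, each direction at least
  # as good as that member's best cross-species hit
  same <- hits |> filter(.data$qtax == .data$stax)
  mutual <- same |>
    inner_join(same |> transmute(query2 = .data$subject,
                                 subject2 = .data$query,
                                 e2 = .data$e_value),
               by = c(query = "query2", subject = "subject2")) |>
    filter(.data$query < .data$subject)
  inpar <- mutual |>
    filter(.data$e_value <= get_best_e(.data$query),
           .data$e2 <= get_best_e(.data$subject)) |>
    transmute(a = .data$query, b = .data$subject) |>
    distinct()

  # coorthologs: x in {a} U inpar(a), y in {b} U inpar(b) for each
  # ortholog (a,b); cross-species, not already orthologs, sharing a hit
  hit_keys <- unique(pair_key(hits$query, hits$subject))
  inpar_map <- bind_rows(inpar |> transmute(g = .data$a, p = .data$b),
                         inpar |> transmute(g = .data$b, p = .data$a))
  if (nrow(orth) > 0) {
    side_a <- orth |> inner_join(inpar_map, by = c(a = "g"),
                                 relationship = "many-to-many") |>
      transmute(x = .data$p, y = .data$b)
    side_b <- orth |> inner_join(inpar_map, by = c(b = "g"),
                                 relationship = "many-to-many") |>
      transmute(x = .data$a, y = .data$p)
    both <- orth |>
      inner_join(inpar_map |> rename(pa = "p"), by = c(a = "g"),
                 relationship = "many-to-many") |>
      inner_join(inpar_map, by = c(b = "g"),
                 relationship = "many-to-many") |>
      transmute(x = .data$pa, y = .data$p)
    co <- bind_rows(side_a, side_b, both) |>
      filter(taxid_of(.data$x) != taxid_of(.data$y)) |>
      transmute(a = pmin(.data$x, .data$y), b = pmax(.data$x, .data$y)) |>
      distinct() |>
      anti_join(orth, by = c("a", "b")) |>
      filter(pair_key(.data$a, .data$b) %in% hit_keys)
  } else {
    co <- tibble(a = character(), b = character())
  }

  edges <- bind_rows(orth |> mutate(edge_class = "ortholog"),
                     inpar |> mutate(edge_class = "inparalog"),
                     co |> mutate(edge_class = "coortholog"))
  if (nrow(edges) == 0) {
    return(tibble(a = character(), b = character(),
                  edge_class = character(), weight = numeric()))
  }

  # raw weight: mean -log10(E) over available directions
  wtab <- hits |>
    mutate(key = pair_key(.data$query, .data$subject),
           nlog = -log10(pmax(.data$e_value, 1e-180))) |>
    group_by(.data$key) |>
    summarise(w_raw = mean(.data$nlog), .groups = "drop")
  edges <- edges |>
    mutate(key = pair_key(.data$a, .data$b)) |>
    left_join(wtab, by = "key") |>
    mutate(atax = taxid_of(.data$a), btax = taxid_of(.data$b),
           sp_pair = paste(pmin(.data$atax, .data$btax),
                           pmax(.data$atax, .data$btax)))

  # normalization
  orth_means <- edges |>
    filter(.data$edge_class == "ortholog") |>
    group_by(.data$sp_pair) |>
    summarise(m = mean(.data$w_raw), .groups = "drop")
  has_orth <- unique(c(edges$a[edges$edge_class == "ortholog"],
                       edges$b[edges$edge_class == "ortholog"]))
  inpar_edges <- edges |> filter(.data$edge_class == "inparalog")
  anchored <- inpar_edges |>
    filter(.data$a %in% has_orth | .data$b %in% has_orth)
  inpar_mean <- if (nrow(anchored) > 0) mean(anchored$w_raw)
                else if (nrow(inpar_edges) > 0) mean(inpar_edges$w_raw)
                else NA_real_
  edges |>
    left_join(orth_means, by = "sp_pair") |>
    mutate(weight = case_when(
      edge_class == "inparalog" ~ .data$w_raw / inpar_mean,
      TRUE ~ .data$w_raw / .data$m)) |>
    select("a", "b", "edge_class", "weight") |>
    arrange(.data$a, .data$b)
}
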