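#' Parameters for the gene-family birth/loss simulator
#'
#' @param n_families Number of families to simulate.
#' @param birth_node_weights Named probability vector over labelled
#'   internal clades; where each family is born. The default places 10%
#'   of births at the bilaterian ancestor and spreads the rest over
#'   older and younger nodes, emulating continuous gene birth along the
#'   backbone.
#' @param loss_prob Per-branch probability that a gene copy is lost.
#' @param dup_prob Per-branch probability that a gene copy duplicates.
#' @param root_length Length of the ancestral sequence (amino acids,
#'   >= 50).
#' @param subst_rate Per-site per-branch substitution probability; a
#'   substituted site is replaced by a uniformly chosen different amino
#'   acid (no indels, so simulated family members stay positionally
#'   comparable and oracles remain exact).
#' @param seed Master seed; all randomness flows from it through named
#'   substreams.
#' @return A `family_params` list.
#' @export
family_params <- function(n_families = 200,
                          birth_node_weights = c(Opisthokonta = 0.25,
                                                 Metazoa = 0.25,
                                                 Eumetazoa = 0.10,
                                                 Bilateria = 0.10,
                                                 Deuterostomia = 0.10,
                                                 Protostomia = 0.10,
                                                 Ecdysozoa = 0.05,
                                                 Lophotrochozoa = 0.05),
                          loss_prob = 0.05, dup_prob = 0.01,
                          root_length = 150, subst_rate = 0.05, seed = 1) {
  stopifnot(n_families >= 1, root_length >= 50,
            loss_prob >= 0, loss_prob <= 1, dup_prob >= 0, dup_prob <= 1,
            subst_rate >= 0)
  if (abs(sum(birth_node_weights) - 1) > 1e-9) abort("birth_node_weights must sum to 1")
  structure(list(n_families = as.integer(n_families),
                 birth_node_weights = birth_node_weights,
                 loss_prob = loss_prob, dup_prob = dup_prob,
                 root_length = as.integer(root_length),
                 subst_rate = subst_rate, seed = as.integer(seed)),
            class = "family_params")
}

mutate_seq <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit) > 0) {
    shift <- sample.int(19L, length(hit), replace = TRUE)
    chars[hit] <- AA20[(match(chars[hit], AA20) - 1L + shift) %% 20L + 1L]
  }
  chars
}

#' Simulate gene families on a species tree
#'
#' Each family is born at a labelled internal node drawn from
#' `birth_node_weights`, with an i.i.d. random root sequence. The gene
#' evolves down the tree: on every branch each copy is lost with
#' `loss_prob`, duplicated with `dup_prob` (duplicates get a `-d<k>`
#' suffix and evolve independently thereafter), and each site
#' substitutes with probability `min(1, subst_rate)`. Sequences reaching
#' a leaf are emitted as that species' proteins under the
#' `<taxid>|ncbi|<uid>` naming scheme.
#'
#' @param tree A [build_species_fixture()] result.
#' @param params A [family_params()] list.
#' @return List with `proteins` (tibble: id, taxid, residues) and
#'   `truth` (tibble: family_id, birth_node, birth_taxid, member_id,
#'   taxid) recording ground-truth family membership.
#' @export
simulate_gene_families <- function(tree, params) {
  stopifnot(inherits(tree, "species_tree"), inherits(params, "family_params"))
  w <- params$birth_node_weights
  if (!all(names(w) %in% names(tree$clade_labels))) {
    abort("birth_node_weights names must be labelled clades of the tree")
  }
  with_substream(params$seed, "families", {
    births <- sample(names(w), params$n_families, replace = TRUE, prob = w)
    prot <- list()
    truth <- list()
    for (f in seq_len(params$n_families)) {
      fam_id <- sprintf("F%04d", f)
      birth_taxid <- tree$clade_labels[[births[f]]]
      root <- sample(AA20, params$root_length, replace = TRUE)
      dup_counter <- 0L
      emitted <- list()
      # depth-first evolution; a "copy" is (label suffix, residue chars)
      evolve <- function(node, copies) {
        if (tree$nodes$is_leaf[match(node, tree$nodes$taxid)]) {
          for (cp in copies) {
            uid <- paste0(fam_id, cp$suffix)
            emitted[[length(emitted) + 1L]] <<-
              list(taxid = node, uid = uid,
                   residues = paste(cp$chars, collapse = ""))
          }
          return(invisible(NULL))
        }
        for (child in tree_children(tree, node)) {
          surv <- list()
          for (cp in copies) {
            if (stats::runif(1) < params$loss_prob) next
            chars <- mutate_seq(cp$chars, min(1, params$subst_rate))
            surv[[length(surv) + 1L]] <- list(suffix = cp$suffix, chars = chars)
            if (stats::runif(1) < params$dup_prob) {
              dup_counter <<- dup_counter + 1L
              surv[[length(surv) + 1L]] <-
                list(suffix = paste0(cp$suffix, "-d", dup_counter),
                     chars = chars)
            }
          }
          if (length(surv) > 0) evolve(child, surv)
        }
      }
      evolve(birth_taxid, list(list(suffix = "", chars = root)))
      if (length(emitted) == 0) next
      em <- tibble(taxid = map_int(emitted, ~ as.integer(.x$taxid)),
                   uid = map_chr(emitted, "uid"),
                   residues = map_chr(emitted, "residues"))
      em$id <- make_seq_id(em$taxid, "ncbi", em$uid)
      prot[[fam_id]] <- em[, c("id", "taxid", "residues")]
      truth[[fam_id]] <- tibble(family_id = fam_id,
                                birth_node = births[f],
                                birth_taxid = birth_taxid,
                                member_id = em$id,
                                taxid = em$taxid)
    }
    list(proteins = bind_rows(prot), truth = bind_rows(truth))
  })
}

#' Write ground truth as TSV
#'
#' Columns: family_id, birth_node, member_id.
#'
#' @param truth Truth tibble from [simulate_gene_families()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth[, c("family_id", "birth_node", "member_id")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
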