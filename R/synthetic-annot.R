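#' Generate domain-annotation and PPI fixtures with known age classes
#'
#' Family representatives (lexicographically first member id per family)
#' receive synthetic domain annotations in the standard domain-scanner
#' column layout, and a protein-protein interaction edge list is drawn
#' over the representatives with configurable within-age-class
#' enrichment. Age class is `B` for families born at or below the
#' bilaterian ancestor and `M` otherwise.
#'
#' @param truth Truth tibble from [simulate_gene_families()].
#' @param spec List of parameters: `tf_fraction` (fraction of families
#'   annotated with a transcription-factor domain, default 0.2),
#'   `tf_domain` (default "Homeobox"), `polyzf_families` (named integer
#'   vector family_id -> zf-C2H2 copy number), `other_fraction`
#'   (fraction of remaining families given a non-TF domain, default
#'   0.6), `fail_fraction` (fraction of annotation rows emitted above
#'   the E-value cutoff, default 0.1), `n_edges` (PPI edges to draw,
#'   default 300), `within_class_odds` (relative sampling odds of
#'   same-class pairs, 1 = random mixing, default 1), `score_min`,
#'   `score_max` (combined-score range, defaults 150 and 999).
#' @param seed Integer seed.
#' @return List with `annotations` (domain-scanner-layout tibble),
#'   `ppi_edges` (tibble: protein1, protein2, combined_score),
#'   `node_classes` (tibble: protein, class).
#' @export
generate_annotation_and_ppi_fixtures <- function(truth, spec = list(), seed = 1) {
  if (nrow(truth) == 0) abort("ground truth is empty")
  spec <- utils::modifyList(
    list(tf_fraction = 0.2, tf_domain = "Homeobox", polyzf_families = NULL,
         other_fraction = 0.6, fail_fraction = 0.1, n_edges = 300,
         within_class_odds = 1, score_min = 150, score_max = 999), spec)
  fams <- truth |>
    group_by(.data$family_id, .data$birth_node) |>
    summarise(rep_id = min(.data$member_id), .groups = "drop") |>
    mutate(class = ifelse(.data$birth_node %in%
                            c("Bilateria", "Deuterostomia", "Protostomia",
                              "Ecdysozoa", "Lophotrochozoa", "Arthropoda",
                              "Vertebrata"), "B", "M"))
  with_substream(seed, "annotation", {
    n <- nrow(fams)
    n_tf <- round(spec$tf_fraction * n)
    tf_idx <- if (n_tf > 0) sample.int(n, n_tf) else integer(0)
    rest <- setdiff(seq_len(n), tf_idx)
    n_other <- round(spec$other_fraction * length(rest))
    other_idx <- if (n_other > 0) sample(rest, n_other) else integer(0)
    ann_row <- function(pid, dom, acc, e) {
      tibble(seq_id = pid, aln_start = 1L, aln_end = 60L,
             env_start = 1L, env_end = 62L, hmm_acc = acc, hmm_name = dom,
             type = "Domain", hmm_start = 1L, hmm_end = 60L, hmm_length = 60L,
             bit_score = 55.0, e_value = e)
    }
    rows <- list()
    for (i in tf_idx) {
      rows[[length(rows) + 1L]] <- ann_row(fams$rep_id[i], spec$tf_domain, "PF00046.28", 1e-10)
    }
    for (i in other_idx) {
      dom <- sample(c("Pkinase", "WD40", "Ank_2", "EGF"), 1)
      rows[[length(rows) + 1L]] <- ann_row(fams$rep_id[i], dom, "PF99999.1", 1e-8)
    }
    if (!is.null(spec$polyzf_families)) {
      for (fid in names(spec$polyzf_families)) {
        pid <- fams$rep_id[fams$family_id == fid]
        k <- spec$polyzf_families[[fid]]
        for (j in seq_len(k)) {
          r <- ann_row(pid, "zf-C2H2", "PF00096.26", 1e-9)
          r$aln_start <- 1L + 25L * (j - 1L); r$aln_end <- r$aln_start + 22L
          rows[[length(rows) + 1L]] <- r
        }
      }
    }
    ann <- bind_rows(rows)
    if (nrow(ann) > 0 && spec$fail_fraction > 0) {
      n_fail <- round(spec$fail_fraction * nrow(ann))
      extra <- ann[sample.int(nrow(ann), min(n_fail, nrow(ann))), ]
      extra$e_value <- 1e-3
      extra$hmm_name <- "DUF9999"
      ann <- bind_rows(ann, extra)
    }
    # PPI edges over representatives
    pairs <- utils::combn(n, 2)
    same <- fams$class[pairs[1, ]] == fams$class[pairs[2, ]]
    w <- ifelse(same, spec$within_class_odds, 1)
    n_edges <- min(spec$n_edges, ncol(pairs))
    pick <- sample.int(ncol(pairs), n_edges, prob = w)
    edges <- tibble(protein1 = fams$rep_id[pairs[1, pick]],
                    protein2 = fams$rep_id[pairs[2, pick]],
                    combined_score = sample(spec$score_min:spec$score_max,
                                            n_edges, replace = TRUE))
    list(annotations = ann,
         ppi_edges = edges,
         node_classes = tibble(protein = fams$rep_id, class = fams$class))
  })
}

#' Write a domain-annotation tibble in the scanner's TSV layout
#' @param annotations Annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_tsv <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a PPI edge list TSV
#' @param edges Edge tibble (protein1, protein2, combined_score).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ppi_tsv <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
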