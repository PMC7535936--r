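#' Build a per-column emission profile from a multiple alignment
#'
#' Columns with non-gap occupancy of at least 0.5 become match columns.
#' Match-column emissions are pseudocounted with the background:
#' emission(a) = (count(a) + alpha * f(a)) / (n_nongap + alpha), where f
#' is estimated from all residues of the alignment.
#'
#' @param msa A `multiple_alignment`.
#' @param alpha Pseudocount weight (0 gives indicator emissions for
#'   single-sequence alignments).
#' @return A `profile_model`: list with `og_id`, `L`, `emissions`
#'   (L x 20 matrix), `f` (background), `column_occupancy`.
#' @export
build_profile <- function(msa, alpha = 1.0) {
  stopifnot(inherits(msa, "multiple_alignment"))
  chars <- do.call(rbind, strsplit(msa$rows, ""))
  occ <- colMeans(chars != "-")
  res <- chars[chars != "-"]
  f <- as.numeric(table(factor(res, levels = AA20)))
  f <- f / sum(f)
  names(f) <- AA20
  match_cols <- which(occ >= 0.5)
  if (length(match_cols) == 0) abort("alignment has no match columns")
  em <- matrix(0, length(match_cols), 20, dimnames = list(NULL, AA20))
  for (k in seq_along(match_cols)) {
    col <- chars[, match_cols[k]]
    col <- col[col != "-"]
    cnt <- as.numeric(table(factor(col, levels = AA20)))
    em[k, ] <- (cnt + alpha * f) / (length(col) + alpha)
  }
  structure(list(og_id = msa$og_id, L = length(match_cols), emissions = em,
                 f = f, column_occupancy = occ[match_cols]),
            class = "profile_model")
}

#' @export
print.profile_model <- function(x, ...) {
  cat("<profile_model> ", x$og_id, ": ", x$L, " match columns\n", sep = "")
  invisible(x)
}

profile_pair_scores <- function(p, q) {
  # log-odds co-emission score per column pair, in bits; the background
  # is the mean of the two profiles' backgrounds
  f <- (p$f + q$f) / 2
  co <- p$emissions %*% (t(q$emissions) / f)
  log2(pmax(co, 1e-12))
}

#' Profile-profile local search
#'
#' Aligns the query profile against every database profile with local
#' dynamic programming over column-pair scores
#' s(i,j) = log2(sum_a p_i(a) q_j(a) / f(a)) and affine gap costs in
#' bits. Hits with at least `min_cols` aligned columns are ranked by
#' score (ties by lexicographic subject id). Self-hits (same og_id) are
#' excluded.
#'
#' @param query A `profile_model`.
#' @param db List of `profile_model`s.
#' @param gap_open,gap_extend Gap costs in bits.
#' @param min_cols Minimum aligned columns for a reportable hit.
#' @param min_score Significance threshold in bits; hits scoring below
#'   it are not reported. The default was calibrated against an
#'   empirical null of unrelated-family profiles (top chance scores
#'   plateau near 50 bits at typical profile lengths, while genuinely
#'   homologous profiles score in the hundreds).
#' @return Tibble with `query`, `subject`, `score`, `aligned_columns`,
#'   ranked best-first.
#' @export
profile_search <- function(query, db, gap_open = 3, gap_extend = 0.3,
                           min_cols = 20, min_score = 60) {
  if (length(db) == 0) abort("empty profile database")
  rows <- map(db, function(q) {
    if (identical(q$og_id, query$og_id)) return(NULL)
    S <- profile_pair_scores(query, q)
    r <- align_matrix_local(S, gap_open, gap_extend)
    tibble(query = query$og_id, subject = q$og_id,
           score = r$score, aligned_columns = r$aligned_cols)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(query = character(), subject = character(),
                  score = numeric(), aligned_columns = integer()))
  }
  out |>
    filter(.data$aligned_columns >= min_cols, .data$score >= min_score) |>
    arrange(desc(.data$score), .data$subject)
}

#' All-vs-all profile search
#'
#' @param profiles List of `profile_model`s (named by og_id or not).
#' @param ... Passed to [profile_search()].
#' @return Tibble of ranked hits for every query profile.
#' @export
profile_search_all <- function(profiles, ...) {
  bind_rows(map(profiles, profile_search, db = profiles, ...))
}

#' Reciprocal best hits among profile search results
#'
#' (A, B) is a reciprocal best hit iff B is A's top non-self hit and A
#' is B's top non-self hit.
#'
#' @param all_hits Hit tibble from [profile_search_all()].
#' @return Tibble with `a`, `b` (a < b) RBH pairs.
#' @export
reciprocal_best_hits <- function(all_hits) {
  if (nrow(all_hits) == 0) return(tibble(a = character(), b = character()))
  top <- all_hits |>
    arrange(.data$query, desc(.data$score), .data$subject) |>
    distinct(.data$query, .keep_all = TRUE) |>
    select(a = "query", b = "subject")
  top |>
    inner_join(top, by = c(a = "b", b = "a")) |>
    filter(.data$a < .data$b) |>
    distinct(.data$a, .data$b)
}

#' Remove candidate lineage-specific orthogroups with older partners
#'
#' A candidate is `removed_ancient` iff it has a reciprocal best-hit
#' partner whose composition includes at least one species outside the
#' focal clade (indicating the candidate is a split-off piece of an
#' older family); otherwise it is `retained`.
#'
#' @param candidates Character vector of candidate og_ids.
#' @param rbh RBH tibble from [reciprocal_best_hits()].
#' @param compositions Composition tibble from
#'   [orthogroup_composition()] covering all orthogroups.
#' @param focal Focal clade column name in `compositions` (e.g.
#'   "Bilateria").
#' @return Verdict tibble with `og_id`, `status`, `partner`, `reason`.
#' @export
correct_lineage_set <- function(candidates, rbh, compositions,
                                focal = "Bilateria") {
  partner_of <- bind_rows(rbh, rbh |> rename(a = "b", b = "a"))
  outside <- compositions$total_species - cc(compositions, focal)
  names(outside) <- compositions$og_id
  verdicts <- map(candidates, function(og) {
    partners <- partner_of$b[partner_of$a == og]
    bad <- partners[!is.na(outside[partners]) & outside[partners] > 0]
    if (length(bad) > 0) {
      tibble(og_id = og, status = "removed_ancient", partner = bad[1],
             reason = paste0("reciprocal best hit ", bad[1], " contains ",
                             outside[bad[1]], " species outside ", focal))
    } else {
      tibble(og_id = og, status = "retained", partner = NA_character_,
             reason = ifelse(length(partners) == 0, "no significant partner",
                             "all partners inside focal clade"))
    }
  })
  bind_rows(verdicts)
}

#' Serialize profiles as plain-text tables
#'
#' One block per profile: a header line `># <og_id> L=<L>` followed by
#' L lines of 20 whitespace-separated emission values (column order
#' ARNDCQEGHILKMFPSTWYV), then a line `#f` with the 20 background
#' frequencies.
#'
#' @param profiles List of `profile_model`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in profiles) {
    writeLines(paste0("># ", p$og_id, " L=", p$L), con)
    utils::write.table(format(p$emissions, digits = 8), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    writeLines(paste("#f", paste(format(p$f, digits = 8), collapse = " ")), con)
  }
  invisible(path)
}
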