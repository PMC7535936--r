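# BLOSUM62 matrix, loaded once per session from Biostrings.
blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

#' Internal aligner configuration
#'
#' Affine-gap Smith-Waterman with BLOSUM62 and Karlin-Altschul
#' E-values, E = K * m * n * exp(-lambda * S), where m is the query
#' length and n the effective database residue count. The lambda and K
#' defaults are the standard gapped BLOSUM62 (11/1) constants.
#'
#' @param gap_open,gap_extend Affine gap penalties.
#' @param lambda,K Karlin-Altschul constants.
#' @param db_size Effective database residue count; when `NULL` it is
#'   computed from the search's subject set.
#' @param kmer_prescreen Use a shared-word prescreen (BLAST-like
#'   seeding) before exact alignment in all-vs-all searches.
#' @param k,min_shared Word length and minimum number of shared distinct
#'   words for a pair to be aligned when prescreening.
#' @return An `aligner_config` list.
#' @export
aligner_config <- function(gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041, db_size = NULL,
                           kmer_prescreen = TRUE, k = 4, min_shared = 2) {
  stopifnot(gap_open > 0, gap_extend > 0, lambda > 0, K > 0)
  structure(list(gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K, db_size = db_size,
                 kmer_prescreen = kmer_prescreen, k = k,
                 min_shared = min_shared),
            class = "aligner_config")
}

karlin_evalue <- function(score, m, n, config) {
  config$K * m * n * exp(-config$lambda * score)
}

# Distinct-kmer incidence matrix over a character vector of sequences.
kmer_incidence <- function(seqs, k) {
  kmers <- map(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    unique(substring(s, 1:(L - k + 1), k:L))
  })
  dict <- unique(unlist(kmers))
  i <- rep(seq_along(seqs), lengths(kmers))
  j <- match(unlist(kmers), dict)
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(seqs), length(dict)))
}

# Unordered candidate pairs sharing >= min_shared distinct kmers.
kmer_candidate_pairs <- function(seqs, k, min_shared) {
  X <- kmer_incidence(seqs, k)
  C <- Matrix::tcrossprod(X)
  s <- Matrix::summary(C)
  s <- s[s$i < s$j & s$x >= min_shared, , drop = FALSE]
  tibble(i = s$i, j = s$j)
}

all_pairs <- function(n) {
  if (n < 2) return(tibble(i = integer(), j = integer()))
  cmb <- utils::combn(n, 2)
  tibble(i = cmb[1, ], j = cmb[2, ])
}

# Align a set of unordered index pairs; returns one row per pair with
# the local alignment score and per-side aligned residue counts.
align_pairs <- function(seqs, pairs, config) {
  if (nrow(pairs) == 0) {
    return(tibble(i = integer(), j = integer(), score = numeric(),
                  ali = integer(), alj = integer()))
  }
  out <- vector("list", length(unique(pairs$j)))
  n <- 0L
  for (jj in unique(pairs$j)) {
    ii <- pairs$i[pairs$j == jj]
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(seqs[ii]), Biostrings::AAString(seqs[jj]),
      type = "local", substitutionMatrix = blosum62(),
      gapOpening = config$gap_open, gapExtension = config$gap_extend)
    p <- Biostrings::pattern(aln)
    s <- Biostrings::subject(aln)
    n <- n + 1L
    out[[n]] <- tibble(i = ii, j = jj, score = Biostrings::score(aln),
                       ali = BiocGenerics::end(p) - BiocGenerics::start(p) + 1L,
                       alj = BiocGenerics::end(s) - BiocGenerics::start(s) + 1L,
                       nmatch = Biostrings::nmatch(aln),
                       naligned = Biostrings::nchar(aln))
  }
  bind_rows(out)
}

# Best E-value of each query against a reference set (exhaustive).
best_evalues <- function(queries, reference, config) {
  n_db <- config$db_size %||% sum(nchar(reference$residues))
  vapply(seq_len(nrow(queries)), function(i) {
    sc <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(reference$residues),
      Biostrings::AAString(queries$residues[i]),
      type = "local", substitutionMatrix = blosum62(),
      gapOpening = config$gap_open, gapExtension = config$gap_extend,
      scoreOnly = TRUE)
    min(karlin_evalue(sc, nchar(queries$residues[i]), n_db, config))
  }, numeric(1))
}

#' All-vs-all local similarity search
#'
#' Computes local alignments for every sequence pair (optionally
#' restricted to pairs sharing seed words, see [aligner_config()]) and
#' reports each ordered pair with E-value below `e_cutoff`. E-values
#' follow the Karlin-Altschul model with m = query length and n = the
#' effective database residue count (total residues of `records` unless
#' fixed in the config). `percent_match` is the fraction of query
#' residues inside the aligned region.
#'
#' @param records Tibble with `id`, `residues` (>= 2 rows).
#' @param config An [aligner_config()].
#' @param e_cutoff Keep hits with E below this value.
#' @return Tibble with `query`, `subject`, `score`, `e_value`,
#'   `percent_match`, sorted by query then subject. Self-hits excluded.
#' @export
all_vs_all_similarity <- function(records, config = aligner_config(),
                                  e_cutoff = 1e-5) {
  if (nrow(records) < 2) abort("need at least two sequences")
  seqs <- records$residues
  pairs <- if (isTRUE(config$kmer_prescreen)) {
    kmer_candidate_pairs(seqs, config$k, config$min_shared)
  } else {
    all_pairs(length(seqs))
  }
  res <- align_pairs(seqs, pairs, config)
  n_db <- config$db_size %||% sum(nchar(seqs))
  li <- nchar(seqs[res$i]); lj <- nchar(seqs[res$j])
  fwd <- tibble(query = records$id[res$i], subject = records$id[res$j],
                score = res$score,
                e_value = karlin_evalue(res$score, li, n_db, config),
                percent_match = res$ali / li)
  rev <- tibble(query = records$id[res$j], subject = records$id[res$i],
                score = res$score,
                e_value = karlin_evalue(res$score, lj, n_db, config),
                percent_match = res$alj / lj)
  bind_rows(fwd, rev) |>
    filter(.data$e_value < e_cutoff) |>
    arrange(.data$query, .data$subject)
}

#' Map external query proteins onto orthogroups
#'
#' A query maps to the orthogroup of its best local-alignment hit iff
#' the hit has identity above `min_identity` over at least `min_len`
#' aligned residues and the orthogroup contains at least `min_species`
#' species (broad-sampling requirement). Identity is matches divided by
#' aligned columns.
#'
#' @param queries Tibble with `id`, `residues`.
#' @param db Tibble with `id`, `residues` of clustered sequences.
#' @param groups Orthogroup tibble (`og_id`, `member_id`, `taxid`).
#' @param min_identity,min_len,min_species Mapping thresholds.
#' @param config An [aligner_config()].
#' @return Tibble with `query`, `og_id` (NA when unmapped), `identity`,
#'   `aligned`, `reason`.
#' @export
map_external_queries <- function(queries, db, groups,
                                 min_identity = 0.95, min_len = 100,
                                 min_species = 75,
                                 config = aligner_config()) {
  og_of <- stats::setNames(groups$og_id, groups$member_id)
  og_species <- groups |>
    group_by(.data$og_id) |>
    summarise(n_species = n_distinct(.data$taxid), .groups = "drop")
  n_sp <- stats::setNames(og_species$n_species, og_species$og_id)
  seqs <- c(queries$residues, db$residues)
  nq <- nrow(queries)
  pairs <- if (isTRUE(config$kmer_prescreen)) {
    p <- kmer_candidate_pairs(seqs, config$k, config$min_shared)
    filter(p, .data$i <= nq, .data$j > nq)
  } else {
    tidyr::expand_grid(i = seq_len(nq), j = nq + seq_len(nrow(db)))
  }
  res <- align_pairs(seqs, pairs, config)
  out <- map(seq_len(nq), function(qi) {
    hits <- res[res$i == qi, ]
    if (nrow(hits) == 0) {
      return(tibble(query = queries$id[qi], og_id = NA_character_,
                    identity = NA_real_, aligned = NA_integer_,
                    reason = "no hit"))
    }
    best <- hits[order(-hits$score, db$id[hits$j - nq]), ][1, ]
    idty <- best$nmatch / best$naligned
    og <- unname(og_of[db$id[best$j - nq]])
    reason <- "mapped"
    if (is.na(og)) reason <- "best hit not clustered"
    else if (best$naligned < min_len) reason <- "aligned length below minimum"
    else if (idty <= min_identity) reason <- "identity below minimum"
    else if (n_sp[og] < min_species) reason <- "orthogroup too few species"
    tibble(query = queries$id[qi],
           og_id = ifelse(reason == "mapped", og, NA_character_),
           identity = idty, aligned = as.integer(best$naligned),
           reason = reason)
  })
  bind_rows(out)
}
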