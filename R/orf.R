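#' Preprocessing configuration
#'
#' Defaults follow the published pipeline: 25-residue minimum ORF
#' length, splitting on runs of 9+ 'X', 35-residue minimum flank after
#' splitting, similarity prefilter at E < 10, 90% identity redundancy
#' reduction, and top-3 ORFs per transcriptome contig.
#'
#' @param min_orf_len Minimum ORF length in residues.
#' @param x_run_len Minimum 'X'-run length that triggers splitting.
#' @param min_flank Minimum number of valid (non-X) residues for a
#'   flank to survive splitting.
#' @param e_max Similarity prefilter E-value threshold (keep if E < e_max).
#' @param identity_threshold Redundancy-reduction identity threshold.
#' @param top_k_tx ORFs kept per transcriptome contig.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(min_orf_len = 25, x_run_len = 9, min_flank = 35,
                              e_max = 10, identity_threshold = 0.90, top_k_tx = 3) {
  stopifnot(min_orf_len > 0, x_run_len > 0, min_flank > 0, e_max > 0,
            identity_threshold > 0, identity_threshold <= 1, top_k_tx > 0)
  structure(list(min_orf_len = min_orf_len, x_run_len = x_run_len,
                 min_flank = min_flank, e_max = e_max,
                 identity_threshold = identity_threshold, top_k_tx = top_k_tx),
            class = "preprocess_config")
}

translate_frame <- function(dna, offset) {
  len <- length(dna) - offset
  len <- len - (len %% 3)
  if (len < 3) return("")
  as.character(Biostrings::translate(
    Biostrings::subseq(dna, start = offset + 1, width = len),
    if.fuzzy.codon = "X", no.init.codon = TRUE))
}

orfs_in_translation <- function(aa, min_len) {
  # maximal stop-free stretches; sequence ends count as boundaries
  if (nchar(aa) == 0) return(tibble(i1 = integer(), i2 = integer(), residues = character()))
  parts <- strsplit(aa, "*", fixed = TRUE)[[1]]
  ends <- cumsum(nchar(parts) + 1L) - 1L     # residue index of last char of each part
  starts <- ends - nchar(parts) + 1L
  keep <- nchar(parts) >= min_len
  tibble(i1 = starts[keep], i2 = ends[keep], residues = parts[keep])
}

#' Six-frame ORF extraction
#'
#' Translates each contig in all six reading frames (standard genetic
#' code; codons containing 'N' translate to 'X') and returns every
#' maximal stop-free stretch of at least `min_orf_len` residues.
#' Coordinates are 0-based half-open on the forward strand.
#'
#' @param contigs Tibble with `id` and `bases` (A/C/G/T/N), or a single
#'   nucleotide string.
#' @param config A [preprocess_config()].
#' @return Tibble with columns `contig`, `frame` (+1..+3, -1..-3),
#'   `start`, `end`, `residues`.
#' @export
six_frame_orfs <- function(contigs, config = preprocess_config()) {
  if (is.character(contigs)) {
    contigs <- tibble(id = paste0("ctg", seq_along(contigs)), bases = contigs)
  }
  out <- pmap(list(contigs$id, contigs$bases), function(cid, bases) {
    if (nchar(bases) == 0) return(NULL)
    dna <- Biostrings::DNAString(bases)
    L <- length(dna)
    rc <- Biostrings::reverseComplement(dna)
    res <- list()
    for (f in 1:3) {
      fwd <- orfs_in_translation(translate_frame(dna, f - 1L), config$min_orf_len)
      if (nrow(fwd) > 0) {
        res[[length(res) + 1L]] <- tibble(
          contig = cid, frame = f,
          start = (f - 1L) + 3L * (fwd$i1 - 1L),
          end = (f - 1L) + 3L * fwd$i2,
          residues = fwd$residues)
      }
      rev <- orfs_in_translation(translate_frame(rc, f - 1L), config$min_orf_len)
      if (nrow(rev) > 0) {
        # coordinates on the reverse complement, reflected to forward
        s_rc <- (f - 1L) + 3L * (rev$i1 - 1L)
        e_rc <- (f - 1L) + 3L * rev$i2
        res[[length(res) + 1L]] <- tibble(
          contig = cid, frame = -f,
          start = L - e_rc, end = L - s_rc,
          residues = rev$residues)
      }
    }
    bind_rows(res)
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(contig = character(), frame = integer(),
                  start = integer(), end = integer(), residues = character()))
  }
  arrange(out, .data$contig, .data$frame, .data$start)
}

#' Split sequences on long 'X' runs
#'
#' Runs of at least `x_run_len` 'X' (translated sequencing gaps or
#' masked repeats) are removed; every flanking fragment with at least
#' `min_flank` valid (non-X) residues is emitted under a new identifier
#' (`<uid>.s<k>`); shorter flanks are discarded. Records without a
#' qualifying run pass through unchanged.
#'
#' @param records Tibble with `id` and `residues`.
#' @param config A [preprocess_config()].
#' @return Tibble with `id`, `residues` (plus any other input columns
#'   carried through for unsplit records).
#' @export
split_x_runs <- function(records, config = preprocess_config()) {
  pat <- paste0("X{", config$x_run_len, ",}")
  out <- pmap(list(seq_len(nrow(records))), function(i) {
    rec <- records[i, ]
    if (!grepl(pat, rec$residues)) return(rec)
    parts <- strsplit(rec$residues, pat)[[1]]
    parts <- parts[nchar(gsub("X", "", parts)) >= config$min_flank]
    if (length(parts) == 0) return(NULL)
    new <- rec[rep(1L, length(parts)), ]
    new$residues <- parts
    new$id <- paste0(rec$id, ".s", seq_along(parts))
    new
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) records[0, ] else out
}

#' Keep the longest ORFs per transcriptome contig
#'
#' Per contig, the `top_k_tx` longest ORFs are retained; ties are broken
#' by earlier start, then lexicographically smaller frame label.
#'
#' @param orfs ORF tibble from [six_frame_orfs()].
#' @param config A [preprocess_config()].
#' @return Filtered ORF tibble.
#' @export
transcriptome_top_orfs <- function(orfs, config = preprocess_config()) {
  orfs |>
    group_by(.data$contig) |>
    arrange(desc(nchar(.data$residues)), .data$start, as.character(.data$frame),
            .by_group = TRUE) |>
    slice_head(n = config$top_k_tx) |>
    ungroup()
}

#' Similarity prefilter against a reference set
#'
#' An ORF is kept iff its best local-alignment E-value against the
#' reference set is below `e_max` (Karlin-Altschul model, see
#' [aligner_config()]), mirroring the published E < 10 screen against a
#' curated opisthokont database.
#'
#' @param orfs Tibble with `id`, `residues`.
#' @param reference Tibble with `id`, `residues` (non-empty).
#' @param config A [preprocess_config()].
#' @param aligner An [aligner_config()].
#' @return The kept rows of `orfs`, with a `best_e` column appended.
#' @export
similarity_prefilter <- function(orfs, reference, config = preprocess_config(),
                                 aligner = aligner_config()) {
  if (nrow(reference) == 0) abort("reference set must be non-empty")
  if (nrow(orfs) == 0) return(mutate(orfs, best_e = numeric(0)))
  best <- best_evalues(orfs, reference, aligner)
  kept <- mutate(orfs, best_e = best)
  filter(kept, .data$best_e < config$e_max)
}

#' Greedy redundancy reduction at an identity threshold
#'
#' Records are processed by descending length (ties by id); each joins
#' the first existing representative to which its global-alignment
#' identity (matches divided by the shorter sequence's length) reaches
#' `identity_threshold`, otherwise it founds a new representative.
#' The greedy longest-first sweep mirrors standard redundancy-removal
#' practice (CD-HIT-like).
#'
#' @param records Tibble with `id`, `residues`.
#' @param config A [preprocess_config()].
#' @return The representative rows, in founding order.
#' @export
reduce_redundancy <- function(records, config = preprocess_config()) {
  if (nrow(records) <= 1) return(records)
  ord <- order(-nchar(records$residues), records$id)
  records <- records[ord, ]
  reps <- integer(0)
  for (i in seq_len(nrow(records))) {
    joined <- FALSE
    if (length(reps) > 0) {
      pat <- Biostrings::AAStringSet(records$residues[reps])
      aln <- Biostrings::pairwiseAlignment(
        pat, Biostrings::AAString(records$residues[i]), type = "global",
        substitutionMatrix = blosum62(),
        gapOpening = 11, gapExtension = 1)
      idty <- Biostrings::nmatch(aln) /
        pmin(nchar(records$residues[reps]), nchar(records$residues[i]))
      joined <- any(idty >= config$identity_threshold)
    }
    if (!joined) reps <- c(reps, i)
  }
  records[reps, ]
}

#' Percent reduction between two sequence counts, truncated
#'
#' Truncation (not rounding) to `digits` decimals, as used when quoting
#' pipeline attrition percentages.
#'
#' @param pre,post Counts before and after a filtering step.
#' @param digits Decimals to keep.
#' @return The percent reduction as a number.
#' @export
percent_reduction <- function(pre, post, digits = 1) {
  floor((1 - post / pre) * 100 * 10^digits) / 10^digits
}
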