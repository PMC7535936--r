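profile_freqs <- function(rows) {
  # per-column amino-acid frequency matrix (L x 20) over non-gap residues
  chars <- do.call(rbind, strsplit(rows, ""))
  L <- ncol(chars)
  f <- matrix(0, L, 20, dimnames = list(NULL, AA20))
  for (j in seq_len(L)) {
    tb <- table(factor(chars[, j], levels = AA20))
    tot <- sum(tb)
    if (tot > 0) f[j, ] <- as.numeric(tb) / tot
  }
  f
}

merge_alignments <- function(rows_a, rows_b, gap_open = 11, gap_extend = 1) {
  fa <- profile_freqs(rows_a)
  fb <- profile_freqs(rows_b)
  B <- blosum62()[AA20, AA20]
  S <- fa %*% B %*% t(fb)
  path <- align_matrix_global(S, gap_open, gap_extend)$path
  ca <- do.call(rbind, strsplit(rows_a, ""))
  cb <- do.call(rbind, strsplit(rows_b, ""))
  ia <- 0L; ib <- 0L
  out_a <- matrix("", nrow(ca), length(path))
  out_b <- matrix("", nrow(cb), length(path))
  for (k in seq_along(path)) {
    mv <- path[k]
    if (mv == 1L) { ia <- ia + 1L; ib <- ib + 1L
      out_a[, k] <- ca[, ia]; out_b[, k] <- cb[, ib]
    } else if (mv == 2L) { ia <- ia + 1L
      out_a[, k] <- ca[, ia]; out_b[, k] <- "-"
    } else { ib <- ib + 1L
      out_a[, k] <- "-"; out_b[, k] <- cb[, ib]
    }
  }
  c(apply(out_a, 1, paste, collapse = ""),
    apply(out_b, 1, paste, collapse = ""))
}

pairwise_identity_matrix <- function(seqs) {
  n <- length(seqs)
  idm <- matrix(1, n, n)
  if (n < 2) return(idm)
  same_len <- length(unique(nchar(seqs))) == 1
  if (same_len) {
    chars <- do.call(rbind, strsplit(seqs, ""))
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      idm[i, j] <- idm[j, i] <- mean(chars[i, ] == chars[j, ])
    }
  } else {
    for (i in 1:(n - 1)) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(seqs[(i + 1):n]), Biostrings::AAString(seqs[i]),
        type = "global", substitutionMatrix = blosum62(),
        gapOpening = 11, gapExtension = 1)
      idty <- Biostrings::nmatch(aln) / pmin(nchar(seqs[(i + 1):n]), nchar(seqs[i]))
      idm[i, (i + 1):n] <- idm[(i + 1):n, i] <- idty
    }
  }
  idm
}

#' Progressive multiple alignment of an orthogroup
#'
#' Builds a single-linkage guide tree from pairwise identities and
#' merges profiles along it with BLOSUM62 sum-of-pairs column scores
#' and affine gaps. Deterministic. An externally produced alignment can
#' be supplied anywhere a `multiple_alignment` is accepted via
#' [multiple_alignment()].
#'
#' @param members Tibble with `id`, `residues` (>= 1 row).
#' @param og_id Orthogroup identifier carried on the result.
#' @return A `multiple_alignment`: list with `og_id`, `rows` (named
#'   character vector of aligned strings) and `n_columns`.
#' @export
build_msa <- function(members, og_id = NA_character_) {
  stopifnot(nrow(members) >= 1)
  if (nrow(members) == 1) {
    return(multiple_alignment(stats::setNames(members$residues, members$id), og_id))
  }
  idm <- pairwise_identity_matrix(members$residues)
  hc <- stats::hclust(stats::as.dist(1 - idm), method = "single")
  # follow the merge schedule; negative entries are leaves
  partial <- list()
  for (k in seq_len(nrow(hc$merge))) {
    pick <- function(x) {
      if (x < 0) stats::setNames(members$residues[-x], members$id[-x])
      else partial[[x]]
    }
    a <- pick(hc$merge[k, 1]); b <- pick(hc$merge[k, 2])
    merged <- merge_alignments(unname(a), unname(b))
    names(merged) <- c(names(a), names(b))
    partial[[k]] <- merged
  }
  rows <- partial[[nrow(hc$merge)]]
  multiple_alignment(rows[members$id], og_id)
}

#' Construct/validate a multiple alignment object
#'
#' @param rows Named character vector of equal-length aligned strings
#'   (gap character `-`).
#' @param og_id Orthogroup identifier.
#' @return A `multiple_alignment` list.
#' @export
multiple_alignment <- function(rows, og_id = NA_character_) {
  if (length(rows) < 1) abort("alignment needs at least one row")
  if (length(unique(nchar(rows))) != 1) abort("alignment rows differ in length")
  chars <- do.call(rbind, strsplit(rows, ""))
  all_gap <- apply(chars == "-", 2, all)
  if (any(all_gap)) {
    chars <- chars[, !all_gap, drop = FALSE]
    rows <- stats::setNames(apply(chars, 1, paste, collapse = ""), names(rows))
  }
  structure(list(og_id = og_id, rows = rows, n_columns = nchar(rows[[1]])),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat("<multiple_alignment> ", x$og_id, ": ", length(x$rows), " rows x ",
      x$n_columns, " columns\n", sep = "")
  invisible(x)
}
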