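#' Read a FASTA file into a sequence tibble
#'
#' Sequence tables throughout the package are tibbles with columns
#' `id` and `residues` (amino acid) or `id` and `bases` (nucleotide);
#' a `taxid` column is added when the identifiers follow the
#' `<taxid>|<source>|<uid>` naming scheme.
#'
#' @param path Path to a FASTA file.
#' @param type `"AA"` or `"DNA"`.
#' @return A tibble with one row per record.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  out <- tibble(id = ids)
  if (type == "AA") out$residues <- as.character(set) else out$bases <- as.character(set)
  names(out[[2]]) <- NULL
  if (all(grepl("^[0-9]+\\|", ids))) out$taxid <- taxid_of(ids)
  out
}

#' Write a sequence tibble to FASTA (60-column wrap)
#'
#' @param seqs Tibble with `id` and `residues` (or `bases`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  col <- if ("residues" %in% names(seqs)) "residues" else "bases"
  set <- if (col == "residues") Biostrings::AAStringSet(seqs[[col]])
         else Biostrings::DNAStringSet(seqs[[col]])
  names(set) <- seqs$id
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

as_aastringset <- function(seqs) {
  set <- Biostrings::AAStringSet(seqs$residues)
  names(set) <- seqs$id
  set
}
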