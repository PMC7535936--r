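#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_chr map_int map_dbl map_lgl map2 pmap imap walk
#' @importFrom stringr str_split str_detect str_starts str_locate_all str_sub
#' @importFrom methods as
#' @useDynLib cladesift, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Deterministic substream seed derived from a master seed and a stream name,
# kept below 2^31 so it is a valid R integer.
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% 2147483629
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629 + 1)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(substream_seed(seed, name))
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

#' Parse pipeline sequence identifiers
#'
#' Identifiers follow `<taxid>|<source>|<uid>` with source one of
#' `ncbi` (curated proteome), `orf` (genomic six-frame ORF) or
#' `tx` (transcriptome ORF).
#'
#' @param ids Character vector of sequence identifiers.
#' @return A tibble with columns `id`, `taxid`, `source`, `uid`.
#' @export
parse_seq_ids <- function(ids) {
  parts <- str_split(ids, stringr::fixed("|"))
  bad <- lengths(parts) != 3
  if (any(bad)) {
    abort(paste0("malformed sequence id(s): ",
                 paste(utils::head(ids[bad], 3), collapse = ", ")))
  }
  m <- do.call(rbind, parts)
  tibble(id = ids, taxid = as.integer(m[, 1]), source = m[, 2], uid = m[, 3])
}

make_seq_id <- function(taxid, source, uid) paste(taxid, source, uid, sep = "|")

taxid_of <- function(ids) {
  as.integer(sub("\\|.*$", "", ids))
}
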