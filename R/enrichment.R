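#' Default transcription-factor domain prefixes
#'
#' The ten DNA-binding domain prefixes used to flag transcription
#' factors; matching is by prefix, so `"zf-"` captures every
#' zinc-finger family domain.
#'
#' @return Character vector of prefixes.
#' @export
tf_domain_list <- function() {
  c("Basic", "bZIP_2", "HLH", "HNF-1_N", "Homeobox",
    "Hox9_act", "HPD", "SOBP", "THAP", "zf-")
}

.domain_cols <- c("seq_id", "aln_start", "aln_end", "env_start", "env_end",
                  "hmm_acc", "hmm_name", "type", "hmm_start", "hmm_end",
                  "hmm_length", "bit_score", "e_value")

#' Load a domain-annotation table
#'
#' Reads the domain scanner's 13-column tab/whitespace-separated layout
#' and keeps rows with E-value below the cutoff. Malformed rows are
#' reported with their line numbers and skipped.
#'
#' @param path Path to the table (or a data frame already in the
#'   column layout).
#' @param e_cutoff E-value cutoff (keep if below).
#' @return Annotation tibble; attribute `n_dropped` counts rows removed
#'   by the cutoff.
#' @export
load_domain_annotations <- function(path, e_cutoff = 5e-5) {
  empty_ann <- function() {
    tibble(seq_id = character(0), aln_start = integer(0),
           aln_end = integer(0), env_start = integer(0),
           env_end = integer(0), hmm_acc = character(0),
           hmm_name = character(0), type = character(0),
           hmm_start = integer(0), hmm_end = integer(0),
           hmm_length = integer(0), bit_score = numeric(0),
           e_value = numeric(0))
  }
  if (is.data.frame(path)) {
    if (nrow(path) == 0) return(structure(empty_ann(), n_dropped = 0L))
    ann <- as_tibble(path)
    names(ann) <- .domain_cols[seq_len(ncol(ann))]
  } else {
    lines <- readLines(path)
    lines <- lines[!str_starts(trimws(lines), "#") & nzchar(trimws(lines))]
    if (length(lines) == 0) {
      warn("empty annotation file")
      return(structure(empty_ann(), n_dropped = 0L))
    }
    fields <- str_split(lines, "\\s+")
    ok <- lengths(fields) >= length(.domain_cols)
    if (any(!ok)) {
      warn(paste0("skipping malformed annotation row(s) at line(s): ",
                  paste(utils::head(which(!ok), 10), collapse = ", ")))
    }
    m <- do.call(rbind, fields[ok])
    ann <- tibble(seq_id = m[, 1],
                  aln_start = as.integer(m[, 2]), aln_end = as.integer(m[, 3]),
                  env_start = as.integer(m[, 4]), env_end = as.integer(m[, 5]),
                  hmm_acc = m[, 6], hmm_name = m[, 7], type = m[, 8],
                  hmm_start = as.integer(m[, 9]), hmm_end = as.integer(m[, 10]),
                  hmm_length = as.integer(m[, 11]),
                  bit_score = as.numeric(m[, 12]), e_value = as.numeric(m[, 13]))
  }
  kept <- filter(ann, .data$e_value < e_cutoff)
  structure(kept, n_dropped = nrow(ann) - nrow(kept))
}

#' Count transcription-factor and poly-zinc-finger proteins
#'
#' A protein is a transcription factor iff at least one of its domains
#' matches a prefix in `tf_list`; it is a poly-ZF protein iff it
#' carries at least `min_fingers` copies of `zf_domain` (C2H2 zinc
#' fingers by default).
#'
#' @param annotations Annotation tibble from
#'   [load_domain_annotations()].
#' @param tf_list Character vector of domain-name prefixes.
#' @param zf_domain Domain counted for the poly-ZF census.
#' @param min_fingers Minimum copy number.
#' @return List with `tf_proteins`, `polyzf_proteins` (character
#'   vectors of ids) and counts `n_tf`, `n_polyzf`.
#' @export
count_domain_classes <- function(annotations, tf_list = tf_domain_list(),
                                 zf_domain = "zf-C2H2", min_fingers = 6) {
  if (nrow(annotations) == 0) {
    return(list(tf_proteins = character(0), polyzf_proteins = character(0),
                n_tf = 0L, n_polyzf = 0L))
  }
  is_tf_domain <- reduce_or(map(tf_list, ~ str_starts(annotations$hmm_name, stringr::fixed(.x))))
  tf_proteins <- sort(unique(annotations$seq_id[is_tf_domain]))
  zf <- annotations |>
    filter(.data$hmm_name == zf_domain) |>
    count(.data$seq_id) |>
    filter(.data$n >= min_fingers)
  list(tf_proteins = tf_proteins, polyzf_proteins = sort(zf$seq_id),
       n_tf = length(tf_proteins), n_polyzf = nrow(zf))
}

reduce_or <- function(lst) Reduce(`|`, lst, init = rep(FALSE, length(lst[[1]])))

#' Control draws of proteins and their transcription-factor counts
#'
#' Draws `reps` random subsets of size `n` without replacement from the
#' reference proteome and counts transcription factors per draw,
#' returning the mean and sample (n-1) standard deviation.
#'
#' @param proteome_tf_flags Logical vector, one element per reference
#'   protein (TRUE = transcription factor).
#' @param n Draw size.
#' @param reps Number of draws.
#' @param seed Integer seed.
#' @return List with `mean`, `sd`, `counts`.
#' @export
control_draw_stats <- function(proteome_tf_flags, n, reps = 10, seed = 42) {
  if (n > length(proteome_tf_flags)) abort("draw size exceeds proteome size")
  with_substream(seed, "control_draws", {
    counts <- map_int(seq_len(reps), function(i) {
      sum(proteome_tf_flags[sample.int(length(proteome_tf_flags), n)])
    })
    list(mean = mean(counts), sd = stats::sd(counts), counts = counts)
  })
}

stat_result <- function(method, statistic, p_value, details = list()) {
  tibble(method = method, statistic = statistic, p_value = p_value,
         details = list(details))
}

#' Upper-tail normal probability
#'
#' P(X > x) for X ~ Normal(mu, sigma); the enrichment p-value used when
#' an observed count is compared against control-draw mean and SD.
#'
#' @param x Observed value.
#' @param mu,sigma Normal parameters (sigma > 0).
#' @return A one-row result tibble (`method`, `statistic`, `p_value`,
#'   `details`).
#' @export
normal_tail_p <- function(x, mu, sigma) {
  if (sigma <= 0) abort("sigma must be positive")
  p <- stats::pnorm(x, mean = mu, sd = sigma, lower.tail = FALSE)
  stat_result("normal_tail", (x - mu) / sigma, p, list(mu = mu, sigma = sigma))
}

#' Upper-tail binomial probability
#'
#' P(X >= k) for X ~ Binomial(n, p).
#'
#' @param k Observed count.
#' @param n Number of draws.
#' @param p Success probability.
#' @return A one-row result tibble.
#' @export
binomial_tail_p <- function(k, n, p) {
  stopifnot(k >= 0, k <= n, p >= 0, p <= 1)
  pv <- if (k == 0) 1 else stats::pbinom(k - 1, n, p, lower.tail = FALSE)
  stat_result("binomial_tail", k, pv, list(n = n, p = p))
}

#' Pearson chi-squared test on a 2x2 table
#'
#' With Yates continuity correction (the correction term is
#' min(0.5, |O-E|), so a table with O = E gives statistic 0), df = 1.
#'
#' @param table 2x2 matrix of counts.
#' @param yates Apply the continuity correction.
#' @return A one-row result tibble.
#' @export
chisq_2x2 <- function(table, yates = TRUE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("zero margin in 2x2 table")
  }
  ht <- stats::chisq.test(table, correct = yates)
  stat_result("chisq_2x2", unname(ht$statistic), ht$p.value,
              list(df = unname(ht$parameter), yates = yates))
}

#' Map annotated domains to GO terms
#'
#' Joins each annotated domain to its GO terms through a pfam2go-layout
#' mapping (`Pfam:PF00046 Homeodomain > GO:... ; GO:0003677`). Domains
#' without a mapping are tallied separately; relative frequencies are
#' over mapped term occurrences and sum to 1.
#'
#' @param annotations Annotation tibble.
#' @param pfam2go Path to a pfam2go flat file, or a tibble with columns
#'   `domain`, `go_id`, `go_name`.
#' @return List with `terms` (tibble: go_id, go_name, count,
#'   rel_frequency) and `n_unmapped` (domain occurrences without GO
#'   mapping).
#' @export
map_go_terms <- function(annotations, pfam2go) {
  mapping <- if (is.data.frame(pfam2go)) as_tibble(pfam2go)
             else read_pfam2go(pfam2go)
  dom <- annotations |>
    mutate(domain = sub("\\..*$", "", .data$hmm_acc), name = .data$hmm_name)
  joined <- dom |>
    left_join(mapping, by = "domain", relationship = "many-to-many")
  # fall back to matching by domain name when accession fails
  miss <- is.na(joined$go_id) & joined$name %in% mapping$domain_name
  if (any(miss)) {
    repl <- mapping[match(joined$name[miss], mapping$domain_name), ]
    joined$go_id[miss] <- repl$go_id
    joined$go_name[miss] <- repl$go_name
  }
  n_unmapped <- joined |>
    filter(is.na(.data$go_id)) |>
    distinct(.data$seq_id, .data$hmm_name, .data$aln_start) |>
    nrow()
  terms <- joined |>
    filter(!is.na(.data$go_id)) |>
    count(.data$go_id, .data$go_name, name = "count") |>
    mutate(rel_frequency = .data$count / sum(.data$count)) |>
    arrange(desc(.data$count), .data$go_id)
  list(terms = terms, n_unmapped = n_unmapped)
}

#' Read a pfam2go flat file
#'
#' Lines look like
#' `Pfam:PF00046 Homeodomain > GO:DNA binding ; GO:0003677`; comment
#' lines start with `!`.
#'
#' @param path Path to the file.
#' @return Tibble with `domain`, `domain_name`, `go_name`, `go_id`.
#' @export
read_pfam2go <- function(path) {
  lines <- readLines(path)
  lines <- lines[!str_starts(lines, "!") & nzchar(lines)]
  m <- stringr::str_match(
    lines, "^Pfam:(PF\\d+)\\s+(\\S+)\\s+>\\s+GO:(.*?)\\s+;\\s+(GO:\\d+)\\s*$")
  ok <- !is.na(m[, 1])
  tibble(domain = m[ok, 2], domain_name = m[ok, 3],
         go_name = m[ok, 4], go_id = m[ok, 5])
}
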