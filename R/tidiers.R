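#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a run report
#'
#' One row per pipeline stage counter.
#'
#' @param x A `run_report`.
#' @param ... Ignored.
#' @return A tibble with `stage` and `count`.
#' @exportS3Method generics::tidy
tidy.run_report <- function(x, ...) {
  tibble(stage = names(x$counts),
         count = as.integer(unlist(x$counts)))
}

#' One-row summary of a run report
#'
#' @param x A `run_report`.
#' @param ... Ignored.
#' @return A one-row tibble.
#' @exportS3Method generics::glance
glance.run_report <- function(x, ...) {
  tibble(n_orthogroups = x$counts$orthogroups %||% NA_integer_,
         n_candidates = x$counts$candidates %||% NA_integer_,
         n_removed = x$counts$removed_ancient %||% 0L,
         n_final = length(x$final_set),
         seed = x$seed)
}

#' Tidy per-node connectivity statistics
#'
#' @param x A `connectivity_stats`.
#' @param ... Ignored.
#' @return The per-node tibble.
#' @exportS3Method generics::tidy
tidy.connectivity_stats <- function(x, ...) x$per_node

#' Per-class summary of connectivity statistics
#'
#' @param x A `connectivity_stats`.
#' @param ... Ignored.
#' @return The class-level summary tibble (median +/- scaled MAD).
#' @exportS3Method generics::glance
glance.connectivity_stats <- function(x, ...) x$summary
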