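#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   geom_vline geom_boxplot labs theme_minimal
NULL

#' Plot a coverage sweep
#'
#' Bar plot of lineage-specific orthogroup counts against the minimum
#' species coverage, with the 50%-coverage mark highlighted.
#'
#' @param object A `coverage_sweep`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.coverage_sweep <- function(object, ...) {
  total <- attr(object, "node_species_total")
  ggplot(as_tibble(object), aes(x = .data$min_species, y = .data$n_groups)) +
    geom_col(fill = "grey35") +
    geom_vline(xintercept = ceiling(total / 2), colour = "red",
               linetype = "dashed") +
    labs(x = "minimum species in orthogroup",
         y = "lineage-specific orthogroups",
         title = paste0(attr(object, "node"), " (50% mark: ",
                        attr(object, "mark50"), " orthogroups)")) +
    theme_minimal()
}

#' Plot per-class connectivity distributions
#'
#' Boxplots of node degree by age class.
#'
#' @param object A `connectivity_stats`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.connectivity_stats <- function(object, ...) {
  ggplot(object$per_node, aes(x = .data$class, y = .data$degree)) +
    geom_boxplot() +
    labs(x = "age class", y = "interactions per protein") +
    theme_minimal()
}

#' Plot orthogroup size distribution
#'
#' @param groups Orthogroup tibble (`og_id`, `member_id`, `taxid`).
#' @return A ggplot object.
#' @export
plot_orthogroup_sizes <- function(groups) {
  sizes <- count(groups, .data$og_id, name = "size")
  ggplot(sizes, aes(x = .data$size)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey35") +
    labs(x = "members per orthogroup", y = "orthogroups") +
    theme_minimal()
}
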