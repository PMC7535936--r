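#' Load a protein-protein interaction edge list
#'
#' Keeps edges with combined score at least `min_score` (the 0-1000
#' scale; 400 corresponds to the usual 0.4 confidence threshold),
#' collapses duplicate edges keeping the maximum score, drops
#' self-edges, and attaches age classes to every node.
#'
#' @param edges Path to a TSV (`protein1 protein2 combined_score`, with
#'   header) or a tibble in that layout.
#' @param node_classes Tibble with `protein`, `class` (e.g. `B` for
#'   bilaterian-age, `M` for metazoan-age), or a path to such a TSV.
#' @param min_score Minimum combined score.
#' @return A `ppi_network`: list with `nodes` (tibble: protein, class)
#'   and `edges` (tibble: a, b, score; a < b).
#' @export
load_ppi_edges <- function(edges, node_classes, min_score = 400) {
  if (!is.data.frame(edges)) {
    edges <- as_tibble(utils::read.table(edges, header = TRUE, sep = "\t",
                                         stringsAsFactors = FALSE))
  }
  names(edges)[1:3] <- c("protein1", "protein2", "combined_score")
  if (!is.data.frame(node_classes)) {
    node_classes <- as_tibble(utils::read.table(node_classes, header = TRUE,
                                                sep = "\t",
                                                stringsAsFactors = FALSE))
  }
  names(node_classes)[1:2] <- c("protein", "class")
  ed <- edges |>
    filter(.data$combined_score >= min_score,
           .data$protein1 != .data$protein2) |>
    transmute(a = pmin(.data$protein1, .data$protein2),
              b = pmax(.data$protein1, .data$protein2),
              score = .data$combined_score) |>
    group_by(.data$a, .data$b) |>
    summarise(score = max(.data$score), .groups = "drop")
  miss <- setdiff(unique(c(ed$a, ed$b)), node_classes$protein)
  if (length(miss) > 0) {
    abort(paste0("edge endpoint without age class: ", miss[1]))
  }
  structure(list(nodes = distinct(node_classes, .data$protein, .data$class),
                 edges = ed),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("<ppi_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges\n", sep = "")
  invisible(x)
}

#' Per-node connectivity and class-composition statistics
#'
#' Degrees, per-node bilaterian-partner fractions (B partners divided
#' by degree; NA at degree 0) and per-class median +/- MAD summaries
#' (MAD scaled by the 1.4826 consistency constant).
#'
#' @param net A `ppi_network`.
#' @return A `connectivity_stats` list with `per_node` (tibble:
#'   protein, class, degree, b_fraction) and `summary` (tibble: class,
#'   median_degree, mad_degree, median_b_fraction, mad_b_fraction).
#' @export
connectivity_stats <- function(net) {
  cls <- stats::setNames(net$nodes$class, net$nodes$protein)
  long <- bind_rows(
    tibble(node = net$edges$a, partner = net$edges$b),
    tibble(node = net$edges$b, partner = net$edges$a))
  per <- long |>
    group_by(.data$node) |>
    summarise(degree = n(),
              b_partners = sum(cls[.data$partner] == "B"), .groups = "drop")
  per_node <- net$nodes |>
    rename(node = "protein") |>
    left_join(per, by = "node") |>
    mutate(degree = tidyr::replace_na(.data$degree, 0L),
           b_fraction = ifelse(.data$degree > 0,
                               .data$b_partners / .data$degree, NA_real_)) |>
    select(protein = "node", "class", "degree", "b_fraction")
  summ <- per_node |>
    group_by(.data$class) |>
    summarise(median_degree = stats::median(.data$degree),
              mad_degree = stats::mad(.data$degree),
              median_b_fraction = stats::median(.data$b_fraction, na.rm = TRUE),
              mad_b_fraction = stats::mad(.data$b_fraction, na.rm = TRUE),
              .groups = "drop")
  structure(list(per_node = per_node, summary = summ),
            class = "connectivity_stats")
}

#' Chi-squared test of interaction-class mixing
#'
#' Observed B-B, B-M and M-M edge counts are compared against random
#' endpoint pairing given the class sizes nB and nM (expected
#' proportions nB(nB-1)/2 : nB nM : nM(nM-1)/2, scaled to the edge
#' total); Pearson chi-squared with df = 2.
#'
#' @param net A `ppi_network` containing both classes and at least one
#'   edge.
#' @return List with `result` (one-row stat tibble) and `counts`
#'   (tibble: class, observed, expected).
#' @export
interaction_class_test <- function(net) {
  if (nrow(net$edges) == 0) abort("network has no edges")
  cls <- stats::setNames(net$nodes$class, net$nodes$protein)
  n_b <- sum(net$nodes$class == "B"); n_m <- sum(net$nodes$class == "M")
  if (n_b == 0 || n_m == 0) abort("both age classes must be present")
  ec <- paste0(pmin(cls[net$edges$a], cls[net$edges$b]),
               pmax(cls[net$edges$a], cls[net$edges$b]))
  obs <- c(BB = sum(ec == "BB"), BM = sum(ec == "BM"), MM = sum(ec == "MM"))
  w <- c(BB = n_b * (n_b - 1) / 2, BM = n_b * n_m, MM = n_m * (n_m - 1) / 2)
  expd <- w / sum(w) * sum(obs)
  stat <- sum((obs - expd)^2 / expd)
  list(result = stat_result("chisq_mixing", stat,
                            stats::pchisq(stat, df = 2, lower.tail = FALSE),
                            list(df = 2)),
       counts = tibble(class = names(obs), observed = as.integer(obs),
                       expected = as.numeric(expd)))
}

#' Rank tests between groups of per-node values
#'
#' Two groups: Mann-Whitney U (tie-corrected normal approximation with
#' continuity correction, or the exact distribution for small untied
#' samples), two-sided. Three or more groups: Kruskal-Wallis with tie
#' correction.
#'
#' @param groups Named list of numeric vectors, each non-empty.
#' @param exact Passed to [stats::wilcox.test()] for two groups.
#' @return A one-row result tibble.
#' @export
rank_tests <- function(groups, exact = NULL) {
  if (any(lengths(groups) == 0)) abort("empty group")
  if (length(groups) < 2) abort("need at least two groups")
  if (length(groups) == 2) {
    # ties force the normal approximation; request it explicitly
    if (is.null(exact) && anyDuplicated(c(groups[[1]], groups[[2]])) > 0) {
      exact <- FALSE
    }
    ht <- stats::wilcox.test(groups[[1]], groups[[2]], exact = exact,
                             correct = TRUE)
    stat_result("mann_whitney", unname(ht$statistic), ht$p.value,
                list(U = unname(ht$statistic),
                     n = lengths(groups)))
  } else {
    ht <- stats::kruskal.test(groups)
    stat_result("kruskal_wallis", unname(ht$statistic), ht$p.value,
                list(df = unname(ht$parameter), H = unname(ht$statistic)))
  }
}

#' Induced subnetwork around seed proteins
#'
#' The subnetwork on the seeds plus their direct interaction partners.
#'
#' @param net A `ppi_network`.
#' @param seeds Character vector of node ids, all present in the
#'   network.
#' @return A `ppi_network`.
#' @export
extract_subnetwork <- function(net, seeds) {
  miss <- setdiff(seeds, net$nodes$protein)
  if (length(miss) > 0) abort(paste0("unknown seed protein: ", miss[1]))
  nbrs <- c(net$edges$b[net$edges$a %in% seeds],
            net$edges$a[net$edges$b %in% seeds])
  keep <- union(seeds, nbrs)
  structure(list(nodes = filter(net$nodes, .data$protein %in% keep),
                 edges = filter(net$edges, .data$a %in% keep,
                                .data$b %in% keep)),
            class = "ppi_network")
}
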