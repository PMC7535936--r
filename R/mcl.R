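#' Markov clustering configuration
#'
#' @param inflation Inflation exponent I > 1; larger values give
#'   finer-grained clusters.
#' @param expansion Matrix power used in the expansion step.
#' @param prune_threshold Entries below this are dropped after inflation.
#' @param convergence_tol Iteration stops when the largest entry change
#'   falls below this.
#' @param max_iterations Iteration cap; exceeding it is an error.
#' @return An `mcl_config` list.
#' @export
mcl_config <- function(inflation = 1.5, expansion = 2, prune_threshold = 1e-5,
                       convergence_tol = 1e-6, max_iterations = 200) {
  stopifnot(inflation > 1, expansion >= 2)
  structure(list(inflation = inflation, expansion = as.integer(expansion),
                 prune_threshold = prune_threshold,
                 convergence_tol = convergence_tol,
                 max_iterations = as.integer(max_iterations)),
            class = "mcl_config")
}

normalize_cols <- function(M) {
  cs <- Matrix::colSums(M)
  cs[cs == 0] <- 1
  M %*% Matrix::Diagonal(x = 1 / cs)
}

# Connected components of a symmetric sparse adjacency pattern.
sparse_components <- function(M) {
  n <- nrow(M)
  comp <- rep(NA_integer_, n)
  Ml <- methods::as(M, "TsparseMatrix")
  adj <- split(Ml@j + 1L, Ml@i + 1L)
  k <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    frontier <- s
    comp[s] <- k
    while (length(frontier) > 0) {
      nbrs <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
      nbrs <- nbrs[!is.na(nbrs)]
      nbrs <- nbrs[is.na(comp[nbrs])]
      comp[nbrs] <- k
      frontier <- nbrs
    }
  }
  comp
}

#' Markov clustering of a weighted similarity graph
#'
#' Builds the column-stochastic transition matrix with self-loops (loop
#' weight = each node's maximum incident edge weight), then alternates
#' expansion (matrix power) and inflation (entrywise power, column
#' renormalization) with pruning until the largest entry change drops
#' below the convergence tolerance. Clusters are the connected
#' components of the thresholded limit matrix; singletons are dropped;
#' clusters are ordered by decreasing size, then by lexicographically
#' smallest member, and labelled `OG_<k>` in that order.
#'
#' @param edges Edge tibble from [build_orthomcl_graph()] (columns `a`,
#'   `b`, `weight`), or any tibble of weighted undirected edges.
#' @param config An [mcl_config()].
#' @return Orthogroup tibble with `og_id`, `member_id`, `taxid` (taxid
#'   `NA` when identifiers do not carry one). Attributes
#'   `n_clusters_raw` (cluster count before singleton dropping) and
#'   `iterations` record the run.
#' @export
mcl_cluster <- function(edges, config = mcl_config()) {
  if (nrow(edges) == 0) abort("empty graph")
  nodes <- sort(unique(c(edges$a, edges$b)))
  n <- length(nodes)
  i <- match(edges$a, nodes); j <- match(edges$b, nodes)
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                            x = rep(edges$weight, 2), dims = c(n, n))
  loop <- apply_max_incident(A)
  A <- A + Matrix::Diagonal(n, loop)
  M <- normalize_cols(A)
  converged <- FALSE
  for (it in seq_len(config$max_iterations)) {
    Mexp <- M
    for (e in seq_len(config$expansion - 1L)) Mexp <- Mexp %*% M
    Minf <- Mexp
    Minf@x <- Minf@x^config$inflation
    Minf <- Matrix::drop0(Minf * (abs(Minf) >= config$prune_threshold))
    Minf <- normalize_cols(Minf)
    delta <- max(abs(Minf - M))
    M <- Minf
    if (delta < config$convergence_tol) { converged <- TRUE; break }
  }
  if (!converged) {
    comp0 <- sparse_components(methods::as(A, "nMatrix"))
    biggest <- which.max(tabulate(comp0))
    ex <- nodes[comp0 == biggest][1]
    abort(paste0("MCL did not converge within ", config$max_iterations,
                 " iterations (component containing ", ex, ")"))
  }
  keep <- Matrix::drop0(M * (abs(M) >= config$prune_threshold))
  patt <- methods::as(keep + Matrix::t(keep), "nMatrix")
  comp <- sparse_components(patt)
  n_raw <- length(unique(comp))
  cl <- split(nodes, comp)
  cl <- cl[lengths(cl) >= 2]
  if (length(cl) == 0) {
    out <- tibble(og_id = character(), member_id = character(),
                  taxid = integer())
    return(structure(out, n_clusters_raw = n_raw, iterations = it))
  }
  first_member <- map_chr(cl, ~ sort(.x)[1])
  ord <- order(-lengths(cl), first_member)
  cl <- cl[ord]
  out <- tibble(og_id = rep(sprintf("OG_%d", seq_along(cl)), lengths(cl)),
                member_id = unlist(map(cl, sort), use.names = FALSE))
  out$taxid <- suppressWarnings(taxid_of(out$member_id))
  structure(out, n_clusters_raw = n_raw, iterations = it)
}

apply_max_incident <- function(A) {
  # maximum incident weight per node (0 for isolated nodes)
  m <- methods::as(A, "TsparseMatrix")
  loop <- rep(0, nrow(A))
  if (length(m@x) > 0) {
    agg <- tapply(m@x, m@i + 1L, max)
    loop[as.integer(names(agg))] <- agg
  }
  loop
}

#' Keep orthogroups with broad species sampling
#'
#' @param groups Orthogroup tibble (`og_id`, `member_id`, `taxid`).
#' @param min_species Minimum number of distinct species.
#' @return Filtered orthogroup tibble.
#' @export
select_orthogroups <- function(groups, min_species = 10) {
  groups |>
    group_by(.data$og_id) |>
    filter(n_distinct(.data$taxid) >= min_species) |>
    ungroup()
}

#' Write orthogroups in the classic groups-file dialect
#'
#' One line per group: `OG_17: 9606|ncbi|P1 7227|orf|Q2 ...`.
#'
#' @param groups Orthogroup tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_groups_file <- function(groups, path) {
  lines <- groups |>
    group_by(.data$og_id) |>
    summarise(line = paste0(.data$og_id[1], ": ",
                            paste(sort(.data$member_id), collapse = " ")),
              .groups = "drop")
  ord <- order(as.integer(sub("OG_", "", lines$og_id)))
  writeLines(lines$line[ord], path)
  invisible(path)
}

#' Read a groups file back into an orthogroup tibble
#'
#' @param path Path to a groups file written by [write_groups_file()].
#' @return Orthogroup tibble (`og_id`, `member_id`, `taxid`).
#' @export
read_groups_file <- function(path) {
  lines <- readLines(path)
  parts <- str_split(lines, ":\\s+", n = 2)
  out <- tibble(og_id = map_chr(parts, 1),
                members = map(parts, ~ strsplit(.x[2], " ")[[1]])) |>
    tidyr::unnest(cols = "members") |>
    rename(member_id = "members")
  out$taxid <- suppressWarnings(taxid_of(out$member_id))
  out
}
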