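#' Construct a taxonomy table
#'
#' A taxonomy table is a tibble with columns `taxid`, `parent` and `name`.
#' Exactly one root is required, marked by `parent == taxid`. Clade
#' membership is resolved by walking ancestor pointers.
#'
#' @param df Data frame with columns `taxid`, `parent`, `name`.
#' @return A validated `taxonomy_tbl`.
#' @export
taxonomy_table <- function(df) {
  df <- as_tibble(df)[, c("taxid", "parent", "name")]
  df$taxid <- as.integer(df$taxid)
  df$parent <- as.integer(df$parent)
  df$name <- as.character(df$name)
  roots <- df$taxid[df$taxid == df$parent]
  if (length(roots) != 1) abort("taxonomy must have exactly one root (parent == taxid)")
  if (anyDuplicated(df$taxid)) abort("duplicate taxids in taxonomy")
  if (!all(df$parent %in% df$taxid)) abort("dangling parent pointers in taxonomy")
  # every lineage must terminate at the root (no cycles)
  idx <- match(df$parent, df$taxid)
  for (i in seq_len(nrow(df))) {
    seen <- integer(0)
    j <- i
    while (df$taxid[j] != df$parent[j]) {
      if (j %in% seen) abort("cycle detected in taxonomy")
      seen <- c(seen, j)
      j <- idx[j]
    }
  }
  structure(df, class = c("taxonomy_tbl", class(df)))
}

#' Read a simplified 3-column taxonomy TSV
#'
#' Columns: taxid, parent taxid, name. This is the canonical fixture
#' format; [read_taxdump()] reads the NCBI dump dialect.
#'
#' @param path Path to a tab-separated file (no header).
#' @return A `taxonomy_tbl`.
#' @export
read_taxonomy_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          col.names = c("taxid", "parent", "name"),
                          stringsAsFactors = FALSE)
  taxonomy_table(df)
}

#' Read NCBI taxdump nodes.dmp / names.dmp
#'
#' Only taxid, parent and the scientific name are used.
#'
#' @param nodes_path Path to `nodes.dmp`.
#' @param names_path Path to `names.dmp`.
#' @return A `taxonomy_tbl`.
#' @export
read_taxdump <- function(nodes_path, names_path) {
  nodes <- utils::read.table(nodes_path, sep = "|", header = FALSE, quote = "",
                             strip.white = TRUE, stringsAsFactors = FALSE,
                             comment.char = "")
  nm <- utils::read.table(names_path, sep = "|", header = FALSE, quote = "",
                          strip.white = TRUE, stringsAsFactors = FALSE,
                          comment.char = "")
  sci <- nm[nm[[4]] == "scientific name", ]
  df <- tibble(taxid = as.integer(nodes[[1]]),
               parent = as.integer(nodes[[2]]),
               name = sci[[2]][match(nodes[[1]], sci[[1]])])
  taxonomy_table(df)
}

tax_index <- function(taxonomy) match(taxonomy$parent, taxonomy$taxid)

#' Ancestor path of a taxid (self first, root last)
#'
#' @param taxid A single taxid present in `taxonomy`.
#' @param taxonomy A `taxonomy_tbl`.
#' @return Integer vector of taxids from `taxid` up to the root.
#' @export
ancestor_path <- function(taxid, taxonomy) {
  i <- match(taxid, taxonomy$taxid)
  if (is.na(i)) abort(paste0("unknown taxid: ", taxid))
  idx <- tax_index(taxonomy)
  path <- integer(0)
  while (TRUE) {
    path <- c(path, taxonomy$taxid[i])
    if (taxonomy$taxid[i] == taxonomy$parent[i]) break
    i <- idx[i]
  }
  path
}

#' Last common ancestor of a set of taxids
#'
#' The deepest taxonomy node ancestral to (or equal to) every input
#' taxid. A singleton input returns itself.
#'
#' @param taxids Integer vector of taxids, all present in `taxonomy`.
#' @param taxonomy A `taxonomy_tbl`.
#' @return A single taxid.
#' @export
last_common_ancestor <- function(taxids, taxonomy) {
  taxids <- unique(as.integer(taxids))
  if (length(taxids) == 0) abort("empty taxid set")
  miss <- setdiff(taxids, taxonomy$taxid)
  if (length(miss) > 0) abort(paste0("unknown taxid: ", miss[1]))
  path <- ancestor_path(taxids[1], taxonomy)
  for (t in taxids[-1]) {
    path <- path[path %in% ancestor_path(t, taxonomy)]
  }
  path[1]
}

#' Taxids belonging to a named clade (the clade node and all descendants)
#'
#' @param taxonomy A `taxonomy_tbl`.
#' @param label Clade name as it appears in the taxonomy `name` column.
#' @return Integer vector of member taxids.
#' @export
clade_taxids <- function(taxonomy, label) {
  root <- taxonomy$taxid[taxonomy$name == label]
  if (length(root) != 1) abort(paste0("clade label not found (or ambiguous): ", label))
  members <- root
  frontier <- root
  while (length(frontier) > 0) {
    kids <- taxonomy$taxid[taxonomy$parent %in% frontier & taxonomy$taxid != taxonomy$parent]
    kids <- setdiff(kids, members)
    members <- c(members, kids)
    frontier <- kids
  }
  members
}

#' Test clade membership of taxids
#'
#' @param taxids Integer vector.
#' @param label Clade name.
#' @param taxonomy A `taxonomy_tbl`.
#' @return Logical vector.
#' @export
in_clade <- function(taxids, label, taxonomy) {
  taxids %in% clade_taxids(taxonomy, label)
}
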