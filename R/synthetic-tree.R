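# Fixed backbone of the consensus animal phylogeny used by the
# synthetic-data generator: each row is child -> parent. Starred
# comments mark "slots", terminal clades that receive species leaves.
.backbone <- function() {
  edges <- c(
    "Fungi",         "Opisthokonta",   # *
    "Metazoa",       "Opisthokonta",
    "Porifera",      "Metazoa",        # *
    "ParaHoxozoa",   "Metazoa",
    "Ctenophora",    "ParaHoxozoa",    # *
    "Eumetazoa",     "ParaHoxozoa",
    "Cnidaria",      "Eumetazoa",      # *
    "Bilateria",     "Eumetazoa",
    "Deuterostomia", "Bilateria",
    "Protostomia",   "Bilateria",
    "Ambulacraria",  "Deuterostomia",  # *
    "Vertebrata",    "Deuterostomia",
    "Cyclostomata",  "Vertebrata",     # *
    "Gnathostomata", "Vertebrata",     # *
    "Ecdysozoa",     "Protostomia",
    "Lophotrochozoa","Protostomia",    # *
    "Nematoda",      "Ecdysozoa",      # *
    "Arthropoda",    "Ecdysozoa",
    "Chelicerata",   "Arthropoda",     # *
    "Mandibulata",   "Arthropoda",
    "Myriapoda",     "Mandibulata",    # *
    "Pancrustacea",  "Mandibulata",
    "Crustacea",     "Pancrustacea",   # *
    "Insecta",       "Pancrustacea")   # *
  matrix(edges, ncol = 2, byrow = TRUE, dimnames = list(NULL, c("child", "parent")))
}

.slots <- c("Fungi", "Porifera", "Ctenophora", "Cnidaria", "Ambulacraria",
            "Cyclostomata", "Gnathostomata", "Lophotrochozoa", "Nematoda",
            "Chelicerata", "Myriapoda", "Crustacea", "Insecta")

# Default apportionment weights per slot, reflecting the taxonomic skew
# of real multi-species protein collections (vertebrates and insects
# over-represented, lophotrochozoans and non-bilaterians sparser).
.slot_weights <- c(Fungi = 1, Porifera = 1, Ctenophora = 1, Cnidaria = 1,
                   Ambulacraria = 2, Cyclostomata = 1, Gnathostomata = 5,
                   Lophotrochozoa = 4, Nematoda = 2, Chelicerata = 2,
                   Myriapoda = 1, Crustacea = 1, Insecta = 2)

slots_below <- function(label) {
  bb <- .backbone()
  members <- label
  frontier <- label
  while (length(frontier) > 0) {
    kids <- bb[bb[, "parent"] %in% frontier, "child"]
    members <- c(members, kids)
    frontier <- kids
  }
  intersect(.slots, members)
}

# Largest-remainder apportionment of n leaves over slots by weight.
apportion <- function(n, slots) {
  w <- .slot_weights[slots]
  q <- n * w / sum(w)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), slots)
}

#' Build a labelled species-tree fixture
#'
#' Constructs a species tree on a fixed consensus backbone of animal and
#' outgroup clades, attaching the requested number of species leaves
#' under each named clade. Requests naming an internal clade (e.g.
#' `Bilateria = 20`) are apportioned over that clade's terminal
#' sub-clades by largest-remainder on realistic weights; requests naming
#' a terminal clade place all leaves there.
#'
#' @param n_species_per_clade Named integer vector, clade name -> species
#'   count. Total must be at least 1.
#' @param seed Integer seed (the fixture is deterministic given the
#'   request; the seed names the fixture's random substream for
#'   downstream use).
#' @return A `species_tree`: list with `nodes` (tibble: taxid, parent,
#'   name, is_leaf), `clade_labels` (name -> taxid), `taxonomy`
#'   (a [taxonomy_table()] over all nodes) and `seed`.
#' @export
build_species_fixture <- function(n_species_per_clade, seed = 1) {
  if (sum(n_species_per_clade) < 1) abort("at least one species is required")
  bb <- .backbone()
  internal_names <- c("Opisthokonta", unname(bb[, "child"]))
  # resolve requests to per-slot counts
  counts <- stats::setNames(integer(length(.slots)), .slots)
  for (nm in names(n_species_per_clade)) {
    n <- n_species_per_clade[[nm]]
    if (n == 0) next
    if (!nm %in% internal_names) abort(paste0("unknown clade: ", nm))
    sl <- slots_below(nm)
    counts[sl] <- counts[sl] + apportion(n, sl)
  }
  nodes <- tibble(
    taxid = seq_along(internal_names),
    parent = c(1L, match(bb[, "parent"], internal_names) ),
    name = internal_names,
    is_leaf = FALSE)
  next_taxid <- 1000L
  leaf_rows <- list()
  for (sl in .slots) {
    k <- counts[[sl]]
    if (k == 0) next
    slot_id <- nodes$taxid[nodes$name == sl]
    leaf_rows[[sl]] <- tibble(
      taxid = next_taxid + seq_len(k) - 1L,
      parent = slot_id,
      name = paste0(tolower(sl), "_sp", seq_len(k)),
      is_leaf = TRUE)
    next_taxid <- next_taxid + k
  }
  nodes <- bind_rows(nodes, bind_rows(leaf_rows))
  structure(list(
    nodes = nodes,
    clade_labels = stats::setNames(seq_along(internal_names), internal_names),
    taxonomy = taxonomy_table(nodes[, c("taxid", "parent", "name")]),
    seed = as.integer(seed)),
    class = "species_tree")
}

#' @export
print.species_tree <- function(x, ...) {
  cat("<species_tree> ", sum(x$nodes$is_leaf), " species, ",
      sum(!x$nodes$is_leaf), " internal nodes\n", sep = "")
  invisible(x)
}

tree_leaves <- function(tree) tree$nodes$taxid[tree$nodes$is_leaf]

leaves_below <- function(tree, node_taxid) {
  intersect(clade_taxids(tree$taxonomy, tree$nodes$name[match(node_taxid, tree$nodes$taxid)]),
            tree_leaves(tree))
}

tree_children <- function(tree, node_taxid) {
  tree$nodes$taxid[tree$nodes$parent == node_taxid & tree$nodes$taxid != node_taxid]
}
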