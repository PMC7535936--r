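test_that("LCA handles singletons, fixtures and random subsets like the oracle", {
  tr <- study_tree(7)
  tax <- tr$taxonomy
  leaves <- tr$nodes$taxid[tr$nodes$is_leaf]
  expect_equal(last_common_ancestor(leaves[1], tax), leaves[1])
  d <- leaves[in_clade(leaves, "Deuterostomia", tax)][1]
  e <- leaves[in_clade(leaves, "Ecdysozoa", tax)][1]
  lca <- last_common_ancestor(c(d, e), tax)
  expect_equal(tax$name[match(lca, tax$taxid)], "Bilateria")
  set.seed(99)
  for (i in 1:100) {
    sub <- sample(leaves, sample(2:6, 1))
    expect_equal(last_common_ancestor(sub, tax), naive_lca(sub, tax))
  }
  expect_error(last_common_ancestor(c(d, 999999L), tax), "999999")
})

test_that("LCA is monotone under set growth", {
  tr <- study_tree(7)
  tax <- tr$taxonomy
  leaves <- tr$nodes$taxid[tr$nodes$is_leaf]
  depth <- function(t) length(ancestor_path(t, tax))
  set.seed(5)
  for (i in 1:50) {
    trip <- sample(leaves, 3)
    l2 <- last_common_ancestor(trip[1:2], tax)
    l3 <- last_common_ancestor(trip, tax)
    expect_lte(depth(l3), depth(l2))
  }
})

test_that("taxonomy readers accept both the simple TSV and the dump dialect", {
  tr <- study_tree(7)
  tsv <- tempfile(fileext = ".tsv")
  utils::write.table(tr$taxonomy, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  rt <- read_taxonomy_tsv(tsv)
  expect_equal(as.data.frame(rt), as.data.frame(tr$taxonomy))
  nodes_dmp <- tempfile(fileext = ".dmp")
  names_dmp <- tempfile(fileext = ".dmp")
  writeLines(paste(tr$taxonomy$taxid, tr$taxonomy$parent, "clade", "",
                   sep = "\t|\t"), nodes_dmp)
  writeLines(paste(tr$taxonomy$taxid, tr$taxonomy$name, "",
                   "scientific name", sep = "\t|\t"), names_dmp)
  dump <- read_taxdump(nodes_dmp, names_dmp)
  expect_equal(dump$parent, tr$taxonomy$parent)
  expect_equal(dump$name, tr$taxonomy$name)
  expect_error(taxonomy_table(data.frame(taxid = 1:2, parent = 2:1,
                                         name = c("a", "b"))),
               "exactly one root")
})

test_that("orthogroup composition counts species once per clade", {
  tr <- study_tree(7)
  tax <- tr$taxonomy
  leaves <- tr$nodes$taxid[tr$nodes$is_leaf]
  deut <- leaves[in_clade(leaves, "Deuterostomia", tax)]
  # three sequences from one deuterostome species count once
  g1 <- tibble::tibble(og_id = "OG_1",
                       member_id = sprintf("%d|ncbi|p%d", deut[1], 1:3),
                       taxid = deut[1])
  comp <- orthogroup_composition(g1, tax)
  expect_equal(comp$Deuterostomia, 1)
  expect_equal(comp$total_species, 1)
  # spanning group: per-clade species counts as constructed
  ecd <- leaves[in_clade(leaves, "Ecdysozoa", tax)]
  g2 <- tibble::tibble(og_id = "OG_2",
                       member_id = sprintf("%d|ncbi|q%d", c(deut, ecd),
                                           seq_along(c(deut, ecd))),
                       taxid = c(deut, ecd))
  c2 <- orthogroup_composition(g2, tax)
  expect_equal(c2$Deuterostomia, length(deut))
  expect_equal(c2$Ecdysozoa, length(ecd))
  expect_equal(c2$Lophotrochozoa, 0)
  expect_equal(c2[["non-Bilateria"]], 0)
  # row order of members is irrelevant
  set.seed(3)
  c3 <- orthogroup_composition(g2[sample.int(nrow(g2)), ], tax)
  expect_equal(c3, c2)
  expect_error(orthogroup_composition(
    tibble::tibble(og_id = "OG_3", member_id = "5|ncbi|x", taxid = 424242L),
    tax), "424242")
})

test_that("lineage rules reproduce the printed decision tables", {
  mk <- function(D = 0, L = 0, E = 0, nonB = 0, Fu = 0, Cn = 0, Ct = 0,
                 Che = 0, Cru = 0, Myr = 0, Ins = 0, Gna = 0, Bil = NULL,
                 Met = NULL, Art = NULL, Ver = NULL) {
    bil <- Bil %||% (D + L + E)
    met <- Met %||% (bil + nonB)
    tibble::tibble(og_id = "OG_x", total_species = met + Fu,
                   Deuterostomia = D, Lophotrochozoa = L, Ecdysozoa = E,
                   "non-Bilateria" = nonB, Fungi = Fu, Cnidaria = Cn,
                   Ctenophora = Ct, Chelicerata = Che, Crustacea = Cru,
                   Myriapoda = Myr, Insecta = Ins, Gnathostomata = Gna,
                   Bilateria = bil, Metazoa = met,
                   Arthropoda = Art %||% (Che + Cru + Myr + Ins),
                   Vertebrata = Ver %||% Gna)
  }
  expect_true(apply_lineage_filter(mk(D = 7, L = 4, E = 4), "bilaterian"))
  expect_true(apply_lineage_filter(mk(D = 7, L = 0, E = 5), "bilaterian"))
  expect_false(apply_lineage_filter(mk(D = 7, L = 4, E = 4, nonB = 1),
                                    "bilaterian"))
  expect_false(apply_lineage_filter(mk(D = 7, L = 3, E = 4), "bilaterian"))
  expect_false(apply_lineage_filter(mk(D = 6, L = 4, E = 4), "bilaterian"))
  # arthropod rule: all arthropod classes, no outsiders
  art <- mk(E = 9, Che = 2, Cru = 0, Myr = 1, Ins = 5, Art = 9, Bil = 9)
  expect_true(apply_lineage_filter(art, "arthropod"))
  art_bad <- mk(E = 9, D = 1, Che = 2, Cru = 0, Myr = 1, Ins = 5, Art = 9,
                Bil = 10)
  expect_false(apply_lineage_filter(art_bad, "arthropod"))
  # vertebrate rule
  expect_true(apply_lineage_filter(
    mk(D = 40, Gna = 40, Ver = 40, Bil = 40), "vertebrate"))
  expect_false(apply_lineage_filter(
    mk(D = 45, Gna = 39, Ver = 45, Bil = 45), "vertebrate"))
  # opisthokont / metazoan / eumetazoan rules as printed
  op <- mk(D = 15, L = 5, E = 10, nonB = 10, Fu = 20)
  expect_true(apply_lineage_filter(op, "opisthokont"))
  expect_false(apply_lineage_filter(op, "metazoan"))
  met <- mk(D = 15, L = 5, E = 10, nonB = 10, Fu = 0)
  expect_true(apply_lineage_filter(met, "metazoan"))
  eu <- mk(D = 15, L = 5, E = 10, nonB = 5, Cn = 3, Ct = 2)
  expect_true(apply_lineage_filter(eu, "eumetazoan"))
  expect_false(apply_lineage_filter(mk(D = 15, L = 5, E = 10, nonB = 5,
                                       Cn = 3, Ct = 3), "eumetazoan"))
  expect_error(apply_lineage_filter(op, "nope"), "unknown rule")
})

test_that("composition counts agree with a ground-truth recount", {
  sm <- small_sim()
  truth <- sm$sim$truth
  groups <- dplyr::transmute(truth, og_id = family_id,
                             member_id = member_id, taxid = taxid)
  comp <- orthogroup_composition(groups, sm$tree$taxonomy)
  bil <- clade_taxids(sm$tree$taxonomy, "Bilateria")
  for (i in seq_len(nrow(comp))) {
    tx <- unique(groups$taxid[groups$og_id == comp$og_id[i]])
    expect_equal(comp$Bilateria[i], sum(tx %in% bil))
    expect_equal(comp$total_species[i], length(tx))
  }
})

test_that("coverage sweep matches a brute-force recount and is monotone", {
  tr <- study_tree(7)
  tax <- tr$taxonomy
  leaves <- tr$nodes$taxid[tr$nodes$is_leaf]
  bil <- leaves[in_clade(leaves, "Bilateria", tax)]
  other <- setdiff(leaves, bil)
  set.seed(21)
  groups <- dplyr::bind_rows(lapply(1:30, function(g) {
    inside <- stats::runif(1) < 0.7
    tx <- if (inside) sample(bil, sample(2:length(bil), 1))
          else sample(leaves, sample(2:10, 1))
    tibble::tibble(og_id = sprintf("OG_%d", g),
                   member_id = sprintf("%d|ncbi|g%d_%d", tx, g, seq_along(tx)),
                   taxid = tx)
  }))
  sw <- coverage_sweep(groups, "Bilateria", tax,
                       node_species_total = length(bil))
  expect_true(all(diff(sw$n_groups) <= 0))
  # brute force
  for (s in c(1, 5, 10, ceiling(length(bil) / 2))) {
    n <- sum(vapply(split(groups$taxid, groups$og_id), function(tx) {
      all(tx %in% bil) && dplyr::n_distinct(tx) >= s
    }, logical(1)))
    expect_equal(sw$n_groups[sw$min_species == s], n)
  }
  expect_equal(attr(sw, "mark50"),
               sw$n_groups[sw$min_species == ceiling(length(bil) / 2)])
  # fully covered specific groups give a constant table
  full <- tibble::tibble(og_id = rep(c("OG_a", "OG_b"), each = length(bil)),
                         member_id = sprintf("%d|ncbi|f%d", rep(bil, 2),
                                             seq_len(2 * length(bil))),
                         taxid = rep(bil, 2))
  swf <- coverage_sweep(full, "Bilateria", tax,
                        node_species_total = length(bil))
  expect_true(all(swf$n_groups == 2))
})
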