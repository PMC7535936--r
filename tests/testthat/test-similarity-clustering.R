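test_that("identical sequences give reciprocal full-coverage hits", {
  s <- random_protein(100, seed = 5)
  recs <- tibble::tibble(id = c("1|ncbi|a", "2|ncbi|b"), residues = c(s, s))
  hits <- all_vs_all_similarity(recs, aligner_config(), 1e-5)
  expect_equal(nrow(hits), 2)
  expect_setequal(hits$query, recs$id)
  expect_equal(hits$percent_match, c(1, 1))
  # E-value matches the Karlin-Altschul formula by hand
  cfg <- aligner_config()
  n_db <- sum(nchar(recs$residues))
  expect_equal(hits$e_value,
               cfg$K * 100 * n_db * exp(-cfg$lambda * hits$score))
})

test_that("unrelated random sequences rarely reach E < 1e-5", {
  hitless <- vapply(1:100, function(s) {
    set.seed(3000 + s)
    recs <- tibble::tibble(id = c("1|ncbi|a", "2|ncbi|b"),
                           residues = c(random_protein(60), random_protein(60)))
    nrow(all_vs_all_similarity(recs, aligner_config(kmer_prescreen = FALSE),
                               1e-5)) == 0
  }, logical(1))
  expect_gte(sum(hitless), 95)
})

test_that("graph construction classifies orthologs, inparalogs, coorthologs", {
  # two species, one gene each: single ortholog edge, weight 1
  s <- random_protein(120, seed = 9)
  two <- tibble::tibble(id = c("1|ncbi|a", "2|ncbi|b"),
                        residues = c(s, mutate_protein(s, 0.05, seed = 1)))
  hits <- all_vs_all_similarity(two, aligner_config(), 1e-5)
  edges <- build_orthomcl_graph(hits)
  expect_equal(nrow(edges), 1)
  expect_equal(edges$edge_class, "ortholog")
  expect_equal(edges$weight, 1.0)

  # one species, two near-identical genes, no cross-species partners
  one_sp <- tibble::tibble(id = c("1|ncbi|a", "1|ncbi|a2"),
                           residues = c(s, mutate_protein(s, 0.02, seed = 2)))
  e2 <- build_orthomcl_graph(all_vs_all_similarity(one_sp, aligner_config(),
                                                   1e-5))
  expect_equal(e2$edge_class, "inparalog")

  # three species, duplicate in species 1: the duplicate joins through
  # inparalogy and becomes co-ortholog to the other species' genes
  a1 <- s
  a2 <- mutate_protein(s, 0.02, seed = 3)       # recent in-paralog of a1
  b1 <- mutate_protein(s, 0.10, seed = 4)
  c1 <- mutate_protein(s, 0.12, seed = 5)
  five <- tibble::tibble(
    id = c("1|ncbi|a1", "1|ncbi|a2", "2|ncbi|b1", "3|ncbi|c1"),
    residues = c(a1, a2, b1, c1))
  h5 <- all_vs_all_similarity(five, aligner_config(), 1e-5)
  e5 <- build_orthomcl_graph(h5)
  cls <- stats::setNames(e5$edge_class, paste(e5$a, e5$b))
  expect_equal(unname(cls["1|ncbi|a1 1|ncbi|a2"]), "inparalog")
  expect_equal(unname(cls["2|ncbi|b1 3|ncbi|c1"]), "ortholog")
  # a1 vs b1/c1 are orthologs (a1 is the closer copy), a2 co-orthologs
  expect_equal(unname(cls["1|ncbi|a1 2|ncbi|b1"]), "ortholog")
  expect_equal(unname(cls["1|ncbi|a1 3|ncbi|c1"]), "ortholog")
  expect_equal(unname(cls["1|ncbi|a2 2|ncbi|b1"]), "coortholog")
  expect_equal(unname(cls["1|ncbi|a2 3|ncbi|c1"]), "coortholog")
  # oracle precondition: a1 really is both species' best hit in species 1
  best_in_1 <- h5 |>
    dplyr::filter(query %in% c("2|ncbi|b1", "3|ncbi|c1"),
                  startsWith(subject, "1|")) |>
    dplyr::group_by(query) |>
    dplyr::slice_min(e_value, n = 1, with_ties = FALSE)
  expect_true(all(best_in_1$subject == "1|ncbi|a1"))
})

test_that("graph construction is invariant to hit order", {
  sm <- small_sim()
  prot <- sm$sim$proteins[1:60, ]
  hits <- all_vs_all_similarity(prot, aligner_config(), 1e-5)
  e1 <- build_orthomcl_graph(hits)
  set.seed(1)
  e2 <- build_orthomcl_graph(hits[sample.int(nrow(hits)), ])
  expect_identical(e1, e2)
  g1 <- mcl_cluster(e1)
  g2 <- mcl_cluster(e2)
  expect_identical(tibble::as_tibble(g1), tibble::as_tibble(g2))
})

test_that("MCL separates disjoint cliques and weakly bridged cliques", {
  mk_clique <- function(ids, w = 1) {
    cmb <- t(utils::combn(ids, 2))
    tibble::tibble(a = cmb[, 1], b = cmb[, 2], weight = w)
  }
  disjoint <- rbind(mk_clique(paste0("x", 1:4)), mk_clique(paste0("y", 1:4)))
  g <- mcl_cluster(disjoint)
  expect_equal(dplyr::n_distinct(g$og_id), 2)
  expect_true(all(table(g$og_id) == 4))
  barbell <- rbind(mk_clique(sprintf("a%02d", 1:6)),
                   mk_clique(sprintf("b%02d", 1:6)),
                   tibble::tibble(a = "a01", b = "b01", weight = 0.1))
  gb <- mcl_cluster(barbell, mcl_config(inflation = 1.5))
  expect_equal(dplyr::n_distinct(gb$og_id), 2)
  # agreement with the dense-matrix oracle
  want <- dense_mcl_partition(barbell, inflation = 1.5)
  got <- stats::setNames(as.integer(factor(gb$og_id)), gb$member_id)
  expect_true(same_partition(got, want[names(got)]))
})

test_that("higher inflation refines clusters and respects components", {
  for (s in 1:5) {
    set.seed(s)
    n <- 18
    cmb <- t(utils::combn(n, 2))
    keep <- stats::runif(nrow(cmb)) < 0.25
    edges <- tibble::tibble(a = sprintf("n%02d", cmb[keep, 1]),
                            b = sprintf("n%02d", cmb[keep, 2]),
                            weight = stats::runif(sum(keep), 0.2, 1))
    counts <- vapply(c(1.2, 1.5, 2, 4, 6), function(I) {
      attr(mcl_cluster(edges, mcl_config(inflation = I)), "n_clusters_raw")
    }, numeric(1))
    expect_true(all(diff(counts) >= 0))
    # clusters never span connected components
    g <- mcl_cluster(edges, mcl_config(inflation = 2))
    comp <- dense_mcl_partition(edges, inflation = 2)
    # oracle partition at same inflation shares component structure; a
    # direct check: every cluster's members are mutually reachable
    adj <- split(c(edges$b, edges$a), c(edges$a, edges$b))
    reachable <- function(from) {
      seen <- from
      frontier <- from
      while (length(frontier) > 0) {
        nxt <- setdiff(unique(unlist(adj[frontier])), seen)
        seen <- c(seen, nxt)
        frontier <- nxt
      }
      seen
    }
    for (og in unique(g$og_id)) {
      mem <- g$member_id[g$og_id == og]
      expect_true(all(mem %in% reachable(mem[1])))
    }
  }
})

test_that("MCL output partitions the clustered node set", {
  sm <- small_sim()
  hits <- all_vs_all_similarity(sm$sim$proteins, aligner_config(), 1e-5)
  edges <- build_orthomcl_graph(hits)
  g <- mcl_cluster(edges)
  expect_false(anyDuplicated(g$member_id) > 0)
  expect_true(all(g$member_id %in% c(edges$a, edges$b)))
})

test_that("orthogroup selection enforces the species minimum", {
  g <- tibble::tibble(
    og_id = rep(c("OG_1", "OG_2"), c(12, 9)),
    member_id = c(sprintf("%d|ncbi|x%d", 1:12, 1:12),
                  sprintf("%d|ncbi|y%d", c(1:9), 1:9)),
    taxid = c(1:12, 1:9))
  kept <- select_orthogroups(g, 10)
  expect_setequal(unique(kept$og_id), "OG_1")
  expect_identical(select_orthogroups(g, 1), g)
  # simulated groups: selected count equals ground-truth recount
  sm <- small_sim()
  hits <- all_vs_all_similarity(sm$sim$proteins, aligner_config(), 1e-5)
  groups <- mcl_cluster(build_orthomcl_graph(hits))
  for (ms in c(5, 10)) {
    kept <- select_orthogroups(groups, ms)
    recount <- groups |>
      dplyr::group_by(og_id) |>
      dplyr::summarise(n = dplyr::n_distinct(taxid)) |>
      dplyr::filter(n >= ms)
    expect_setequal(unique(kept$og_id), recount$og_id)
  }
})

test_that("clustering recovers simulated families nearly perfectly", {
  sm <- small_sim()
  hits <- all_vs_all_similarity(sm$sim$proteins, aligner_config(), 1e-5)
  groups <- mcl_cluster(build_orthomcl_graph(hits))
  truth_of <- stats::setNames(sm$sim$truth$family_id, sm$sim$truth$member_id)
  common <- intersect(names(truth_of), groups$member_id)
  ari <- rand_ari(truth_of[common],
                  groups$og_id[match(common, groups$member_id)])
  expect_gte(ari, 0.9)
})

test_that("external queries map only under the printed criteria", {
  sm <- small_sim()
  prot <- sm$sim$proteins
  truth <- sm$sim$truth
  groups <- dplyr::transmute(truth, og_id = family_id,
                             member_id = member_id, taxid = taxid)
  big_og <- names(sort(table(dplyr::distinct(groups, og_id, taxid)$og_id),
                       decreasing = TRUE))[1]
  member <- groups$member_id[groups$og_id == big_og][1]
  n_sp <- dplyr::n_distinct(groups$taxid[groups$og_id == big_og])
  q <- tibble::tibble(id = "9606|ncbi|q1",
                      residues = prot$residues[prot$id == member])
  mapped <- map_external_queries(q, prot, groups, min_species = n_sp)
  expect_equal(mapped$og_id, big_og)
  # same query against a species floor it cannot meet
  unmapped <- map_external_queries(q, prot, groups, min_species = n_sp + 1)
  expect_true(is.na(unmapped$og_id))
  expect_match(unmapped$reason, "too few species")
  # high identity over too short an alignment fails the length rule
  q2 <- tibble::tibble(id = "9606|ncbi|q2",
                       residues = substr(prot$residues[prot$id == member], 1, 90))
  short <- map_external_queries(q2, prot, groups, min_len = 100,
                                min_species = 1)
  expect_true(is.na(short$og_id))
  expect_match(short$reason, "length")
})
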