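test_that("load_taxonomy reads and validates node tables", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tparent\trank\tname",
               "1\t1\tgenus\tGen",
               "2\t1\tspecies\tSpA",
               "3\t1\tspecies\tSpB"), path)
  tr <- load_taxonomy(path)
  expect_s3_class(tr, "taxonomy_tree")
  expect_equal(nrow(tr$nodes), 3L)
  expect_equal(tree_leaves(tr), c(2L, 3L))

  writeLines(c("id\tparent\trank\tname",
               "1\t1\tgenus\tGen",
               "2\t9\tspecies\tOrphan"), path)
  expect_error(load_taxonomy(path), "orphan")

  expect_error(taxonomy_tree(data.frame(
    id = c(1, 1), parent = c(NA, 1), rank = c("genus", "species"),
    name = c("a", "b"))), "duplicate")
  expect_error(taxonomy_tree(data.frame(
    id = c(1, 2), parent = c(2, 1), rank = c("genus", "species"),
    name = c("a", "b"))), "root")
})

test_that("generated fixture taxonomy has the configured shape", {
  fix <- flat_fixture()
  lv <- tree_leaves(fix$tree)
  euk <- lv[lv >= 500 & lv < 600]
  expect_length(euk, 16L)
  nodes <- fix$tree$nodes
  expect_equal(sum(nodes$rank == "genus"), 4L)
  expect_equal(sum(nodes$rank == "family"), 2L)
})

test_that("taxonomic distance is the rank of the lowest ranked common ancestor", {
  tr <- tiny_tree()
  expect_identical(taxonomic_distance(tr, 21, 21), 0L)
  expect_identical(taxonomic_distance(tr, 21, 22), 1L)  # congeners
  expect_identical(taxonomic_distance(tr, 21, 23), 2L)  # same family
  expect_identical(taxonomic_distance(tr, 21, 25), 3L)  # same order
  # symmetry, non-negativity over all leaf pairs
  lv <- tree_leaves(tr)
  for (a in lv) for (b in lv) {
    d <- taxonomic_distance(tr, a, b)
    expect_gte(d, 0L)
    expect_identical(d, taxonomic_distance(tr, b, a))
  }
  expect_error(taxonomic_distance(tr, 21, 999), "not in tree")
})

test_that("leaves sharing only the superkingdom (or an unranked root) are at distance 7", {
  fix <- default_fixture()
  expect_identical(taxonomic_distance(fix$tree, 501L, 601L), 7L)
  expect_identical(taxonomic_distance(fix$tree, 601L, 602L), 7L)
})

test_that("traversal order sorts by distance and shuffles within classes reproducibly", {
  tr <- tiny_tree()
  ord <- traversal_order(tr, 21, rng_seed = 3)
  expect_setequal(ord, c(22, 23, 24, 25, 26))
  d <- vapply(ord, function(x) taxonomic_distance(tr, 21, x), integer(1))
  expect_false(is.unsorted(d))           # increasing distance
  expect_identical(ord[1], 22L)          # lone distance-1 leaf first
  expect_true(all(ord[4:5] %in% c(25, 26)))  # distance-3 leaves last
  expect_identical(ord, traversal_order(tr, 21, rng_seed = 3))
  expect_error(traversal_order(tr, 999, 1), "not in tree")
})

test_that("equidistant taxa are visited first with near-uniform frequency over seeds", {
  # 6 equidistant species in one genus
  nodes <- data.frame(id = c(1, 2, 10, 11, 21:27),
                      parent = c(1, 1, 2, 2, rep(10, 1), rep(11, 6)),
                      rank = c("superkingdom", "family", "genus", "genus",
                               rep("species", 7)),
                      name = paste0("n", 1:11), stringsAsFactors = FALSE)
  tr <- taxonomy_tree(nodes)
  firsts <- vapply(1:3000, function(s) traversal_order(tr, 21, s)[1],
                   integer(1))
  freq <- table(factor(firsts, levels = 22:27)) / length(firsts)
  expect_true(all(abs(freq - 1 / 6) < 0.035))
})

test_that("rank-bound pruning removes leaves diverging within minDist or beyond maxDist", {
  tr <- tiny_tree()
  pr <- prune_rank_bounds(tr, 21, "genus", "superkingdom")
  expect_setequal(tree_leaves(pr), c(23, 24, 25, 26))  # congener + p0 gone
  pr2 <- prune_rank_bounds(tr, 21, "species", "superkingdom")
  expect_setequal(tree_leaves(pr2), c(21, 22, 23, 24, 25, 26))
  pr3 <- prune_rank_bounds(tr, 21, "family", "superkingdom")
  expect_setequal(tree_leaves(pr3), c(25, 26))  # genus + family sharers gone
  # the upper bound at the ladder top prunes nothing within one superkingdom
  expect_setequal(tree_leaves(prune_rank_bounds(tr, 21, "species", "genus")),
                  c(21, 22))
})

test_that("minDist=family on the 16-leaf fixture removes p0's genus and family", {
  fix <- flat_fixture()
  p0 <- fix$seed_taxon
  tr <- prune_rank_bounds(fix$tree, p0, "family", "superkingdom")
  lv <- tree_leaves(tr)
  d <- vapply(lv, function(x) taxonomic_distance(fix$tree, p0, x), integer(1))
  expect_true(all(d > 2))
})

test_that("iteration pruning removes pi, its congeners, and keeps primer taxa apart", {
  tr <- tiny_tree()
  # pi = 25 has one congener (26)
  pr <- prune_after_iteration(tr, 21, 25, "genus")
  expect_false(any(c(25, 26, 22) %in% tree_leaves(pr)))
  # pi without congeners in the active set: only pi (and p0-near leaves) go
  pr0 <- prune_rank_bounds(tr, 21, "genus", "superkingdom")
  pr1 <- prune_after_iteration(pr0, 21, 23, "genus", full_tree = tr)
  expect_setequal(tree_leaves(pr1), c(25, 26))

  # simulated selection loop: primer taxa stay pairwise above min_dist
  fix <- default_fixture()
  p0 <- fix$seed_taxon
  act <- prune_rank_bounds(fix$tree, p0, "genus", "superkingdom")
  primers <- p0
  for (k in 1:4) {
    lv <- tree_leaves(act)
    if (!length(lv)) break
    pi <- lv[1]
    primers <- c(primers, pi)
    act <- prune_after_iteration(act, p0, pi, "genus", full_tree = fix$tree)
  }
  for (i in seq_along(primers)) for (j in seq_along(primers)) {
    if (i < j) {
      expect_gte(taxonomic_distance(fix$tree, primers[i], primers[j]), 1L)
    }
  }
})
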