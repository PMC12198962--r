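toy_matrix <- toy_profile_matrix

test_that("FAS filtering reproduces hand-computed record sets per mode", {
  m <- toy_matrix()
  # forward at 0.75: fas_f >= 0.75 -> p1, p2, p3, p6, p10
  expect_setequal(filter_by_fas(m, 0.75, "forward")$records$protein,
                  c("p1", "p2", "p3", "p6", "p10"))
  # backward at 0.75: fas_b >= 0.75 -> p1, p3, p4, p6, p7
  expect_setequal(filter_by_fas(m, 0.75, "backward")$records$protein,
                  c("p1", "p3", "p4", "p6", "p7"))
  # mean at 0.75: means 0.9, 0.7, 0.775, 0.7, 0.2, 1, 0.775, 0.72, 0.275, 0.525
  expect_setequal(filter_by_fas(m, 0.75, "mean")$records$protein,
                  c("p1", "p3", "p6", "p7"))
  # a record with FAS_F 0.8 / FAS_B 0.6 survives forward but not mean
  expect_true("p2" %in% filter_by_fas(m, 0.75, "forward")$records$protein)
  expect_false("p2" %in% filter_by_fas(m, 0.75, "mean")$records$protein)
})

test_that("FAS filtering is idempotent, monotone, and neutral at threshold 0", {
  m <- toy_matrix()
  expect_identical(filter_by_fas(m, 0, "mean")$records, m$records)
  f1 <- filter_by_fas(m, 0.5, "mean")
  expect_identical(filter_by_fas(f1, 0.5, "mean")$records, f1$records)
  for (t2 in c(0.6, 0.8, 1)) {
    hi <- filter_by_fas(m, t2, "mean")$records$protein
    expect_true(all(hi %in% f1$records$protein))
  }
  # threshold 1 keeps only records with the selected score exactly 1
  expect_setequal(filter_by_fas(m, 1, "mean")$records$protein, "p6")
})

test_that("binarization applies the below-0.3 filter and the at-least-one rule", {
  rec <- data.frame(
    seed = "s1", taxon = c(1, 2, 3, 3, 3, 3),
    protein = paste0("q", 1:6), hmm_bits = 40, kimura = 0.3,
    fas_f = c(0.2, 0.3, 0.5, 0.4, 0.35, 0.3),
    fas_b = c(0.2, 0.3, 0.5, 0.4, 0.35, 0.3),
    is_representative = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    co_ortholog_rank = c(1L, 1L, 1L, 2L, 3L, 4L), stringsAsFactors = FALSE)
  m <- profile_matrix(rec, seeds = "s1", taxa = 1:4)
  b <- binarize(m, fas_min = 0.3)
  expect_identical(unname(b[, "s1"]), c(0L, 1L, 1L, 0L))
  # cell with records at FAS 0.2 only -> 0; exactly 0.3 -> kept;
  # 4 co-orthologs >= 0.3 -> still a single 1; empty cell -> 0
})

test_that("binarize commutes with mean-mode filtering", {
  m <- toy_matrix()
  t <- 0.6
  expect_identical(binarize(filter_by_fas(m, t, "mean"), 0),
                   binarize(m, t, "mean"))
})

test_that("the 2-D embedding separates disjoint repertoires and is deterministic", {
  bin <- rbind(matrix(rep(c(1L, 1L, 1L, 0L, 0L, 0L), 5), 5, byrow = TRUE),
               matrix(rep(c(0L, 0L, 0L, 1L, 1L, 1L), 5), 5, byrow = TRUE))
  rownames(bin) <- paste0("t", 1:10); colnames(bin) <- paste0("s", 1:6)
  em <- embed_profiles(bin, rng_seed = 7)
  co <- as.matrix(em[, c("x", "y")])
  D <- as.matrix(stats::dist(co))
  intra <- mean(D[1:5, 1:5][upper.tri(D[1:5, 1:5])])
  inter <- mean(D[1:5, 6:10])
  expect_gt(inter, intra)
  # determinism and identical rows -> near-identical coordinates
  em2 <- embed_profiles(bin, rng_seed = 7)
  expect_identical(em, em2)
  expect_lt(max(stats::dist(co[1:5, ])), 1e-6)
  expect_equal(em$n_seeds, rowSums(bin), ignore_attr = TRUE)

  # permuting rows permutes coordinates (within numerical tolerance)
  perm <- c(3, 1, 2, 7, 10, 4, 5, 6, 9, 8)
  em3 <- embed_profiles(bin[perm, ], rng_seed = 7)
  m3 <- as.matrix(em3[match(em$taxon, em3$taxon), c("x", "y")])
  d_orig <- as.matrix(stats::dist(co))
  d_perm <- as.matrix(stats::dist(m3))
  expect_equal(d_orig, d_perm, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("paralog representatives and duplication origins are resolved", {
  tr <- tiny_tree()
  rec <- data.frame(
    seed = c("sA", "sA", "sA", "sB", "sB"),
    taxon = c(22, 23, 25, 23, 25),
    protein = c("o22", "o23", "oShared", "o23b", "oShared"),
    hmm_bits = 40, kimura = 0.2, fas_f = 1, fas_b = 1,
    is_representative = TRUE, co_ortholog_rank = 1L,
    stringsAsFactors = FALSE)
  m <- profile_matrix(rec, seeds = c("sA", "sB"), taxa = c(22, 23, 25))
  res <- select_paralog_representative(c("sA", "sB"), m, tr,
                                       seed_taxon = 21, focal_lineage = 2)
  # taxon 25 (distance 3) is the closest relative sharing one ortholog for
  # both seeds; sA has more orthologs below the focal lineage
  expect_identical(res$origin_taxon, 25L)
  expect_identical(res$representative, "sA")
  expect_identical(res$origin_scope, "shared")

  rec2 <- rec[rec$protein != "oShared", ]
  m2 <- profile_matrix(rec2, seeds = c("sA", "sB"), taxa = c(22, 23, 25))
  res2 <- select_paralog_representative(c("sA", "sB"), m2, tr, 21, 2)
  expect_identical(res2$origin_scope, "within seed species")
  expect_true(is.na(res2$origin_taxon))
})

test_that("taxa rank by the number of represented seed families", {
  bin <- rbind(t1 = c(1L, 1L, 1L, 0L), t2 = c(0L, 0L, 0L, 0L),
               t3 = c(1L, 0L, 1L, 0L), t4 = c(0L, 1L, 0L, 1L))
  colnames(bin) <- paste0("s", 1:4)
  fams <- stats::setNames(c("f1", "f2", "f3", "f3"), paste0("s", 1:4))
  rk <- rank_taxa_by_repertoire(bin, fams)
  expect_identical(rk$taxon[1], "t1")           # 3 distinct families
  expect_identical(rk$n_families[rk$taxon == "t3"], 2L)
  expect_identical(rk$n_families[rk$taxon == "t4"], 2L)
  expect_lt(which(rk$taxon == "t3"), which(rk$taxon == "t4"))  # id tie-break
  expect_identical(rk$taxon[4], "t2")           # all-zero row ranks last
  expect_identical(rk$n_families[4], 0L)
})

test_that("PhyloProfile export writes the viewer's tabular layout", {
  m <- toy_matrix()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_phyloprofile(m, path)
  tab <- utils::read.delim(path)
  expect_identical(names(tab), c("geneID", "ncbiID", "orthoID",
                                 "FAS_F", "FAS_B"))
  expect_identical(nrow(tab), nrow(m$records))
  expect_true(all(grepl("^ncbi", tab$ncbiID)))
  expect_true(file.exists(paste0(path, ".config.json")))
})
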