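test_that("reciprocity accepts best-hit core orthologs and applies the distance rule", {
  set.seed(61)
  core_seq <- random_protein_seq(60)
  cand_direct <- mutate_seq(core_seq, 0.2)
  ref <- proteome(1L, c(core = core_seq,
                        junk1 = random_protein_seq(60),
                        junk2 = random_protein_seq(60)))
  rc <- reciprocity_check(cand_direct, ref, "core")
  expect_true(rc$accept)
  expect_identical(rc$best_hit, "core")

  # best hit is a close in-paralog of the core, but the core is closer to
  # it than the candidate is: accept via the distance inequality
  paralog <- mutate_seq(core_seq, 0.1)
  cand_via_paralog <- mutate_seq(paralog, 0.25)
  ref2 <- proteome(1L, c(core = core_seq, paralog = paralog))
  rc2 <- reciprocity_check(cand_via_paralog, ref2, "core")
  expect_true(rc2$accept)
  expect_identical(rc2$best_hit, "paralog")
  expect_lt(rc2$d_core_best, rc2$d_cand_best)

  # best hit is an unrelated protein much closer to the candidate than to
  # the core: reject (putative out-paralog / spurious family)
  stranger <- random_protein_seq(60)
  cand_stranger <- mutate_seq(stranger, 0.05)
  ref3 <- proteome(1L, c(core = core_seq, stranger = stranger))
  rc3 <- reciprocity_check(cand_stranger, ref3, "core")
  expect_false(rc3$accept)
  expect_gt(rc3$d_core_best, rc3$d_cand_best)
})

test_that("representative selection minimizes Kimura distance with id tie-break", {
  acc <- data.frame(protein = c("b", "a", "c"), kimura = c(0.5, 0.2, 0.2))
  expect_identical(select_representative(acc), "a")
  expect_identical(select_representative(acc[1, , drop = FALSE]), "b")
  expect_error(select_representative(acc[0, ]), "no accepted")
})

test_that("co-ortholog filtering retains candidates near the representative", {
  set.seed(62)
  seed_seq <- random_protein_seq(80)
  rep_seq <- mutate_seq(seed_seq, 0.15)
  near <- mutate_seq(rep_seq, 0.05)   # kimura to rep well below rep-to-seed
  far <- mutate_seq(rep_seq, 0.5)     # beyond the rep-to-seed distance
  d_rep_seed <- kimura_distance(global_align(rep_seq, seed_seq))
  acc <- data.frame(protein = c("rep", "near", "far"),
                    kimura = c(d_rep_seed, NA, NA),
                    seq = c(rep_seq, near, far), stringsAsFactors = FALSE)
  kept <- filter_coorthologs(acc, "rep", seed_seq)
  expect_true("rep" %in% kept$protein)
  expect_true("near" %in% kept$protein)
  expect_false("far" %in% kept$protein)
})

test_that("per-taxon search returns planted orthologs, in-paralog pairs, and no decoys", {
  fix <- default_fixture()
  own <- fix$proteomes[[as.character(fix$seed_taxon)]]

  # a taxon with a planted 1:1 ortholog
  tr1 <- fix$truth[fix$truth$relation == "ortholog" &
                   fix$truth$taxon > 501 & fix$truth$taxon < 600, ]
  fam <- tr1$family[1]; tx <- tr1$taxon[1]
  seed <- seed_protein_of(fix, fam)
  cg <- compile_core_group(seed, fix$proteomes, fix$tree, fix$architectures,
                           compile_options(rng_seed = 4))
  rec <- search_taxon(cg, fix$proteomes[[as.character(tx)]], own,
                      fix$architectures)
  truth_ids <- fix$truth$protein[fix$truth$family == fam &
                                 fix$truth$taxon == tx]
  expect_gte(nrow(rec), 1L)
  expect_true(rec$protein[rec$is_representative] %in% truth_ids)
  expect_identical(sum(rec$is_representative), 1L)
  expect_true(all(!is.na(rec$fas_f)) && all(!is.na(rec$fas_b)))

  # a taxon with a planted post-speciation duplication keeps both copies
  dup <- fix$truth[fix$truth$relation == "in-paralog", ][1, ]
  seed2 <- seed_protein_of(fix, dup$family)
  cg2 <- compile_core_group(seed2, fix$proteomes, fix$tree,
                            fix$architectures, compile_options(rng_seed = 4))
  rec2 <- search_taxon(cg2, fix$proteomes[[as.character(dup$taxon)]], own,
                       fix$architectures)
  expect_gte(nrow(rec2), 2L)
  expect_true(dup$protein %in% rec2$protein)

  # a proteome of decoys only yields nothing
  set.seed(63)
  decoys <- vapply(1:20, function(i) random_protein_seq(60), character(1))
  names(decoys) <- paste0("d", 1:20)
  rec3 <- search_taxon(cg, proteome(999L, decoys), own, fix$architectures)
  expect_identical(nrow(rec3), 0L)
})

test_that("full search output is invariant under the worker partition", {
  fix <- default_fixture()
  groups <- lapply(1:2, function(f) {
    compile_core_group(seed_protein_of(fix, f), fix$proteomes, fix$tree,
                       fix$architectures, compile_options(rng_seed = 6))
  })
  refs <- stats::setNames(list(fix$proteomes[[as.character(fix$seed_taxon)]]),
                          as.character(fix$seed_taxon))
  pm1 <- run_full_search(groups, fix$proteomes, refs, fix$architectures,
                         n_workers = 1)
  pm4 <- run_full_search(groups, fix$proteomes, refs, fix$architectures,
                         n_workers = 4)
  expect_identical(pm1$records, pm4$records)
  expect_gt(nrow(pm1$records), 0L)
})

test_that("searches can be restricted to subgroups and extended incrementally", {
  fix <- default_fixture()
  cg <- compile_core_group(seed_protein_of(fix, 5), fix$proteomes, fix$tree,
                           fix$architectures, compile_options(rng_seed = 6))
  refs <- stats::setNames(list(fix$proteomes[[as.character(fix$seed_taxon)]]),
                          as.character(fix$seed_taxon))
  # restriction to one family's species
  fam_taxa <- c(503L, 504L)
  pm_sub <- run_full_search(list(cg), fix$proteomes, refs, fix$architectures,
                            taxa = fam_taxa)
  expect_true(all(pm_sub$records$taxon %in% fam_taxa))
  # incremental extension: new taxa only, re-using the stored model
  path <- withr::local_tempfile(fileext = ".json")
  write_phmm(cg$hmm, path)
  cg2 <- cg; cg2$hmm <- read_phmm(path)
  new_taxa <- c(505L, 506L)
  pm_new <- run_full_search(list(cg2), fix$proteomes, refs,
                            fix$architectures, taxa = new_taxa)
  expect_true(all(pm_new$records$taxon %in% new_taxa))
  full <- run_full_search(list(cg), fix$proteomes, refs, fix$architectures)
  expect_equal(pm_new$records,
               full$records[full$records$taxon %in% new_taxa,
                            names(pm_new$records)],
               ignore_attr = TRUE)
})

test_that("paralogous seeds share orthologs in taxa that diverged before the duplication", {
  fix <- default_fixture()
  # the last two families duplicated on the eukaryote stem; bacteria carry
  # one pre-duplication copy
  n <- fix$spec$n_families
  pair <- c(n - 1L, n)
  bact <- tree_leaves(fix$tree)
  bact <- bact[bact >= 600]
  refs <- stats::setNames(list(fix$proteomes[[as.character(fix$seed_taxon)]]),
                          as.character(fix$seed_taxon))
  found <- lapply(pair, function(f) {
    cg <- compile_core_group(seed_protein_of(fix, f), fix$proteomes,
                             fix$tree, fix$architectures,
                             compile_options(rng_seed = 8))
    pm <- run_full_search(list(cg), fix$proteomes, refs, fix$architectures,
                          taxa = bact)
    pm$records[pm$records$is_representative, c("taxon", "protein")]
  })
  joint <- merge(found[[1]], found[[2]], by = "taxon")
  expect_gt(nrow(joint), 0L)
  expect_identical(joint$protein.x, joint$protein.y)
})
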