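arch <- function(id, len, types, starts, ends) {
  architecture(id, len, data.frame(type = types, start = starts, end = ends,
                                   stringsAsFactors = FALSE))
}

test_that("architecture construction validates coordinates and orders instances", {
  a <- arch("p", 100, "PFAM:PF00759", 10, 80)
  expect_identical(nrow(a$instances), 1L)
  expect_error(arch("p", 100, "PFAM:PF00759", 10, 101), "out of range")
  expect_error(arch("p", 100, "PFAM:PF00759", 0, 50), "out of range")
  b <- arch("p", 100, c("TM:helix", "PFAM:X"), c(50, 5), c(70, 40))
  expect_identical(b$instances$start, c(5L, 50L))  # ordered by start
})

test_that("architecture JSON round-trips and flags unknown namespaces", {
  fix <- default_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  some <- fix$architectures[1:50]
  write_architectures(some, path)
  back <- read_architectures(path)
  expect_identical(names(back), names(some))
  for (id in names(some)) {
    expect_identical(back[[id]]$length, some[[id]]$length)
    expect_identical(back[[id]]$instances, some[[id]]$instances)
  }
  odd <- list(x = arch("x", 50, "WEIRD:thing", 1, 10))
  write_architectures(odd, path)
  expect_warning(back2 <- read_architectures(path), "unknown feature namespace")
  expect_identical(back2$x$instances$type, "WEIRD:thing")  # kept
})

test_that("FAS boundary contract: identical architectures score 1, disjoint types 0", {
  a <- arch("a", 120, c("PFAM:PF1", "PFAM:PF2", "TM:helix"),
            c(10, 60, 100), c(40, 90, 118))
  expect_equal(fas_score(a, a), 1)
  b <- arch("b", 120, c("SMART:SM1", "LCR:seg"), c(5, 80), c(30, 100))
  expect_equal(fas_score(a, b), 0)
  expect_equal(fas_score(b, a), 0)
  fp <- bidirectional_fas(a, a)
  expect_equal(fp$fas_f, 1); expect_equal(fp$fas_b, 1)
})

test_that("FAS is asymmetric: missing reference features depress only the forward score", {
  ref <- arch("r", 100, c("PFAM:A", "PFAM:B"), c(10, 60), c(40, 90))
  qry <- arch("q", 100, "PFAM:A", 10, 40)  # perfectly overlapping PFAM:A
  expect_equal(fas_score(ref, qry), 0.5)
  expect_equal(fas_score(qry, ref), 1.0)
  fp <- bidirectional_fas(ref, qry)
  expect_lt(fp$fas_f, 1); expect_equal(fp$fas_b, 1)
})

test_that("multiplied query domains leave the forward score at 1 and depress the backward score", {
  ref <- arch("r", 100, "PFAM:G28", 10, 90)
  qry <- arch("q", 100, rep("PFAM:G28", 4), rep(10, 4), rep(90, 4))
  fp <- bidirectional_fas(ref, qry)
  expect_equal(fp$fas_f, 1)      # reference fully covered
  expect_lt(fp$fas_b, 1)         # quadruplication is unmatched in reverse
  expect_equal(fp$fas_b, 0.25)
})

test_that("removing a matched query instance never increases the score", {
  set.seed(41)
  for (k in 1:50) {
    len <- 100L
    n <- sample(2:5, 1)
    types <- sample(paste0("PFAM:T", 1:3), n, replace = TRUE)
    starts <- sample(1:60, n, replace = TRUE)
    q_inst <- data.frame(type = types, start = starts,
                         end = pmin(len, starts + sample(10:40, n, TRUE)))
    ref <- arch("r", len, c("PFAM:T1", "PFAM:T2"), c(5, 50), c(45, 95))
    qry <- architecture("q", len, q_inst)
    full <- fas_score(ref, qry)
    drop <- sample(n, 1)
    qry2 <- architecture("q", len, q_inst[-drop, , drop = FALSE])
    expect_lte(fas_score(ref, qry2), full + 1e-12)
  }
})

test_that("FAS stays within [0, 1] for random architecture pairs", {
  set.seed(42)
  rand_arch <- function(id) {
    len <- sample(50:300, 1)
    n <- sample(0:6, 1)
    if (n == 0) return(architecture(id, len))
    starts <- sample(seq_len(len - 10), n, replace = TRUE)
    architecture(id, len, data.frame(
      type = sample(c(paste0("PFAM:PF", 1:4), "TM:helix", "LCR:seg"),
                    n, replace = TRUE),
      start = starts,
      end = pmin(len, starts + sample(5:80, n, replace = TRUE))))
  }
  for (k in 1:1000) {
    a <- rand_arch("a"); b <- rand_arch("b")
    s <- fas_score(a, b)
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("architecture diffs report gains, losses and multiplicity changes", {
  a <- arch("a", 100, c("PFAM:A", "PFAM:B"), c(10, 60), c(40, 90))
  expect_identical(nrow(architecture_diff(a, a)), 0L)

  # +3 instances of a cellulose-binding-like motif in the ortholog
  b <- arch("b", 160, c("PFAM:A", "PFAM:B", rep("PFAM:CBM", 3)),
            c(10, 60, 100, 120, 140), c(40, 90, 110, 130, 150))
  d <- architecture_diff(a, b)
  row <- d[d$type == "PFAM:CBM", ]
  expect_identical(row$change, "gained")
  expect_identical(row$n_ortholog, 3L)

  # random pair: the diff equals the symmetric multiset difference
  set.seed(43)
  for (k in 1:20) {
    ta <- sample(paste0("PFAM:T", 1:4), sample(1:5, 1), replace = TRUE)
    tb <- sample(paste0("PFAM:T", 1:4), sample(1:5, 1), replace = TRUE)
    mk <- function(id, tt) architecture(id, 200, data.frame(
      type = tt, start = seq(1, by = 10, length.out = length(tt)),
      end = seq(9, by = 10, length.out = length(tt))))
    d <- architecture_diff(mk("a", ta), mk("b", tb))
    for (t in union(ta, tb)) {
      na <- sum(ta == t); nb <- sum(tb == t)
      if (na == nb) expect_false(t %in% d$type)
      else {
        expect_identical(d$n_seed[d$type == t], na)
        expect_identical(d$n_ortholog[d$type == t], nb)
      }
    }
  }
})
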