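# Shared fixtures, generated in code at test time.

# Default synthetic scenario, generated once per test run.
default_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_scenario(scenario_spec(rng_seed = 1L))
    cache
  }
})

# Small taxonomy used by the spec-shape examples: 16 species in 4 genera
# and 2 families (single class, single order).
flat_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_scenario(scenario_spec(
        n_classes = 1L, orders_per_class = 1L, families_per_order = 2L,
        genera_per_family = 2L, species_per_genus = 4L,
        n_families = 4L, rng_seed = 2L))
    }
    cache
  }
})

seed_protein_of <- function(fix, family) {
  id <- fix$seeds[[as.character(family)]]
  protein(id, fix$seed_taxon,
          fix$proteomes[[as.character(fix$seed_taxon)]]$seqs[[id]])
}

# A minimal hand-written taxonomy: 1 superkingdom, 2 families, 3 genera,
# 6 species. Distances from s1: s2 -> 1, s3/s4 -> 2, s5/s6 -> 3.
tiny_tree <- function() {
  taxonomy_tree(data.frame(
    id     = c(1,  2,   3,   4,  10, 11, 12, 21, 22, 23, 24, 25, 26),
    parent = c(1,  1,   2,   2,   3,  3,  4, 10, 10, 11, 11, 12, 12),
    rank   = c("superkingdom", "order", "family", "family", "genus",
               "genus", "genus", rep("species", 6)),
    name   = c("SK", "Ord", "FamA", "FamB", "GenA", "GenB", "GenC",
               paste0("s", 1:6)),
    stringsAsFactors = FALSE))
}

# Ten hand-scored ortholog records across two seeds and five taxa, used to
# check filtering semantics against hand-computed record sets.
toy_profile_matrix <- function() {
  rec <- data.frame(
    seed = rep(c("s1", "s2"), each = 5),
    taxon = rep(1:5, 2),
    protein = paste0("p", 1:10),
    hmm_bits = 50, kimura = 0.2,
    fas_f = c(0.90, 0.80, 0.75, 0.60, 0.20, 1.00, 0.70, 0.74, 0.30, 0.95),
    fas_b = c(0.90, 0.60, 0.80, 0.80, 0.20, 1.00, 0.85, 0.70, 0.25, 0.10),
    is_representative = TRUE, co_ortholog_rank = 1L,
    stringsAsFactors = FALSE)
  profile_matrix(rec, seeds = c("s1", "s2"), taxa = 1:5)
}

# Independent affine-gap global alignment oracle (score only); gap of
# length L costs open + ext * L, end gaps included.
nw_score_oracle <- function(a, b, m, open = 10, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  la <- length(A); lb <- length(B); NEG <- -1e9
  M <- X <- Y <- matrix(NEG, la + 1, lb + 1)
  M[1, 1] <- 0
  for (i in 2:(la + 1)) X[i, 1] <- -open - ext * (i - 1)
  for (j in 2:(lb + 1)) Y[1, j] <- -open - ext * (j - 1)
  for (i in 2:(la + 1)) for (j in 2:(lb + 1)) {
    s <- m[A[i - 1], B[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
    Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
  }
  max(M[la + 1, lb + 1], X[la + 1, lb + 1], Y[la + 1, lb + 1])
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

random_protein_seq <- function(n, alphabet = c("A", "C", "D", "E", "G", "K",
                                               "L", "S", "T", "V")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, p) {
  aa20 <- c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V")
  r <- strsplit(seq, "")[[1]]
  hit <- runif(length(r)) < p
  r[hit] <- vapply(r[hit], function(x) sample(setdiff(aa20, x), 1), character(1))
  paste(r, collapse = "")
}
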