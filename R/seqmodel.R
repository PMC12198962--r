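#' @importFrom Biostrings pairwiseAlignment AAString AAStringSet
#'   readAAStringSet writeXStringSet alignedPattern alignedSubject
NULL

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Lazily loaded BLOSUM62 from Biostrings.
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Default alignment scoring parameters
#'
#' BLOSUM62 with affine gap penalties (gap opening 10, gap extension 1 per
#' gap position), the conventional defaults of protein search tools.
#'
#' @param gap_open,gap_extend gap penalties (positive costs).
#' @return list of scoring parameters.
#' @export
align_params <- function(gap_open = 10, gap_extend = 1) {
  list(matrix = "BLOSUM62", gap_open = gap_open, gap_extend = gap_extend)
}

#' Construct a protein record
#'
#' @param id protein identifier.
#' @param taxon taxon id the protein belongs to.
#' @param seq amino-acid sequence (20-letter alphabet plus X); uppercased.
#' @return a `protein` list.
#' @export
protein <- function(id, taxon, seq) {
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("empty protein sequence: ", id)
  if (grepl("[-.]", seq)) stop("gap characters in protein sequence: ", id)
  bad <- setdiff(strsplit(seq, "")[[1]], c(.AA20, "X"))
  if (length(bad)) stop("illegal residue characters in ", id, ": ",
                        paste(unique(bad), collapse = ""))
  list(id = as.character(id), taxon = as.integer(taxon), seq = seq)
}

#' Construct a proteome
#'
#' @param taxon taxon id.
#' @param seqs named character vector of protein sequences (names = ids).
#' @param isoform_map optional named list: gene id -> character vector of
#'   protein ids.
#' @return a `proteome` object.
#' @export
proteome <- function(taxon, seqs, isoform_map = NULL) {
  if (anyDuplicated(names(seqs))) stop("duplicate protein id in proteome")
  structure(list(taxon = as.integer(taxon), seqs = toupper(seqs),
                 isoform_map = isoform_map),
            class = "proteome")
}

#' @export
print.proteome <- function(x, ...) {
  cat("proteome: taxon", x$taxon, "-", length(x$seqs), "proteins\n")
  invisible(x)
}

#' Read a proteome from FASTA
#'
#' The first whitespace-delimited token of each description line is the
#' protein id; residues are uppercased on read.
#'
#' @param path FASTA file.
#' @param taxon taxon id to attach.
#' @return a `proteome`.
#' @export
read_fasta <- function(path, taxon = NA_integer_) {
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) stop("duplicate id in FASTA: ", path)
  proteome(taxon, stats::setNames(toupper(as.character(ss)), ids))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector (ids -> sequences) or a `proteome`.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "proteome")) seqs <- seqs$seqs
  ss <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch global alignment under BLOSUM62 with affine gap
#' penalties. The alignment score of a candidate against the seed, divided
#' by the seed's self score, is the AS ratio entering the candidate score.
#'
#' @param a,b amino-acid sequences (character) or `protein` records.
#' @param params scoring parameters from [align_params()].
#' @return list with `score`, gapped `aligned_a`/`aligned_b`, and
#'   `p_distance` (fraction of mismatched aligned positions, gap columns
#'   excluded).
#' @export
global_align <- function(a, b, params = align_params()) {
  if (is.list(a)) a <- a$seq
  if (is.list(b)) b <- b$seq
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = blosum62(),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  ga <- as.character(Biostrings::alignedPattern(pa))
  gb <- as.character(Biostrings::alignedSubject(pa))
  list(score = Biostrings::score(pa),
       aligned_a = ga, aligned_b = gb,
       p_distance = p_distance(ga, gb))
}

# Batch alignment scores of many sequences against one subject.
align_scores_many <- function(seqs, subject, params = align_params()) {
  if (length(seqs) == 0L) return(numeric(0))
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(seqs), Biostrings::AAString(subject),
    type = "global", substitutionMatrix = blosum62(),
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    scoreOnly = TRUE)
  stats::setNames(s, names(seqs))
}

#' Self alignment score
#'
#' The maximally achievable alignment score of a sequence, i.e. its global
#' alignment score against itself.
#'
#' @inheritParams global_align
#' @return numeric score.
#' @export
self_score <- function(a, params = align_params()) {
  if (is.list(a)) a <- a$seq
  # self-alignment is gap-free under matrices with a maximal diagonal:
  # sum the diagonal substitution scores directly
  m <- blosum62()
  r <- strsplit(a, "")[[1]]
  sum(m[cbind(r, r)])
}

# Fraction of mismatching positions among gap-free aligned columns.
p_distance <- function(ga, gb) {
  a <- strsplit(ga, "")[[1]]
  b <- strsplit(gb, "")[[1]]
  ok <- a != "-" & b != "-"
  if (!any(ok)) return(1)
  mean(a[ok] != b[ok])
}

#' Kimura protein distance
#'
#' The standard log correction of the observed proportion of differing
#' residues p: d = -ln(1 - p - 0.2 p^2), in substitutions per site.
#' Saturated inputs (1 - p - 0.2 p^2 <= 0) return `Inf`, which compares as
#' larger than any finite distance.
#'
#' @param x an alignment result from [global_align()], or a numeric
#'   p-distance.
#' @return non-negative numeric distance (possibly `Inf`).
#' @export
kimura_distance <- function(x) {
  p <- if (is.list(x)) x$p_distance else x
  arg <- 1 - p - 0.2 * p^2
  ifelse(arg <= 0, Inf, -log(arg))
}

# Kimura distance between two raw sequences via a fresh global alignment.
kimura_between <- function(a, b, params = align_params()) {
  kimura_distance(global_align(a, b, params))
}

## ---- internal progressive multiple aligner --------------------------------

# Profile = list(cols = list of named count vectors over residues, n = #seqs,
# rows = gapped character strings). Columns align by average-of-pairs
# BLOSUM62 score with a linear gap penalty.

# average substitution score between two profile columns (count vectors);
# gaps inside a profile column score 0 against anything.
.col_score <- function(ca, cb, m) {
  total <- 0; npair <- 0
  for (ra in names(ca)) for (rb in names(cb)) {
    w <- ca[[ra]] * cb[[rb]]
    if (ra == "-" || rb == "-") s <- 0
    else s <- m[ra, rb]
    total <- total + w * s
    npair <- npair + w
  }
  total / npair
}

.profile_align <- function(pa, pb, gap = 8) {
  m <- blosum62()
  A <- pa$counts; B <- pb$counts
  la <- length(A); lb <- length(B)
  S <- matrix(0, la, lb)
  for (i in seq_len(la)) for (j in seq_len(lb)) S[i, j] <- .col_score(A[[i]], B[[j]], m)
  F <- matrix(0, la + 1L, lb + 1L)
  F[, 1L] <- -gap * (0:la)
  F[1L, ] <- -gap * (0:lb)
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      F[i + 1L, j + 1L] <- max(F[i, j] + S[i, j],
                               F[i, j + 1L] - gap,
                               F[i + 1L, j] - gap)
    }
  }
  # traceback, preferring diagonal, then gap in profile B, then in A
  i <- la; j <- lb
  ops <- character(0)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L && isTRUE(all.equal(F[i + 1L, j + 1L], F[i, j] + S[i, j]))) {
      ops <- c("D", ops); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && isTRUE(all.equal(F[i + 1L, j + 1L], F[i, j + 1L] - gap))) {
      ops <- c("A", ops); i <- i - 1L
    } else {
      ops <- c("B", ops); j <- j - 1L
    }
  }
  # merge rows according to the operation string
  rows_a <- pa$rows; rows_b <- pb$rows
  out_a <- rep("", length(rows_a)); out_b <- rep("", length(rows_b))
  ia <- 0L; ib <- 0L
  ca <- lapply(rows_a, function(r) strsplit(r, "")[[1]])
  cb <- lapply(rows_b, function(r) strsplit(r, "")[[1]])
  res_a <- lapply(ca, function(x) character(length(ops)))
  res_b <- lapply(cb, function(x) character(length(ops)))
  for (k in seq_along(ops)) {
    op <- ops[k]
    if (op == "D") { ia <- ia + 1L; ib <- ib + 1L }
    else if (op == "A") ia <- ia + 1L
    else ib <- ib + 1L
    for (s in seq_along(ca)) res_a[[s]][k] <- if (op %in% c("D", "A")) ca[[s]][ia] else "-"
    for (s in seq_along(cb)) res_b[[s]][k] <- if (op %in% c("D", "B")) cb[[s]][ib] else "-"
  }
  rows <- c(vapply(res_a, paste, character(1), collapse = ""),
            vapply(res_b, paste, character(1), collapse = ""))
  .profile_from_rows(rows)
}

.profile_from_rows <- function(rows) {
  chs <- lapply(rows, function(r) strsplit(r, "")[[1]])
  L <- length(chs[[1]])
  counts <- lapply(seq_len(L), function(k) {
    col <- vapply(chs, `[`, character(1), k)
    tab <- table(col)
    stats::setNames(as.numeric(tab), names(tab))
  })
  list(counts = counts, rows = rows)
}

# fraction of 3-mers of the rarer sequence shared with the other; the
# standard cheap guide-tree distance of progressive aligners
.kmer_dist <- function(a, b, k = 3L) {
  km <- function(s) {
    n <- nchar(s)
    if (n < k) return(s)
    substring(s, 1:(n - k + 1L), k:n)
  }
  ta <- table(km(a)); tb <- table(km(b))
  common <- intersect(names(ta), names(tb))
  1 - sum(pmin(ta[common], tb[common])) / min(sum(ta), sum(tb))
}

#' Align a core ortholog group
#'
#' Deterministic internal progressive aligner: a UPGMA guide tree is built
#' from pairwise 3-mer distances, and profiles are merged bottom-up by
#' profile-profile dynamic programming (average BLOSUM62 column score,
#' linear gap penalty). A single input sequence is returned unchanged as a
#' one-row alignment. An external aligner can be substituted via the
#' `aligner` hook, which must map a named sequence vector to a named gapped
#' vector.
#'
#' @param seqs named character vector of ungapped sequences.
#' @param params pairwise scoring parameters for the guide tree.
#' @param aligner optional function(named seqs) -> named gapped seqs.
#' @return named character vector of equal-length gapped rows, in input
#'   order.
#' @export
align_core_group <- function(seqs, params = align_params(), aligner = NULL) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  if (!is.null(aligner)) return(aligner(seqs))
  n <- length(seqs)
  if (n == 1L) return(seqs)
  if (n == 2L) {
    al <- global_align(seqs[[1]], seqs[[2]], params)
    return(stats::setNames(c(al$aligned_a, al$aligned_b), names(seqs)))
  }
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    d <- .kmer_dist(seqs[[i]], seqs[[j]])
    D[i, j] <- D[j, i] <- d
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  profiles <- lapply(seq_along(seqs), function(s) {
    pr <- .profile_from_rows(unname(seqs[s]))
    pr$rows <- stats::setNames(pr$rows, names(seqs)[s])
    pr
  })
  merged <- vector("list", n - 1L)
  node_profile <- function(k) if (k < 0) profiles[[-k]] else merged[[k]]
  for (k in seq_len(n - 1L)) {
    pa <- node_profile(hc$merge[k, 1L])
    pb <- node_profile(hc$merge[k, 2L])
    pr <- .profile_align(pa, pb)
    pr$rows <- stats::setNames(pr$rows, c(names(pa$rows), names(pb$rows)))
    merged[[k]] <- pr
  }
  out <- merged[[n - 1L]]$rows
  out[names(seqs)]
}

#' Sum-of-pairs score of a multiple alignment
#'
#' @param rows named character vector of equal-length gapped rows.
#' @param gap linear gap penalty per residue-gap pair.
#' @return numeric sum-of-pairs score under BLOSUM62.
#' @export
msa_sp_score <- function(rows, gap = 8) {
  m <- blosum62()
  chs <- lapply(rows, function(r) strsplit(r, "")[[1]])
  total <- 0
  n <- length(chs)
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    a <- chs[[i]]; b <- chs[[j]]
    for (k in seq_along(a)) {
      if (a[k] == "-" && b[k] == "-") next
      if (a[k] == "-" || b[k] == "-") total <- total - gap
      else total <- total + m[a[k], b[k]]
    }
  }
  total
}
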