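# Background amino-acid frequencies (Robinson & Robinson), the conventional
# null model of profile search tools.
.BG_FREQ <- c(
  A = 0.0787945, C = 0.0151600, D = 0.0535222, E = 0.0668298,
  F = 0.0397062, G = 0.0695071, H = 0.0229198, I = 0.0590092,
  K = 0.0594422, L = 0.0963728, M = 0.0237718, N = 0.0414386,
  P = 0.0481777, Q = 0.0341470, R = 0.0516258, S = 0.0677699,
  T = 0.0585129, V = 0.0647413, W = 0.0143859, Y = 0.0342359)

#' Train a profile HMM from a multiple alignment
#'
#' Builds a Plan-7-like profile HMM (match/insert/delete states, flanking
#' inserts emitting from the background). Match columns are alignment
#' columns with at most 50% gaps. Emission and transition distributions are
#' maximum-likelihood counts smoothed with a Laplace pseudocount.
#'
#' @param msa named character vector of equal-length gapped rows (a single
#'   ungapped sequence is the degenerate one-row alignment used to seed the
#'   first iteration).
#' @param pseudocount Laplace pseudocount weight added to every emission
#'   (over the 20-letter alphabet); allowed transitions receive a sparse
#'   prior (match-match favored) scaled by the same weight.
#' @return a `profile_hmm` object.
#' @export
train_phmm <- function(msa, pseudocount = 1) {
  rows <- lapply(msa, function(r) strsplit(r, "")[[1]])
  L <- unique(lengths(rows))
  if (length(L) != 1L) stop("alignment rows differ in length")
  n <- length(rows)
  colmat <- do.call(rbind, rows)  # n x L
  gap_frac <- colMeans(colmat == "-")
  is_match <- gap_frac <= 0.5
  m <- sum(is_match)
  if (m == 0L) stop("alignment has zero match columns")
  match_idx <- which(is_match)

  # --- emissions ---
  em_counts <- matrix(pseudocount, nrow = m, ncol = 20,
                      dimnames = list(NULL, .AA20))
  for (j in seq_len(m)) {
    col <- colmat[, match_idx[j]]
    col <- col[col %in% .AA20]
    if (length(col)) {
      tab <- table(factor(col, levels = .AA20))
      em_counts[j, ] <- em_counts[j, ] + as.numeric(tab)
    }
  }
  em_probs <- em_counts / rowSums(em_counts)

  # --- transitions ---
  # boundary j in 0..m separates match column j from j+1 (0 = begin,
  # m = end); allowed: M->{M,I,D}, I->{M,I}, D->{M,D}; at the last boundary
  # deletes cannot continue and matches cannot delete.
  cnt <- list(tmm = numeric(m + 1), tmi = numeric(m + 1), tmd = numeric(m + 1),
              tim = numeric(m + 1), tii = numeric(m + 1),
              tdm = numeric(m + 1), tdd = numeric(m + 1))
  col_boundary <- cumsum(is_match)  # boundary index right of each column
  for (s in seq_len(n)) {
    r <- rows[[s]]
    state <- "M"; at <- 0L  # begin acts as match state at boundary 0
    for (k in seq_len(L)) {
      if (is_match[k]) {
        new_state <- if (r[k] == "-") "D" else "M"
        key <- paste0("t", tolower(state), tolower(new_state))
        cnt[[key]][at + 1L] <- cnt[[key]][at + 1L] + 1
        state <- new_state; at <- col_boundary[k]
      } else if (r[k] != "-") {
        key <- paste0("t", tolower(state), "i")
        cnt[[key]][at + 1L] <- cnt[[key]][at + 1L] + 1
        state <- "I"
      }
    }
    key <- paste0("t", tolower(state), "m")  # into end
    cnt[[key]][m + 1L] <- cnt[[key]][m + 1L] + 1
  }
  # transition prior: a sparse-prior pseudocount favoring match-match, the
  # standard remedy against over-penalizing sparse alignments (a flat
  # Laplace count would price every match column ~1 bit with few rows)
  pw <- pseudocount
  prior <- list(mm = 0.90 * pw, mi = 0.05 * pw, md = 0.05 * pw,
                im = 0.50 * pw, ii = 0.50 * pw,
                dm = 0.50 * pw, dd = 0.50 * pw)
  trans <- list(tmm = numeric(m + 1), tmi = numeric(m + 1), tmd = numeric(m + 1),
                tim = numeric(m + 1), tii = numeric(m + 1),
                tdm = numeric(m + 1), tdd = numeric(m + 1))
  for (j in 0:m) {
    i <- j + 1L
    last <- j == m
    # match outgoing
    mm <- cnt$tmm[i] + prior$mm; mi <- cnt$tmi[i] + prior$mi
    md <- if (last) 0 else cnt$tmd[i] + prior$md
    tot <- mm + mi + md
    trans$tmm[i] <- mm / tot; trans$tmi[i] <- mi / tot
    trans$tmd[i] <- if (last) 0 else md / tot
    # insert outgoing
    im <- cnt$tim[i] + prior$im; ii <- cnt$tii[i] + prior$ii
    tot <- im + ii
    trans$tim[i] <- im / tot; trans$tii[i] <- ii / tot
    # delete outgoing (boundary 0 has no delete state)
    if (j == 0L) {
      trans$tdm[i] <- 0; trans$tdd[i] <- 0
    } else {
      dm <- cnt$tdm[i] + prior$dm
      dd <- if (last) 0 else cnt$tdd[i] + prior$dd
      tot <- dm + dd
      trans$tdm[i] <- dm / tot
      trans$tdd[i] <- if (last) 0 else dd / tot
    }
  }

  structure(list(
    length = m,
    alphabet = .AA20,
    em_probs = em_probs,
    trans = trans,
    bg = .BG_FREQ[.AA20],
    pseudocount = pseudocount,
    match_columns = match_idx,
    trained_from = names(msa) %||% character(0)
  ), class = "profile_hmm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.profile_hmm <- function(x, ...) {
  cat("profile_hmm:", x$length, "match states, trained from",
      length(x$trained_from), "sequence(s)\n")
  invisible(x)
}

.hmm_log_pieces <- function(hmm) {
  em <- log(hmm$em_probs) - matrix(log(hmm$bg), nrow = hmm$length,
                                   ncol = 20, byrow = TRUE)
  trans <- lapply(hmm$trans, function(v) matrix(log(v), ncol = 1))
  list(em = em, trans = trans)
}

.encode_seqs <- function(seqs, alphabet = .AA20) {
  lapply(seqs, function(s) {
    r <- strsplit(s, "")[[1]]
    i <- match(r, alphabet)
    i[is.na(i)] <- 0L  # unknown residues (X) score log-odds 0
    as.integer(i - 1L)
  })
}

#' Log-odds score of sequences against a profile HMM
#'
#' @param hmm a `profile_hmm`.
#' @param seqs character vector of ungapped sequences.
#' @param algorithm `"forward"` (sum over paths; the hit score) or
#'   `"viterbi"` (best path; always less than or equal to forward).
#' @return numeric vector of log-odds scores in bits.
#' @export
phmm_score <- function(hmm, seqs, algorithm = c("forward", "viterbi")) {
  algorithm <- match.arg(algorithm)
  pieces <- .hmm_log_pieces(hmm)
  enc <- .encode_seqs(seqs, hmm$alphabet)
  nats <- .phmm_score_cpp(pieces$em, pieces$trans, enc,
                          algorithm == "forward")
  stats::setNames(nats / log(2), names(seqs))
}

#' Search a proteome with a profile HMM
#'
#' Scores every protein by the forward algorithm against the background
#' residue model and returns hits at or above the bit threshold, sorted by
#' decreasing score (ties broken by protein id).
#'
#' @param hmm a `profile_hmm`.
#' @param prot a `proteome`.
#' @param bit_threshold minimum log-odds in bits (default 10).
#' @return data.frame with columns `protein`, `taxon`, `bits`, `rank`.
#' @export
search_phmm <- function(hmm, prot, bit_threshold = 10) {
  bits <- phmm_score(hmm, prot$seqs, "forward")
  keep <- which(bits >= bit_threshold)
  ids <- names(prot$seqs)[keep]
  ord <- order(-bits[keep], ids)
  data.frame(protein = ids[ord],
             taxon = rep(prot$taxon, length(ord)),
             bits = unname(bits[keep][ord]),
             rank = seq_along(ord),
             stringsAsFactors = FALSE)
}

#' Serialize a profile HMM to JSON
#'
#' The JSON layout (versioned, documented here) allows re-using a trained
#' model library across runs: fields `format`, `length`, `alphabet`,
#' `match_emissions` (row-major probabilities), `transitions` (per-boundary
#' probability vectors), `background`, `trained_from`.
#'
#' @param hmm a `profile_hmm`.
#' @param path output file.
#' @export
write_phmm <- function(hmm, path) {
  obj <- list(format = "orthoscout-phmm-1",
              length = hmm$length,
              alphabet = paste(hmm$alphabet, collapse = ""),
              match_emissions = unname(apply(hmm$em_probs, 1, as.numeric,
                                             simplify = FALSE)),
              transitions = lapply(hmm$trans, as.numeric),
              background = as.numeric(hmm$bg),
              pseudocount = hmm$pseudocount,
              trained_from = hmm$trained_from)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a profile HMM from JSON
#' @param path file written by [write_phmm()].
#' @return a `profile_hmm`.
#' @export
read_phmm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "orthoscout-phmm-1"))
    stop("unrecognized profile HMM format: ", obj$format)
  alphabet <- strsplit(obj$alphabet, "")[[1]]
  em <- if (is.matrix(obj$match_emissions)) obj$match_emissions
        else do.call(rbind, lapply(obj$match_emissions, as.numeric))
  colnames(em) <- alphabet
  structure(list(length = obj$length,
                 alphabet = alphabet,
                 em_probs = em,
                 trans = lapply(obj$transitions, as.numeric),
                 bg = stats::setNames(as.numeric(obj$background), alphabet),
                 pseudocount = obj$pseudocount,
                 match_columns = NULL,
                 trained_from = obj$trained_from),
            class = "profile_hmm")
}
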