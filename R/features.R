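# Recognized feature namespaces (prefix before the colon in a feature type).
# Unknown namespaces are kept with a warning on read.
.KNOWN_NAMESPACES <- c("PFAM", "SMART", "TM", "SP", "COILS", "LCR", "FLPS")

#' Construct a feature architecture
#'
#' An architecture is the ordered list of annotated feature instances
#' (domains, transmembrane helices, signal peptides, coiled coils,
#' low-complexity regions, ...) along a protein. Instances from different
#' namespaces may overlap.
#'
#' @param protein protein id.
#' @param length protein length in residues.
#' @param instances data.frame with columns `type` (namespaced identifier,
#'   e.g. "PFAM:PF00759"), `start`, `end` (1-based inclusive).
#' @return an `architecture` object, instances ordered by start.
#' @export
architecture <- function(protein, length, instances = NULL) {
  if (is.null(instances) || nrow(instances) == 0L) {
    instances <- data.frame(type = character(0), start = integer(0),
                            end = integer(0), stringsAsFactors = FALSE)
  } else {
    instances <- data.frame(type = as.character(instances$type),
                            start = as.integer(instances$start),
                            end = as.integer(instances$end),
                            stringsAsFactors = FALSE)
    bad <- instances$start < 1L | instances$start > instances$end |
      instances$end > length
    if (any(bad)) {
      stop("feature coordinates out of range for ", protein, ": ",
           paste(instances$type[bad], collapse = ", "))
    }
    instances <- instances[order(instances$start, instances$end,
                                 instances$type), , drop = FALSE]
    rownames(instances) <- NULL
  }
  structure(list(protein = as.character(protein), length = as.integer(length),
                 instances = instances),
            class = "architecture")
}

#' @export
print.architecture <- function(x, ...) {
  cat("architecture:", x$protein, "(", x$length, "aa ) -",
      nrow(x$instances), "feature instance(s)\n")
  invisible(x)
}

#' Read feature architectures from JSON
#'
#' Schema (`orthoscout-arch-1`): a top-level object mapping protein ids to
#' `{"length": n, "features": [{"type": ..., "start": ..., "end": ...}]}`.
#' Writing then reading is the identity.
#'
#' @param path JSON file.
#' @return named list of `architecture` objects.
#' @export
read_architectures <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(names(obj), function(id) {
    rec <- obj[[id]]
    inst <- NULL
    if (length(rec$features)) {
      inst <- do.call(rbind, lapply(rec$features, function(f) {
        data.frame(type = f$type, start = f$start, end = f$end,
                   stringsAsFactors = FALSE)
      }))
      ns <- sub(":.*$", "", inst$type)
      unk <- setdiff(unique(ns), .KNOWN_NAMESPACES)
      if (length(unk)) {
        warning("unknown feature namespace(s) kept: ",
                paste(unk, collapse = ", "))
      }
    }
    architecture(id, rec$length, inst)
  })
  stats::setNames(out, names(obj))
}

#' Write feature architectures to JSON
#' @param archs named list of `architecture` objects.
#' @param path output file.
#' @export
write_architectures <- function(archs, path) {
  obj <- lapply(archs, function(a) {
    feats <- lapply(seq_len(nrow(a$instances)), function(i) {
      list(type = a$instances$type[i], start = a$instances$start[i],
           end = a$instances$end[i])
    })
    list(length = a$length, features = feats)
  })
  names(obj) <- vapply(archs, function(a) a$protein, character(1))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Jaccard overlap of two instances after normalizing coordinates by the
# protein lengths, so that orthologs of different lengths are comparable.
.norm_overlap <- function(s1, e1, len1, s2, e2, len2) {
  a1 <- (s1 - 1) / len1; b1 <- e1 / len1
  a2 <- (s2 - 1) / len2; b2 <- e2 / len2
  inter <- max(0, min(b1, b2) - max(a1, a2))
  uni <- max(b1, b2) - min(a1, a2)
  if (uni <= 0) return(0)
  inter / uni
}

#' Feature architecture similarity (FAS) score
#'
#' Asymmetric architecture similarity in \[0, 1\]. For each feature type t
#' present in the *reference*, the type score is the multiplicity coverage
#' min(n_ref(t), n_qry(t)) / n_ref(t) multiplied by a positional term
#' (1 + o) / 2, where o is the mean, over reference instances of t, of the
#' best positional overlap with a query instance of t (Jaccard on
#' length-normalized residue intervals). The positional term maps perfect
#' overlap to 1 and is bounded below by 1/2, so that sharing a feature type
#' always contributes: the score is exactly 0 only when no reference type
#' occurs in the query. Type scores are averaged with per-namespace
#' weights. Summing over reference types only
#' makes the score asymmetric: a query carrying every reference feature
#' scores 1 in the forward direction even if it carries extra features.
#' Identical architectures score 1; architectures sharing no feature type
#' score 0.
#'
#' This scoring is this package's own surrogate for the published FAS
#' algorithm: it implements the same contract (asymmetry, \[0, 1\] range,
#' boundary values) but not the published algorithm's internals.
#'
#' @param reference,query `architecture` objects.
#' @param weights named numeric vector of per-namespace weights (default 1
#'   for every namespace).
#' @return numeric score in \[0, 1\]. An empty reference scores 1 against an
#'   empty query (identical) and 0 otherwise by the no-shared-type rule
#'   applied to the reverse direction; by convention an empty reference
#'   returns 1 (nothing to recover).
#' @export
fas_score <- function(reference, query, weights = NULL) {
  ri <- reference$instances
  qi <- query$instances
  if (nrow(ri) == 0L) return(1)
  types <- unique(ri$type)
  ns <- sub(":.*$", "", types)
  w <- rep(1, length(types))
  if (!is.null(weights)) {
    has <- ns %in% names(weights)
    w[has] <- weights[ns[has]]
  }
  s <- vapply(seq_along(types), function(k) {
    t <- types[k]
    rk <- ri[ri$type == t, , drop = FALSE]
    qk <- qi[qi$type == t, , drop = FALSE]
    n_ref <- nrow(rk); n_qry <- nrow(qk)
    if (n_qry == 0L) return(0)
    cov <- min(n_ref, n_qry) / n_ref
    best <- vapply(seq_len(n_ref), function(i) {
      max(vapply(seq_len(n_qry), function(j) {
        .norm_overlap(rk$start[i], rk$end[i], reference$length,
                      qk$start[j], qk$end[j], query$length)
      }, numeric(1)))
    }, numeric(1))
    cov * (1 + mean(best)) / 2
  }, numeric(1))
  out <- sum(w * s) / sum(w)
  min(max(out, 0), 1)
}

#' Bidirectional FAS scores
#'
#' FAS scores are not symmetric, so both directions are computed: `fas_f`
#' uses the seed protein as reference, `fas_b` the ortholog.
#'
#' @param seed,ortholog `architecture` objects.
#' @param weights per-namespace weights, see [fas_score()].
#' @return list with `fas_f` and `fas_b`.
#' @export
bidirectional_fas <- function(seed, ortholog, weights = NULL) {
  list(fas_f = fas_score(seed, ortholog, weights),
       fas_b = fas_score(ortholog, seed, weights))
}

#' Report feature architecture differences
#'
#' Lists feature types present only in the seed, only in the ortholog, and
#' types whose instance multiplicity changed, grouped by namespace. The
#' direction semantics mirror [fas_score()]: "lost" features depress the
#' forward score, "gained" features the backward score.
#'
#' @param seed,ortholog `architecture` objects.
#' @return data.frame with columns `type`, `namespace`, `n_seed`,
#'   `n_ortholog`, `change` (one of "lost", "gained", "multiplicity").
#'   Identical type multisets give a zero-row report.
#' @export
architecture_diff <- function(seed, ortholog) {
  ts <- table(seed$instances$type)
  to <- table(ortholog$instances$type)
  types <- sort(union(names(ts), names(to)))
  n_s <- as.integer(ifelse(types %in% names(ts), ts[types], 0L))
  n_o <- as.integer(ifelse(types %in% names(to), to[types], 0L))
  keep <- n_s != n_o
  types <- types[keep]; n_s <- n_s[keep]; n_o <- n_o[keep]
  change <- ifelse(n_o == 0L, "lost",
                   ifelse(n_s == 0L, "gained", "multiplicity"))
  data.frame(type = types,
             namespace = sub(":.*$", "", types),
             n_seed = n_s, n_ortholog = n_o,
             change = change, stringsAsFactors = FALSE)
}
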