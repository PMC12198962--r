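#' Construct a phylogenetic profile matrix
#'
#' A seeds-by-taxa container of ortholog records. Cells are the record rows
#' matching a (seed, taxon) pair; empty cells are simply absent rows.
#'
#' @param records data.frame of ortholog records (columns `seed`, `taxon`,
#'   `protein`, `hmm_bits`, `kimura`, `fas_f`, `fas_b`,
#'   `is_representative`, `co_ortholog_rank`).
#' @param seeds ordered seed protein ids (defaults to those present).
#' @param taxa ordered taxon ids (defaults to those present).
#' @return a `profile_matrix` object.
#' @export
profile_matrix <- function(records, seeds = NULL, taxa = NULL) {
  seeds <- as.character(seeds %||% sort(unique(records$seed)))
  taxa <- as.integer(taxa %||% sort(unique(records$taxon)))
  stray <- !(records$seed %in% seeds) | !(records$taxon %in% taxa)
  if (any(stray)) stop("records reference seeds/taxa outside the matrix")
  structure(list(records = records, seeds = seeds, taxa = taxa),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("profile_matrix:", length(x$seeds), "seed(s) x", length(x$taxa),
      "taxa,", nrow(x$records), "ortholog record(s)\n")
  invisible(x)
}

# Per-record FAS under a direction mode.
.fas_of <- function(records, mode = c("mean", "forward", "backward")) {
  mode <- match.arg(mode)
  switch(mode,
         forward = records$fas_f,
         backward = records$fas_b,
         mean = (records$fas_f + records$fas_b) / 2)
}

#' Filter profile records by FAS score
#'
#' Removes ortholog records whose FAS score under the selected direction
#' mode falls below the threshold, a post hoc stringency control on the
#' ortholog assignments.
#'
#' @param matrix a `profile_matrix`.
#' @param threshold FAS threshold in \[0, 1\].
#' @param mode `"forward"` (seed as reference), `"backward"` (ortholog as
#'   reference), or `"mean"`.
#' @return the filtered `profile_matrix` (same seeds/taxa).
#' @export
filter_by_fas <- function(matrix, threshold,
                          mode = c("mean", "forward", "backward")) {
  stopifnot(threshold >= 0, threshold <= 1)
  sel <- .fas_of(matrix$records, match.arg(mode)) >= threshold
  sel[is.na(sel)] <- FALSE
  out <- matrix$records[sel | threshold == 0, , drop = FALSE]
  rownames(out) <- NULL
  profile_matrix(out, matrix$seeds, matrix$taxa)
}

#' Binarize a profile matrix
#'
#' Records with a FAS score below `fas_min` are dropped, and each (taxon,
#' seed) cell becomes 1 if at least one ortholog remains, otherwise 0.
#'
#' @param matrix a `profile_matrix`.
#' @param fas_min FAS threshold (default 0.3; records *below* it are
#'   dropped, a record at exactly `fas_min` is kept).
#' @param mode FAS direction mode (default `"mean"`).
#' @return integer 0/1 matrix, taxa as rows, seeds as columns.
#' @export
binarize <- function(matrix, fas_min = 0.3,
                     mode = c("mean", "forward", "backward")) {
  mode <- match.arg(mode)
  rec <- matrix$records
  if (nrow(rec)) {
    fas <- .fas_of(rec, mode)
    fas[is.na(fas)] <- 1  # unscored records count as present
    rec <- rec[fas >= fas_min, , drop = FALSE]
  }
  out <- base::matrix(0L, nrow = length(matrix$taxa),
                      ncol = length(matrix$seeds),
                      dimnames = list(as.character(matrix$taxa),
                                      matrix$seeds))
  if (nrow(rec)) {
    out[cbind(as.character(rec$taxon), rec$seed)] <- 1L
  }
  out
}

# Pairwise Jaccard distance between binary rows; a pair of all-zero rows
# has distance 0 (identical repertoires), zero vs non-zero has distance 1.
.jaccard_dist <- function(x) {
  x <- x > 0
  inter <- tcrossprod(x * 1)
  size <- rowSums(x)
  uni <- outer(size, size, `+`) - inter
  d <- 1 - inter / uni
  d[uni == 0] <- 0
  stats::as.dist(d)
}

#' Embed taxa in two dimensions by repertoire similarity
#'
#' Projects the binary presence/absence vectors of the taxa into 2-D so
#' that taxa with similar ortholog repertoires are placed near each other.
#' The default is a classical metric scaling (principal coordinates) of the
#' Jaccard distances; `method = "nmds"` refines it by non-metric
#' multidimensional scaling (vegan). Both are deterministic for a fixed
#' `rng_seed`.
#'
#' @param bin integer 0/1 matrix from [binarize()] (taxa rows).
#' @param method `"pcoa"` or `"nmds"`.
#' @param metric distance metric; only `"jaccard"` is implemented.
#' @param rng_seed seed for the stochastic refinement.
#' @return data.frame with columns `taxon`, `x`, `y`, `n_seeds` (count of
#'   seeds present); embedding parameters in `attr(, "params")`.
#' @export
embed_profiles <- function(bin, method = c("pcoa", "nmds"),
                           metric = "jaccard", rng_seed = 42L) {
  method <- match.arg(method)
  if (!identical(metric, "jaccard")) stop("unsupported metric: ", metric)
  if (nrow(bin) < 2L) stop("need at least 2 taxa to embed")
  d <- .jaccard_dist(bin)
  co <- suppressWarnings(stats::cmdscale(d, k = 2))
  if (ncol(co) < 2L) co <- cbind(co, 0)[, 1:2, drop = FALSE]
  if (method == "nmds") {
    if (!requireNamespace("vegan", quietly = TRUE))
      stop("method 'nmds' requires the vegan package")
    co <- with_seed(rng_seed, {
      fit <- vegan::monoMDS(d, y = co, k = 2)
      fit$points[, 1:2, drop = FALSE]
    })
  }
  out <- data.frame(taxon = rownames(bin), x = co[, 1], y = co[, 2],
                    n_seeds = rowSums(bin), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "params") <- list(method = method, metric = metric,
                              rng_seed = rng_seed)
  out
}

#' Select the representative of a group of paralogous seeds
#'
#' For paralogous seed proteins from the same seed species, approximates
#' the origin of the gene duplication by the closest relative of the seed
#' species in which one target protein is found as ortholog to at least two
#' of the seeds; the representative seed is the one with the most orthologs
#' among taxa descending from the focal lineage (ties by seed id).
#'
#' @param paralog_seeds character vector of seed ids (>= 2) from the same
#'   seed species.
#' @param matrix a `profile_matrix`.
#' @param tree a `taxonomy_tree`.
#' @param seed_taxon taxon id of the seed species.
#' @param focal_lineage taxon id of the lineage in which ortholog counts
#'   determine the representative.
#' @return list with `representative`, `origin_taxon` (closest relative
#'   sharing an ortholog, or `NA`), `origin_distance`, and `origin_scope`
#'   (`"shared"` or `"within seed species"`).
#' @export
select_paralog_representative <- function(paralog_seeds, matrix, tree,
                                          seed_taxon, focal_lineage) {
  stopifnot(length(paralog_seeds) >= 2L)
  rec <- matrix$records[matrix$records$seed %in% paralog_seeds, , drop = FALSE]
  # taxa where one protein id is ortholog to >= 2 seeds
  shared <- vapply(split(rec, rec$taxon), function(df) {
    any(vapply(split(df$seed, df$protein),
               function(s) length(unique(s)) >= 2L, logical(1)))
  }, logical(1))
  shared_taxa <- as.integer(names(shared))[shared]
  if (length(shared_taxa)) {
    d <- taxonomic_distances(tree, seed_taxon, shared_taxa)
    ord <- order(d, shared_taxa)
    origin <- shared_taxa[ord[1L]]
    origin_d <- d[ord[1L]]
    scope <- "shared"
  } else {
    origin <- NA_integer_; origin_d <- NA_integer_
    scope <- "within seed species"
  }
  focal_taxa <- Filter(function(tx) is_ancestor_or_self(tree, focal_lineage, tx),
                       matrix$taxa)
  counts <- vapply(paralog_seeds, function(s) {
    sub <- rec[rec$seed == s & rec$taxon %in% focal_taxa, , drop = FALSE]
    length(unique(sub$taxon))
  }, integer(1))
  ord <- order(-counts, paralog_seeds)
  list(representative = paralog_seeds[ord[1L]],
       origin_taxon = origin, origin_distance = origin_d,
       origin_scope = scope)
}

#' Rank taxa by the diversity of their repertoires
#'
#' Counts, per taxon, the distinct seed families with at least one ortholog
#' present in the binary matrix and ranks taxa by decreasing count (ties in
#' taxon-id order).
#'
#' @param bin 0/1 matrix from [binarize()].
#' @param seed_families named character vector mapping seed id to family.
#' @return data.frame `taxon`, `n_families`, `rank`, sorted.
#' @export
rank_taxa_by_repertoire <- function(bin, seed_families) {
  fam <- seed_families[colnames(bin)]
  counts <- apply(bin, 1, function(row) length(unique(fam[row > 0])))
  ord <- order(-counts, rownames(bin))
  out <- data.frame(taxon = rownames(bin)[ord],
                    n_families = as.integer(counts[ord]),
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a profile matrix in the PhyloProfile tabular layout
#'
#' Tab-separated columns `geneID`, `ncbiID`, `orthoID`, `FAS_F`, `FAS_B`
#' (one row per ortholog record, taxon ids prefixed "ncbi"), directly
#' loadable by the PhyloProfile viewer. A small JSON configuration file
#' describing the upload is written alongside.
#'
#' @param matrix a `profile_matrix`.
#' @param path output TSV path; the configuration file is written to
#'   `<path>.config.json`.
#' @export
write_phyloprofile <- function(matrix, path) {
  rec <- matrix$records
  out <- data.frame(geneID = rec$seed,
                    ncbiID = paste0("ncbi", rec$taxon),
                    orthoID = rec$protein,
                    FAS_F = rec$fas_f, FAS_B = rec$fas_b,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- list(mainInput = basename(path),
              var1 = "FAS_F", var2 = "FAS_B",
              var1_range = c(0, 1), var2_range = c(0, 1))
  jsonlite::write_json(cfg, paste0(path, ".config.json"), auto_unbox = TRUE)
  invisible(path)
}
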