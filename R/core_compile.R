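#' Options for the core-group compilation phase
#'
#' @param core_size total size of the core ortholog group including the
#'   seed (default 6 = seed + 5 iterations).
#' @param min_dist minimal taxonomic distance (rank name) of primer taxa
#'   from the seed taxon and from each other (default "genus").
#' @param max_dist maximal taxonomic distance of primer taxa from the seed
#'   taxon (default "superkingdom").
#' @param dist_deviation margin of the soft max-score stopping rule: a
#'   candidate whose total score is within this fraction of the maximal
#'   score 2 is accepted without visiting more distant clades (default
#'   0.05).
#' @param core_taxa optional taxon-id subset from which primer taxa may be
#'   drawn.
#' @param rng_seed integer seed driving the randomized traversal order of
#'   equidistant taxa.
#' @param bit_threshold minimum profile-HMM hit score in bits.
#' @param pseudocount Laplace pseudocount for profile HMM training.
#' @param hard_stop,soft_stop,fas_skip enable the hard max-score cut-off,
#'   the soft max-score cut-off, and the FAS computation shortcut. All
#'   default to TRUE; disabling all three yields the exhaustive scoring
#'   used by validation oracles.
#' @return a `compile_options` list.
#' @export
compile_options <- function(core_size = 6L, min_dist = "genus",
                            max_dist = "superkingdom", dist_deviation = 0.05,
                            core_taxa = NULL, rng_seed = 42L,
                            bit_threshold = 10, pseudocount = 1,
                            hard_stop = TRUE, soft_stop = TRUE,
                            fas_skip = TRUE) {
  stopifnot(core_size >= 1L, dist_deviation >= 0, dist_deviation < 1)
  rank_index(min_dist); rank_index(max_dist)  # validate rank names
  structure(list(core_size = as.integer(core_size), min_dist = min_dist,
                 max_dist = max_dist, dist_deviation = dist_deviation,
                 core_taxa = core_taxa, rng_seed = as.integer(rng_seed),
                 bit_threshold = bit_threshold, pseudocount = pseudocount,
                 hard_stop = hard_stop, soft_stop = soft_stop,
                 fas_skip = fas_skip),
            class = "compile_options")
}

#' Combined candidate score
#'
#' The maximization target of the core compilation: the alignment-score
#' ratio against the seed plus the mean of the two directional feature
#' architecture similarities, `as_ratio + (fas_f + fas_b) / 2`. The maximal
#' possible value is 2.
#'
#' @param as_ratio alignment score of the candidate against the seed,
#'   divided by the seed self score (in (0, 1] for homologous pairs).
#' @param fas_f,fas_b directional FAS scores in \[0, 1\].
#' @return numeric total score in \[0, 2\].
#' @export
candidate_total_score <- function(as_ratio, fas_f, fas_b) {
  as_ratio + 0.5 * (fas_f + fas_b)
}

#' May the FAS computation be skipped for a candidate?
#'
#' The FAS computation is skipped when even the maximal FAS contribution of
#' 1 could not lift the candidate above the current best total score.
#' Skipped candidates are never selected.
#'
#' @param as_ratio candidate alignment-score ratio.
#' @param best_total_so_far best total score seen in this iteration.
#' @return logical.
#' @export
fas_skip_allowed <- function(as_ratio, best_total_so_far) {
  as_ratio + 1 < best_total_so_far
}

#' Early-stopping decision for a scored candidate
#'
#' A candidate is accepted immediately when (i) it reaches the maximally
#' possible score of 2 (hard max-score cut-off), or (ii) its total score is
#' within the `dist_deviation` margin of 2, so that no sequence from a
#' taxonomically more distant clade could supersede it by that margin
#' (soft max-score cut-off).
#'
#' @param total candidate total score.
#' @param remaining unvisited distance classes (informational; the soft
#'   rule's premise is that only more distant clades remain).
#' @param dist_deviation soft-rule margin (default 0.05).
#' @param hard_stop,soft_stop rule toggles.
#' @return `"accept_now"` or `"keep_searching"`.
#' @export
early_stop_decision <- function(total, remaining = integer(0),
                                dist_deviation = 0.05, hard_stop = TRUE,
                                soft_stop = TRUE) {
  if (hard_stop && abs(total - 2) <= 1e-9) return("accept_now")
  if (soft_stop && total >= 2 * (1 - dist_deviation)) return("accept_now")
  "keep_searching"
}

#' @export
print.core_group <- function(x, ...) {
  cat("core_group: seed", x$seed$id, "(taxon", x$seed$taxon, "),",
      nrow(x$members), "members,", x$hmm$length, "match states\n")
  invisible(x)
}

#' Compile a core ortholog group from a single seed protein
#'
#' The iterative training phase. The core group C starts as the seed alone
#' and the primer-taxon set P as the seed taxon. In each iteration the
#' active search taxa are visited in order of increasing taxonomic distance
#' to the seed taxon (equidistant taxa in seeded random order); in each
#' taxon a targeted ortholog search with the current profile HMM proposes
#' candidates, which are scored with [candidate_total_score()]. The best
#' candidate (ties: smallest taxonomic distance, then protein id) joins C,
#' its taxon joins P, the group is re-aligned and the model re-trained, and
#' the selected taxon plus all taxa closer than `min_dist` to it or to the
#' seed taxon are pruned. Compilation stops when the group reaches
#' `core_size`, the active taxon set is empty, or an iteration finds no
#' ortholog.
#'
#' @param seed a `protein` (the seed c0).
#' @param proteomes named list of `proteome` objects (names = taxon ids);
#'   must include the seed taxon.
#' @param tree a `taxonomy_tree` covering all proteome taxa.
#' @param architectures named list of `architecture` objects, or `NULL`.
#' @param opts a [compile_options()] list.
#' @param params alignment scoring parameters.
#' @return a `core_group`: `seed`, `members` (data.frame id, taxon,
#'   as_ratio, fas_f, fas_b, total), `primer_taxa`, `alignment`, `hmm`,
#'   `log` (per-candidate decisions), `seqs`.
#' @export
compile_core_group <- function(seed, proteomes, tree, architectures = NULL,
                               opts = compile_options(),
                               params = align_params()) {
  p0 <- seed$taxon
  own <- proteomes[[as.character(p0)]]
  if (is.null(own) || !(seed$id %in% names(own$seqs)))
    stop("seed protein ", seed$id, " absent from its proteome")
  self0 <- self_score(seed$seq, params)

  # S = all proteome taxa except p0, restricted to tree leaves and bounds
  search_tree <- restrict_to_leaves(
    tree, intersect(tree_leaves(tree), as.integer(names(proteomes))))
  search_tree <- prune_rank_bounds(search_tree, p0, opts$min_dist,
                                   opts$max_dist)
  if (!is.null(opts$core_taxa)) {
    search_tree <- restrict_to_leaves(
      search_tree, intersect(tree_leaves(search_tree),
                             as.integer(opts$core_taxa)))
  }

  members <- data.frame(id = seed$id, taxon = p0, as_ratio = 1,
                        fas_f = 1, fas_b = 1, total = 2,
                        stringsAsFactors = FALSE)
  seqs <- stats::setNames(seed$seq, seed$id)
  alignment <- seqs
  hmm <- train_phmm(alignment, opts$pseudocount)
  group <- structure(list(seed = seed, members = members,
                          primer_taxa = p0, alignment = alignment,
                          hmm = hmm, seqs = seqs),
                     class = "core_group")
  log_rows <- list()
  iter <- 0L
  cache <- new.env(parent = emptyenv())  # reciprocity/alignment memo

  while (nrow(group$members) < opts$core_size &&
         length(tree_leaves(search_tree)) > 0L) {
    iter <- iter + 1L
    active <- tree_leaves(search_tree)
    ord <- traversal_order(tree, p0, opts$rng_seed + iter, leaves = active)
    dists <- stats::setNames(taxonomic_distances(tree, p0, ord), ord)
    best <- NULL  # list(total, dist, id, taxon, seq, as_ratio, fas_f, fas_b)
    stop_now <- FALSE
    for (tx in ord) {
      recs <- search_taxon(group, proteomes[[as.character(tx)]], own,
                           architectures, opts$bit_threshold, params,
                           compute_fas = FALSE, cache = cache)
      if (nrow(recs) == 0L) next
      recs <- recs[order(recs$protein), , drop = FALSE]
      for (i in seq_len(nrow(recs))) {
        as_ratio <- recs$seed_score[i] / self0
        if (opts$fas_skip &&
            fas_skip_allowed(as_ratio, if (is.null(best)) -Inf else best$total)) {
          log_rows[[length(log_rows) + 1L]] <- data.frame(
            iteration = iter, taxon = tx, protein = recs$protein[i],
            as_ratio = as_ratio, fas_f = NA_real_, fas_b = NA_real_,
            total = NA_real_, decision = "fas_skipped",
            stringsAsFactors = FALSE)
          next
        }
        cand_seq <- proteomes[[as.character(tx)]]$seqs[[recs$protein[i]]]
        seed_arch <- architectures[[seed$id]] %||%
          architecture(seed$id, nchar(seed$seq))
        cand_arch <- architectures[[recs$protein[i]]] %||%
          architecture(recs$protein[i], nchar(cand_seq))
        fp <- bidirectional_fas(seed_arch, cand_arch)
        total <- candidate_total_score(as_ratio, fp$fas_f, fp$fas_b)
        d <- dists[[as.character(tx)]]
        is_better <- if (is.null(best)) TRUE else {
          if (total > best$total + 1e-9) TRUE
          else if (abs(total - best$total) <= 1e-9) {
            if (d < best$dist) TRUE
            else if (d == best$dist && recs$protein[i] < best$id) TRUE
            else FALSE
          } else FALSE
        }
        decision <- "scored"
        if (is_better) {
          best <- list(total = total, dist = d, id = recs$protein[i],
                       taxon = tx, seq = cand_seq, as_ratio = as_ratio,
                       fas_f = fp$fas_f, fas_b = fp$fas_b)
          decision <- "best_so_far"
          es <- early_stop_decision(total, dist_deviation = opts$dist_deviation,
                                    hard_stop = opts$hard_stop,
                                    soft_stop = opts$soft_stop)
          if (es == "accept_now") {
            decision <- "accepted_early"
            stop_now <- TRUE
          }
        }
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          iteration = iter, taxon = tx, protein = recs$protein[i],
          as_ratio = as_ratio, fas_f = fp$fas_f, fas_b = fp$fas_b,
          total = total, decision = decision, stringsAsFactors = FALSE)
        if (stop_now) break
      }
      if (stop_now) break
    }
    if (is.null(best)) break  # termination (iii): no ortholog found
    group$members <- rbind(group$members, data.frame(
      id = best$id, taxon = best$taxon, as_ratio = best$as_ratio,
      fas_f = best$fas_f, fas_b = best$fas_b, total = best$total,
      stringsAsFactors = FALSE))
    group$primer_taxa <- c(group$primer_taxa, best$taxon)
    group$seqs <- c(group$seqs, stats::setNames(best$seq, best$id))
    group$alignment <- align_core_group(group$seqs, params)
    group$hmm <- train_phmm(group$alignment, opts$pseudocount)
    search_tree <- prune_after_iteration(search_tree, p0, best$taxon,
                                         opts$min_dist, full_tree = tree)
  }
  group$log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(iteration = integer(0), taxon = integer(0),
               protein = character(0), as_ratio = numeric(0),
               fas_f = numeric(0), fas_b = numeric(0), total = numeric(0),
               decision = character(0), stringsAsFactors = FALSE)
  group
}

#' Write core-group outputs to a directory
#'
#' Emits the core-group FASTA, the aligned FASTA, the trained profile HMM
#' (JSON), and the per-candidate score log (TSV).
#'
#' @param group a `core_group`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_core_group <- function(group, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(group$seqs, file.path(dir, "core_group.fa"))
  write_fasta(group$alignment, file.path(dir, "core_group_aligned.fa"))
  write_phmm(group$hmm, file.path(dir, "core_group.phmm.json"))
  utils::write.table(group$log, file.path(dir, "score_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(group$members, file.path(dir, "members.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
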