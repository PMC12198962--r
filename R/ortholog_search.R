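#' Reciprocity check of an ortholog candidate
#'
#' The candidate is searched against the proteome of a reference species
#' represented in the core group. It passes if the core ortholog is its
#' best hit; if the best hit is another protein, it still passes when the
#' evolutionary (Kimura) distance between the core ortholog and that best
#' hit is smaller than the distance between the candidate and the best hit.
#'
#' @param candidate candidate sequence (character) or `protein`.
#' @param reference a `proteome` (the reference species).
#' @param core_id protein id of the core ortholog inside `reference`.
#' @param params alignment scoring parameters.
#' @return list with `accept` (logical), `best_hit`, and the two Kimura
#'   distances entering the inequality (`NA` when the best hit decides).
#' @export
reciprocity_check <- function(candidate, reference, core_id,
                              params = align_params()) {
  if (is.list(candidate)) candidate <- candidate$seq
  if (!(core_id %in% names(reference$seqs)))
    stop("core protein ", core_id, " absent from reference proteome")
  sc <- align_scores_many(reference$seqs, candidate, params)
  ord <- order(-sc, names(sc))
  best <- names(sc)[ord[1L]]
  if (best == core_id) {
    return(list(accept = TRUE, best_hit = best,
                d_core_best = NA_real_, d_cand_best = NA_real_))
  }
  d_core <- kimura_between(reference$seqs[[core_id]], reference$seqs[[best]],
                           params)
  d_cand <- kimura_between(candidate, reference$seqs[[best]], params)
  list(accept = d_core < d_cand, best_hit = best,
       d_core_best = d_core, d_cand_best = d_cand)
}

#' Select the representative ortholog of a taxon
#'
#' Among accepted candidates, the representative is the one minimizing the
#' Kimura distance to the seed protein; ties are broken by protein id.
#'
#' @param accepted data.frame with columns `protein` and `kimura`.
#' @return the protein id of the representative.
#' @export
select_representative <- function(accepted) {
  if (nrow(accepted) == 0L) stop("no accepted candidates")
  ord <- order(accepted$kimura, accepted$protein)
  accepted$protein[ord[1L]]
}

#' Filter co-orthologs against the representative
#'
#' Retains a candidate only if its Kimura distance to the representative is
#' at most the distance between the representative and the seed, which
#' drops putative out-paralogs. The representative itself is always
#' retained (distance 0).
#'
#' @param accepted data.frame with columns `protein`, `kimura`, `seq`.
#' @param representative protein id of the representative.
#' @param seed_seq seed protein sequence.
#' @param params alignment scoring parameters.
#' @return the retained subset of `accepted`.
#' @export
filter_coorthologs <- function(accepted, representative, seed_seq,
                               params = align_params()) {
  rep_row <- match(representative, accepted$protein)
  if (is.na(rep_row)) stop("representative not among accepted candidates")
  d_rep_seed <- accepted$kimura[rep_row]
  keep <- vapply(seq_len(nrow(accepted)), function(i) {
    if (i == rep_row) return(TRUE)
    d <- kimura_between(accepted$seq[i], accepted$seq[rep_row], params)
    d <= d_rep_seed
  }, logical(1))
  accepted[keep, , drop = FALSE]
}

#' Targeted ortholog search in one taxon
#'
#' Runs the profile HMM over the taxon's proteome, validates every hit with
#' the reciprocity criterion against the reference species, selects the
#' representative ortholog, filters co-orthologs, and (optionally) scores
#' bidirectional feature architecture similarity for every retained record.
#'
#' @param group a `core_group` (needs at least `$hmm`, `$seed`).
#' @param prot `proteome` of the searched taxon.
#' @param reference `proteome` of the reference species (default is the
#'   seed species' proteome, which must then be supplied here).
#' @param architectures named list of `architecture` objects (by protein
#'   id), or `NULL` to skip FAS scoring.
#' @param bit_threshold minimum profile-HMM hit score in bits.
#' @param params alignment scoring parameters.
#' @param compute_fas compute FAS for retained records (default TRUE when
#'   `architectures` are given).
#' @param cache optional environment memoizing reciprocity and seed
#'   alignment results per (taxon, protein); these do not depend on the
#'   current model, so the iterative training phase re-uses them across
#'   iterations.
#' @return data.frame of ortholog records: `seed`, `taxon`, `protein`,
#'   `hmm_bits`, `kimura`, `fas_f`, `fas_b`, `is_representative`,
#'   `co_ortholog_rank`, plus `seed_score` (alignment score to the seed).
#' @export
search_taxon <- function(group, prot, reference, architectures = NULL,
                         bit_threshold = 10, params = align_params(),
                         compute_fas = !is.null(architectures),
                         cache = NULL) {
  empty <- data.frame(seed = character(0), taxon = integer(0),
                      protein = character(0), hmm_bits = numeric(0),
                      kimura = numeric(0), fas_f = numeric(0),
                      fas_b = numeric(0), is_representative = logical(0),
                      co_ortholog_rank = integer(0), seed_score = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(prot$seqs) == 0L) return(empty)
  hits <- search_phmm(group$hmm, prot, bit_threshold)
  if (nrow(hits) == 0L) return(empty)
  seed_seq <- group$seed$seq
  acc <- lapply(seq_len(nrow(hits)), function(i) {
    id <- hits$protein[i]
    key <- paste0(prot$taxon, "\r", id)
    memo <- if (!is.null(cache)) cache[[key]] else NULL
    if (is.null(memo)) {
      rc <- reciprocity_check(prot$seqs[[id]], reference, group$seed$id,
                              params)
      memo <- list(accept = rc$accept)
      if (rc$accept) {
        al <- global_align(prot$seqs[[id]], seed_seq, params)
        memo$kimura <- kimura_distance(al)
        memo$seed_score <- al$score
      }
      if (!is.null(cache)) cache[[key]] <- memo
    }
    if (!memo$accept) return(NULL)
    data.frame(protein = id, hmm_bits = hits$bits[i],
               kimura = memo$kimura, seed_score = memo$seed_score,
               seq = prot$seqs[[id]], stringsAsFactors = FALSE)
  })
  acc <- do.call(rbind, acc)
  if (is.null(acc) || nrow(acc) == 0L) return(empty)
  rep_id <- select_representative(acc)
  kept <- filter_coorthologs(acc, rep_id, seed_seq, params)
  ord <- order(kept$kimura, kept$protein)
  kept <- kept[ord, , drop = FALSE]
  fas_f <- fas_b <- rep(NA_real_, nrow(kept))
  if (isTRUE(compute_fas)) {
    seed_arch <- architectures[[group$seed$id]] %||%
      architecture(group$seed$id, nchar(seed_seq))
    for (i in seq_len(nrow(kept))) {
      a <- architectures[[kept$protein[i]]] %||%
        architecture(kept$protein[i], nchar(kept$seq[i]))
      fp <- bidirectional_fas(seed_arch, a)
      fas_f[i] <- fp$fas_f; fas_b[i] <- fp$fas_b
    }
  }
  data.frame(seed = group$seed$id, taxon = prot$taxon,
             protein = kept$protein, hmm_bits = kept$hmm_bits,
             kimura = kept$kimura, fas_f = fas_f, fas_b = fas_b,
             is_representative = kept$protein == rep_id,
             co_ortholog_rank = seq_len(nrow(kept)),
             seed_score = kept$seed_score,
             stringsAsFactors = FALSE)
}

#' Full ortholog search across a taxon collection
#'
#' Runs the per-taxon targeted search for every core group across every
#' taxon. Taxa are partitioned into `n_workers` non-overlapping subsets
#' processed independently; the merged, sorted output is invariant under
#' the worker count. Per-taxon failures are logged and skipped, the run
#' continues.
#'
#' @param groups list of `core_group` objects (pre-trained models may be
#'   re-used across runs to extend profiles with new taxa).
#' @param proteomes named list of `proteome` objects (names = taxon ids).
#' @param reference_proteomes named list supplying the reference proteome
#'   per group seed taxon (typically includes the seed species).
#' @param architectures named list of `architecture` objects.
#' @param taxa optional subset of taxon ids to search (default: all in
#'   `proteomes` except each group's own seed taxon).
#' @param n_workers number of partitions.
#' @param bit_threshold minimum hit score in bits.
#' @param params alignment scoring parameters.
#' @return a `profile_matrix` (see [profile_matrix()]); failed taxa are
#'   recorded in `attr(, "failures")`.
#' @export
run_full_search <- function(groups, proteomes, reference_proteomes,
                            architectures = NULL, taxa = NULL,
                            n_workers = 1L, bit_threshold = 10,
                            params = align_params()) {
  all_taxa <- sort(as.integer(names(proteomes)))
  if (!is.null(taxa)) all_taxa <- all_taxa[all_taxa %in% as.integer(taxa)]
  chunks <- split(all_taxa, (seq_along(all_taxa) - 1L) %% max(1L, n_workers))
  failures <- list()
  rows <- list()
  for (ch in chunks) {
    for (tx in ch) {
      for (g in groups) {
        if (tx == g$seed$taxon) next
        res <- tryCatch(
          search_taxon(g, proteomes[[as.character(tx)]],
                       reference_proteomes[[as.character(g$seed$taxon)]],
                       architectures, bit_threshold, params),
          error = function(e) e)
        if (inherits(res, "error")) {
          failures[[length(failures) + 1L]] <-
            list(seed = g$seed$id, taxon = tx, message = conditionMessage(res))
          next
        }
        if (nrow(res)) rows[[length(rows) + 1L]] <- res
      }
    }
  }
  records <- if (length(rows)) do.call(rbind, rows) else
    search_taxon(groups[[1]], proteome(0L, character(0)), NULL)[0, ]
  records <- records[order(records$seed, records$taxon, records$protein), ,
                     drop = FALSE]
  rownames(records) <- NULL
  pm <- profile_matrix(records,
                       seeds = vapply(groups, function(g) g$seed$id,
                                      character(1)),
                       taxa = all_taxa)
  attr(pm, "failures") <- failures
  pm
}
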