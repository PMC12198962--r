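#' Specification of a synthetic evolutionary scenario
#'
#' Defines the taxonomy shape, gene-family count, per-family event rates
#' and sequence-evolution parameters of a generated fixture. The default
#' scenario is 16 eukaryote search species (2 classes x 1 order x 2
#' families x 2 genera x 2 species) plus 2 bacterial outgroup species,
#' with 20 gene families of ~60-residue proteins; a whole-pipeline run
#' completes in seconds.
#'
#' @param n_classes,orders_per_class,families_per_order,genera_per_family,species_per_genus
#'   branching factors of the eukaryote lineage.
#' @param n_bacteria bacterial outgroup species (HGT/contamination donors).
#' @param n_families gene families traced across the taxonomy.
#' @param protein_length ancestral protein length in residues.
#' @param subs_rate substitution probability per site and rank level
#'   (substitutions accumulate along the ranked tree, so sequence identity
#'   decays monotonically with taxonomic distance).
#' @param loss_rate probability that a family is lost in a given non-seed
#'   search taxon.
#' @param dup_after_rate probability that a family carries an extra
#'   in-paralog (post-speciation duplicate) in one random taxon.
#' @param n_dup_before number of family *pairs* arising from a duplication
#'   on the eukaryote stem: the bacteria retain one pre-duplication copy
#'   that is the common ortholog of both paralogous families.
#' @param n_hgt number of horizontally transferred genes (a bacterial copy
#'   inserted into a random eukaryote gene set, on a normal contig).
#' @param n_contaminants number of contaminant genes planted in the focal
#'   taxon, each on its own short single-gene contig.
#' @param arch_event_rate probability of a feature-architecture change
#'   (feature loss or multiplication) on a non-seed ortholog.
#' @param n_decoys random unrelated proteins added to every proteome.
#' @param rng_seed integer seed; the whole fixture is reproducible from it.
#' @return a `scenario_spec` list.
#' @export
scenario_spec <- function(n_classes = 2L, orders_per_class = 1L,
                          families_per_order = 2L, genera_per_family = 2L,
                          species_per_genus = 2L, n_bacteria = 2L,
                          n_families = 20L, protein_length = 60L,
                          subs_rate = 0.05, loss_rate = 0.1,
                          dup_after_rate = 0.1, n_dup_before = 1L,
                          n_hgt = 1L, n_contaminants = 3L,
                          arch_event_rate = 0.1, n_decoys = 5L,
                          rng_seed = 1L) {
  stopifnot(loss_rate >= 0, loss_rate <= 1, dup_after_rate >= 0,
            dup_after_rate <= 1, arch_event_rate >= 0, arch_event_rate <= 1,
            n_families >= 1L)
  if (2L * n_dup_before > n_families)
    stop("infeasible spec: more duplicated pairs than families")
  structure(as.list(environment()), class = "scenario_spec")
}

# Eukaryote lineage node ids: fixed offsets keep fixtures readable.
.SYN_ROOT <- 1L; .SYN_EUK <- 2L; .SYN_BACT <- 3L

# Build the taxonomy node table for a scenario.
synth_taxonomy <- function(spec) {
  nodes <- data.frame(id = c(.SYN_ROOT, .SYN_EUK, .SYN_BACT,
                             10L, 11L),
                      parent = c(NA, .SYN_ROOT, .SYN_ROOT, .SYN_EUK, 10L),
                      rank = c("no rank", "superkingdom", "superkingdom",
                               "kingdom", "phylum"),
                      name = c("cellular organisms", "Eukaryota", "Bacteria",
                               "Eukingdom", "Euphylum"),
                      stringsAsFactors = FALSE)
  add <- function(id, parent, rank, name) {
    nodes <<- rbind(nodes, data.frame(id = id, parent = parent, rank = rank,
                                      name = name, stringsAsFactors = FALSE))
  }
  sp <- 0L; ge <- 0L; fa <- 0L; or <- 0L
  for (cl in seq_len(spec$n_classes)) {
    add(100L + cl, 11L, "class", paste0("Class", cl))
    for (o in seq_len(spec$orders_per_class)) {
      or <- or + 1L
      add(200L + or, 100L + cl, "order", paste0("Order", or))
      for (f in seq_len(spec$families_per_order)) {
        fa <- fa + 1L
        add(300L + fa, 200L + or, "family", paste0("Family", fa))
        for (g in seq_len(spec$genera_per_family)) {
          ge <- ge + 1L
          add(400L + ge, 300L + fa, "genus", paste0("Genus", ge))
          for (s in seq_len(spec$species_per_genus)) {
            sp <- sp + 1L
            add(500L + sp, 400L + ge, "species", paste0("Species", sp))
          }
        }
      }
    }
  }
  for (b in seq_len(spec$n_bacteria)) {
    add(600L + b, .SYN_BACT, "species", paste0("Bacterium", b))
  }
  taxonomy_tree(nodes)
}

# depth on the rank ladder used for branch lengths (root = 8, species = 0)
.syn_depth <- function(rank) {
  if (rank %in% .RANK_LADDER) rank_index(rank) else 8L
}

# sample without the base-R length-1 surprise
.resample <- function(x, n) x[sample.int(length(x), n)]

.syn_random_seq <- function(n) {
  paste(sample(.AA20, n, replace = TRUE, prob = .BG_FREQ[.AA20]),
        collapse = "")
}

.syn_mutate <- function(seq, p) {
  if (p <= 0) return(seq)
  r <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(r)) < p
  if (any(hit)) {
    r[hit] <- vapply(r[hit], function(a) sample(setdiff(.AA20, a), 1L),
                     character(1))
  }
  paste(r, collapse = "")
}

# Evolve a sequence from a node down to all leaf descendants; returns a
# named vector leaf-taxon -> sequence. Branch substitution probability is
# subs_rate x (depth(parent) - depth(child)).
.syn_evolve <- function(tree, node, seq, subs_rate) {
  nodes <- tree$nodes
  children <- nodes$id[!is.na(nodes$parent) & nodes$parent == node]
  if (length(children) == 0L) return(stats::setNames(seq, node))
  d_par <- .syn_depth(nodes$rank[nodes$id == node])
  out <- list()
  for (ch in children) {
    d_ch <- .syn_depth(nodes$rank[nodes$id == ch])
    p <- subs_rate * max(0L, d_par - d_ch)
    out[[length(out) + 1L]] <- .syn_evolve(tree, ch, .syn_mutate(seq, p),
                                           subs_rate)
  }
  do.call(c, out)
}

# Architecture template for a family: one PFAM domain spanning most of the
# protein, plus (cyclically) a TM helix or a low-complexity region.
.syn_arch_template <- function(family, len) {
  inst <- data.frame(type = sprintf("PFAM:PF%05d", 10000L + family),
                     start = max(1L, round(len * 0.1)),
                     end = round(len * 0.85), stringsAsFactors = FALSE)
  if (family %% 3L == 0L) {
    inst <- rbind(inst, data.frame(type = "TM:helix", start = 2L,
                                   end = min(len, 21L)))
  } else if (family %% 3L == 1L) {
    inst <- rbind(inst, data.frame(type = "LCR:seg",
                                   start = max(1L, len - 9L), end = len))
  }
  inst
}

#' Generate a synthetic fixture
#'
#' Evolves `n_families` gene families along the scenario taxonomy with the
#' planted events and returns every input the pipeline consumes, plus the
#' ground-truth table used as the oracle of recovery tests.
#'
#' @param spec a [scenario_spec()].
#' @return a `synth_fixture` list: `tree`, `proteomes` (named by taxon id;
#'   bacteria included), `architectures`, `truth` (family, taxon, protein,
#'   relation in ortholog / in-paralog / hgt / contaminant / absent),
#'   `seed_taxon`, `seeds` (family -> seed protein id), `focal_taxon`,
#'   `hit_table`, `contig_map`, `contig_lengths`, `isoform_map`, `spec`.
#' @export
generate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  tree <- synth_taxonomy(spec)
  leaves <- tree_leaves(tree)
  euk <- leaves[leaves >= 500L & leaves < 600L]
  bact <- leaves[leaves >= 600L]
  seed_taxon <- euk[1L]
  focal_taxon <- euk[length(euk)]  # recipient of planted contaminations

  with_seed(spec$rng_seed, {
    pair_members <- if (spec$n_dup_before > 0L) {
      tail(seq_len(spec$n_families), 2L * spec$n_dup_before)
    } else integer(0)
    pairs <- if (length(pair_members))
      split(pair_members, rep(seq_len(spec$n_dup_before), each = 2L))
    else list()
    singles <- setdiff(seq_len(spec$n_families), pair_members)

    seqs <- list()   # per taxon: named character vectors
    for (tx in c(euk, bact)) seqs[[as.character(tx)]] <- character(0)
    truth <- list()
    archs <- list()
    pid <- function(tx, fam, suffix = "") sprintf("t%d_f%02d%s", tx, fam, suffix)

    add_gene <- function(tx, fam, seq, relation, suffix = "",
                         arch_events = TRUE) {
      id <- pid(tx, fam, suffix)
      seqs[[as.character(tx)]][id] <<- seq
      len <- nchar(seq)
      inst <- .syn_arch_template(fam, len)
      if (arch_events && stats::runif(1) < spec$arch_event_rate) {
        if (nrow(inst) > 1L && stats::runif(1) < 0.5) {
          inst <- inst[1L, , drop = FALSE]        # feature loss
        } else {                                   # feature multiplication
          extra <- inst[1L, , drop = FALSE]
          width <- extra$end - extra$start
          extra$start <- max(1L, extra$start - 2L)
          extra$end <- min(len, extra$start + width)
          inst <- rbind(inst, extra)
        }
      }
      archs[[id]] <<- architecture(id, len, inst)
      truth[[length(truth) + 1L]] <<- data.frame(
        family = fam, taxon = tx, protein = id, relation = relation,
        stringsAsFactors = FALSE)
      id
    }

    evolve_family <- function(fam, root_seq, euk_seq) {
      # bacteria: straight path root -> superkingdom -> species
      for (b in bact) {
        s <- .syn_mutate(root_seq, spec$subs_rate * 1)      # root -> SK
        s <- .syn_mutate(s, spec$subs_rate * 7)             # SK -> species
        add_gene(b, fam, s, "ortholog", arch_events = FALSE)
      }
      # eukaryotes: recurse down the ranked lineage from the superkingdom
      leafseqs <- .syn_evolve(tree, .SYN_EUK, euk_seq, spec$subs_rate)
      lost <- euk[euk != seed_taxon &
                  stats::runif(length(euk)) < spec$loss_rate]
      for (tx in euk) {
        if (tx %in% lost) {
          truth[[length(truth) + 1L]] <<- data.frame(
            family = fam, taxon = tx, protein = NA_character_,
            relation = "absent", stringsAsFactors = FALSE)
          next
        }
        add_gene(tx, fam, leafseqs[[as.character(tx)]], "ortholog",
                 arch_events = tx != seed_taxon)
      }
      # post-speciation duplication: an in-paralog in one random taxon
      if (stats::runif(1) < spec$dup_after_rate) {
        pool <- setdiff(setdiff(euk, lost), seed_taxon)
        if (length(pool)) {
          tx <- .resample(pool, 1L)
          base <- seqs[[as.character(tx)]][[pid(tx, fam)]]
          add_gene(tx, fam, .syn_mutate(base, spec$subs_rate), "in-paralog",
                   suffix = "_p2")
        }
      }
    }

    for (fam in singles) {
      root_seq <- .syn_random_seq(spec$protein_length)
      euk_seq <- .syn_mutate(root_seq, spec$subs_rate * 1)  # root -> SK
      evolve_family(fam, root_seq, euk_seq)
    }
    # duplication on the eukaryote stem: bacteria keep one copy, the two
    # paralogous families evolve from diverged duplicates of it
    for (pr in pairs) {
      root_seq <- .syn_random_seq(spec$protein_length)
      anc_id <- NULL
      for (b in bact) {
        s <- .syn_mutate(root_seq, spec$subs_rate * 1)
        s <- .syn_mutate(s, spec$subs_rate * 7)
        id <- pid(b, pr[1L], "x")   # single pre-duplication copy
        seqs[[as.character(b)]][id] <- s
        archs[[id]] <- architecture(id, nchar(s),
                                    .syn_arch_template(pr[1L], nchar(s)))
        for (fam in pr) {
          truth[[length(truth) + 1L]] <- data.frame(
            family = fam, taxon = b, protein = id, relation = "ortholog",
            stringsAsFactors = FALSE)
        }
      }
      euk_base <- .syn_mutate(root_seq, spec$subs_rate * 1)
      for (fam in pr) {
        dup_copy <- .syn_mutate(euk_base, spec$subs_rate)
        leafseqs <- .syn_evolve(tree, .SYN_EUK, dup_copy, spec$subs_rate)
        lost <- euk[euk != seed_taxon &
                    stats::runif(length(euk)) < spec$loss_rate]
        for (tx in euk) {
          if (tx %in% lost) {
            truth[[length(truth) + 1L]] <- data.frame(
              family = fam, taxon = tx, protein = NA_character_,
              relation = "absent", stringsAsFactors = FALSE)
            next
          }
          add_gene(tx, fam, leafseqs[[as.character(tx)]], "ortholog",
                   arch_events = tx != seed_taxon)
        }
      }
    }

    # horizontal transfers: bacterial copy into a random eukaryote
    hgt_fams <- if (spec$n_hgt > 0L)
      .resample(singles, min(spec$n_hgt, length(singles))) else integer(0)
    hgt_rows <- list()
    for (fam in hgt_fams) {
      donor <- bact[1L]
      recipient <- .resample(setdiff(euk, c(seed_taxon, focal_taxon)), 1L)
      base <- seqs[[as.character(donor)]][[pid(donor, fam)]]
      id <- add_gene(recipient, fam, .syn_mutate(base, 0.02), "hgt",
                     suffix = "_hgt", arch_events = FALSE)
      hgt_rows[[length(hgt_rows) + 1L]] <-
        list(taxon = recipient, protein = id, family = fam, donor = donor)
    }

    # contaminations: bacterial genes on short extra contigs of the focal
    # taxon; one planted HGT gene there exercises the long-contig rule
    ctm_pool <- setdiff(singles, hgt_fams)
    ctm_fams <- .resample(ctm_pool, min(spec$n_contaminants,
                                        length(ctm_pool)))
    ctm_ids <- character(0)
    for (fam in ctm_fams) {
      donor <- bact[(fam %% length(bact)) + 1L]
      base <- seqs[[as.character(donor)]][[pid(donor, fam)]]
      id <- add_gene(focal_taxon, fam, .syn_mutate(base, 0.01),
                     "contaminant", suffix = "_ctm", arch_events = FALSE)
      ctm_ids <- c(ctm_ids, id)
    }
    hgt_focal <- if (spec$n_hgt > 0L &&
                     length(singles) > length(c(hgt_fams, ctm_fams))) {
      fam <- .resample(setdiff(singles, c(hgt_fams, ctm_fams)), 1L)
      donor <- bact[1L]
      base <- seqs[[as.character(donor)]][[pid(donor, fam)]]
      add_gene(focal_taxon, fam, .syn_mutate(base, 0.02), "hgt",
               suffix = "_hgt", arch_events = FALSE)
    } else character(0)

    # decoys: random unrelated proteins
    for (tx in c(euk, bact)) {
      for (k in seq_len(spec$n_decoys)) {
        id <- sprintf("t%d_dec%d", tx, k)
        seqs[[as.character(tx)]][id] <- .syn_random_seq(spec$protein_length)
      }
    }

    # contig map of the focal taxon: native genes on 3 long contigs,
    # each contaminant alone on a short contig
    focal_genes <- names(seqs[[as.character(focal_taxon)]])
    native <- setdiff(focal_genes, ctm_ids)
    contig_of <- rep(paste0("ctg", (seq_along(native) - 1L) %% 3L + 1L))
    contig_map <- data.frame(gene = native,
                             contig = contig_of,
                             stringsAsFactors = FALSE)
    contig_map <- contig_map[order(contig_map$contig, contig_map$gene), ]
    contig_map$ordinal <- stats::ave(seq_len(nrow(contig_map)),
                                     contig_map$contig, FUN = seq_along)
    if (length(ctm_ids)) {
      contig_map <- rbind(contig_map, data.frame(
        gene = ctm_ids, contig = paste0("ctg_s", seq_along(ctm_ids)),
        ordinal = 1L, stringsAsFactors = FALSE))
    }
    contig_map$start <- 1000L * contig_map$ordinal
    contig_map$end <- contig_map$start + 900L
    contig_map$strand <- "+"
    contig_lengths <- stats::setNames(rep(300000, 3), paste0("ctg", 1:3))
    if (length(ctm_ids)) {
      contig_lengths <- c(contig_lengths,
                          stats::setNames(rep(4000, length(ctm_ids)),
                                          paste0("ctg_s", seq_along(ctm_ids))))
    }

    # similarity hit table for the focal taxon's genes
    hit <- list()
    add_hit <- function(q, s, tx, bit) {
      hit[[length(hit) + 1L]] <<- data.frame(
        qseqid = q, sseqid = s, staxid = tx, bitscore = bit,
        stringsAsFactors = FALSE)
    }
    for (g in focal_genes) {
      add_hit(g, g, focal_taxon, 200)
      if (g %in% ctm_ids || g %in% hgt_focal) {
        fam <- as.integer(sub("^t\\d+_f(\\d+).*$", "\\1", g))
        for (b in bact) add_hit(g, pid(b, fam), b, 190 - 5 * match(b, bact))
        add_hit(g, pid(seed_taxon, fam), seed_taxon, 90)
      } else if (grepl("_f\\d+$", g)) {
        fam <- as.integer(sub("^t\\d+_f(\\d+)$", "\\1", g))
        sib <- euk[euk != focal_taxon]
        near <- sib[length(sib)]; far <- sib[1L]
        add_hit(g, pid(near, fam), near, 180)
        add_hit(g, pid(far, fam), far, 170)
        add_hit(g, pid(bact[1L], fam), bact[1L], 80)
      }
    }
    hit_table <- do.call(rbind, hit)

    # one native gene carries two isoforms (the longer one is the query);
    # the isoform sequences feed the contamination module only and are kept
    # out of the searchable proteome
    iso_gene <- native[grepl("_f\\d+$", native)][1L]
    isoform_map <- NULL; isoform_seqs <- NULL
    if (!is.na(iso_gene)) {
      short_id <- paste0(iso_gene, "_iso2")
      full <- seqs[[as.character(focal_taxon)]][[iso_gene]]
      isoform_seqs <- stats::setNames(c(full, substr(full, 1L, 30L)),
                                      c(iso_gene, short_id))
      isoform_map <- stats::setNames(list(c(iso_gene, short_id)), iso_gene)
    }

    proteomes <- lapply(stats::setNames(names(seqs), names(seqs)),
                        function(tx) proteome(as.integer(tx), seqs[[tx]]))
    truth <- do.call(rbind, truth)
    seeds <- stats::setNames(pid(seed_taxon, seq_len(spec$n_families)),
                             seq_len(spec$n_families))

    structure(list(tree = tree, proteomes = proteomes,
                   architectures = archs, truth = truth,
                   seed_taxon = seed_taxon, seeds = seeds,
                   focal_taxon = focal_taxon, hit_table = hit_table,
                   contig_map = contig_map, contig_lengths = contig_lengths,
                   isoform_map = isoform_map, isoform_seqs = isoform_seqs,
                   spec = spec),
              class = "synth_fixture")
  })
}

#' Write a synthetic fixture to disk
#'
#' Emits `taxonomy.tsv`, `proteomes/<taxon>.fa`, `architectures.json`,
#' `truth.tsv`, `hit_table.tsv`, `contig_map.tsv` and
#' `contig_lengths.tsv` under `dir`.
#'
#' @param fix a `synth_fixture` from [generate_scenario()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(fix, dir) {
  dir.create(file.path(dir, "proteomes"), showWarnings = FALSE,
             recursive = TRUE)
  write_taxonomy(fix$tree, file.path(dir, "taxonomy.tsv"))
  for (tx in names(fix$proteomes)) {
    write_fasta(fix$proteomes[[tx]], file.path(dir, "proteomes",
                                               paste0(tx, ".fa")))
  }
  write_architectures(fix$architectures, file.path(dir, "architectures.json"))
  utils::write.table(fix$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fix$hit_table, file.path(dir, "hit_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fix$contig_map, file.path(dir, "contig_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(contig = names(fix$contig_lengths),
               length = as.numeric(fix$contig_lengths)),
    file.path(dir, "contig_lengths.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
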