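#' Pick the query isoform per gene
#'
#' When a gene has several annotated isoforms, the longest protein is used
#' as the query of the taxonomic assignment; ties are broken by protein id.
#'
#' @param isoform_map named list: gene id -> character vector of protein
#'   ids.
#' @param seqs named character vector of protein sequences.
#' @return named character vector: gene id -> chosen protein id.
#' @export
pick_query_isoform <- function(isoform_map, seqs) {
  vapply(stats::setNames(names(isoform_map), names(isoform_map)),
         function(g) {
    ids <- isoform_map[[g]]
    if (length(ids) == 0L) stop("gene with zero isoforms: ", g)
    missing <- setdiff(ids, names(seqs))
    if (length(missing)) stop("isoform without sequence: ",
                              paste(missing, collapse = ","))
    len <- nchar(seqs[ids])
    ids[order(-len, ids)][1L]
  }, character(1))
}

#' Taxonomic assignment of a query from a similarity hit table
#'
#' The query's self-hit is excluded; hits within the bit-score margin of
#' the best remaining hit (bit >= (1 - margin) * best) are kept, and the
#' assigned taxon is the lowest common ancestor of the kept hits' taxa.
#'
#' @param hits data.frame of hit rows for one query: columns `qseqid`,
#'   `sseqid`, `staxid`, `bitscore`.
#' @param tree a `taxonomy_tree` containing the subject taxa.
#' @param margin bit-score margin as a fraction of the best hit's score
#'   (default 0.10).
#' @return assigned taxon id, or `NA` ("unassigned") without non-self hits.
#' @export
assign_taxon <- function(hits, tree, margin = 0.10) {
  hits <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]
  if (nrow(hits) == 0L) return(NA_integer_)
  best <- max(hits$bitscore)
  kept <- hits[hits$bitscore >= (1 - margin) * best, , drop = FALSE]
  tax_lca(tree, unique(as.integer(kept$staxid)))
}

#' Is an assigned taxon foreign to a species?
#'
#' A taxonomic assignment is foreign when the assigned taxon is neither the
#' species itself nor one of its ancestors, i.e. it lies off the path from
#' the species to the root of cellular organisms.
#'
#' @param assigned assigned taxon id.
#' @param species taxon id of the species the assembly derives from.
#' @param tree a `taxonomy_tree`.
#' @return logical (`FALSE` for `NA` assignments).
#' @export
is_foreign <- function(assigned, species, tree) {
  if (is.na(assigned)) return(FALSE)
  !is_ancestor_or_self(tree, assigned, species)
}

#' Classify foreign genes as contamination or horizontal transfer
#'
#' A gene flagged foreign is a *contamination* if (i) its contig is shorter
#' than the mean contig length across the assembly and (ii) all of its
#' direct neighbors on the contig (ordinal predecessor and successor;
#' single-gene contigs vacuously satisfy this) are also foreign. Any other
#' foreign gene is flagged *horizontally acquired*; non-foreign genes are
#' *native*.
#'
#' @param foreign named logical vector: gene id -> foreign flag.
#' @param contig_map data.frame with columns `gene`, `contig`, `ordinal`
#'   (consecutive gene position on its contig).
#' @param contig_lengths named numeric vector: contig id -> length.
#' @return data.frame `gene`, `contig`, `status` in
#'   {"native", "foreign-contamination", "foreign-hgt"}.
#' @export
classify_genes <- function(foreign, contig_map, contig_lengths) {
  missing <- setdiff(names(foreign), contig_map$gene)
  if (length(missing)) stop("gene missing from contig map: ",
                            paste(missing, collapse = ","))
  mean_len <- mean(contig_lengths)
  status <- vapply(names(foreign), function(g) {
    if (!isTRUE(foreign[[g]])) return("native")
    row <- contig_map[contig_map$gene == g, , drop = FALSE]
    ctg <- row$contig[1L]
    short <- contig_lengths[[ctg]] < mean_len
    sibs <- contig_map[contig_map$contig == ctg, , drop = FALSE]
    nb <- sibs$gene[abs(sibs$ordinal - row$ordinal[1L]) == 1L]
    nb_foreign <- length(nb) == 0L ||
      all(vapply(nb, function(x) isTRUE(foreign[[x]]), logical(1)))
    if (short && nb_foreign) "foreign-contamination" else "foreign-hgt"
  }, character(1))
  data.frame(gene = names(foreign),
             contig = contig_map$contig[match(names(foreign),
                                              contig_map$gene)],
             status = unname(status), stringsAsFactors = FALSE)
}

#' Read a 4-column similarity hit table
#'
#' Tab-separated columns `qseqid`, `sseqid`, `staxid`, `bitscore` (the
#' common tabular dialect of protein similarity search tools). A header
#' line is optional.
#'
#' @param path file path.
#' @return data.frame of hits.
#' @export
read_hit_table <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("qseqid", first, fixed = TRUE)
  tab <- utils::read.delim(path, header = header, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!header) names(tab) <- c("qseqid", "sseqid", "staxid", "bitscore")
  tab$staxid <- as.integer(tab$staxid)
  tab$bitscore <- as.numeric(tab$bitscore)
  if (any(tab$bitscore <= 0)) stop("non-positive bit score in hit table")
  tab
}

#' Flag foreign, contaminating and horizontally acquired genes
#'
#' End-to-end wrapper: per gene, choose the query isoform, assign a taxon
#' from its hit rows, test it against the species' root path, and classify
#' foreign genes by the contig rules.
#'
#' @param hit_table data.frame from [read_hit_table()] (all queries).
#' @param species taxon id of the assembly's species.
#' @param tree a `taxonomy_tree`.
#' @param contig_map,contig_lengths see [classify_genes()].
#' @param isoform_map optional named list gene -> protein ids; when given,
#'   `seqs` must be supplied and hits are looked up under the chosen
#'   isoform's id.
#' @param seqs protein sequences (required with `isoform_map`).
#' @param margin bit-score margin (default 0.10).
#' @return data.frame `gene`, `contig`, `assigned_taxon`, `foreign`,
#'   `status`.
#' @export
flag_contamination <- function(hit_table, species, tree, contig_map,
                               contig_lengths, isoform_map = NULL,
                               seqs = NULL, margin = 0.10) {
  genes <- unique(contig_map$gene)
  query_of <- stats::setNames(genes, genes)
  if (!is.null(isoform_map)) {
    mapped <- intersect(names(isoform_map), genes)
    if (length(mapped)) {
      query_of[mapped] <- pick_query_isoform(isoform_map[mapped], seqs)
    }
  }
  assigned <- vapply(genes, function(g) {
    q <- query_of[[g]]
    assign_taxon(hit_table[hit_table$qseqid == q, , drop = FALSE],
                 tree, margin)
  }, integer(1))
  foreign <- vapply(genes, function(g) is_foreign(assigned[[g]], species, tree),
                    logical(1))
  names(foreign) <- genes
  cls <- classify_genes(foreign, contig_map, contig_lengths)
  data.frame(gene = genes,
             contig = cls$contig[match(genes, cls$gene)],
             assigned_taxon = unname(assigned),
             foreign = unname(foreign),
             status = cls$status[match(genes, cls$gene)],
             stringsAsFactors = FALSE)
}
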