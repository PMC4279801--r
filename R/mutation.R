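#' Assign mutations to genes via the coding-span window
#'
#' A gene is affected by a mutation when the mutation falls within
#' [upstream anchor - window, downstream anchor + window] in genomic
#' coordinates, where the anchors are the ends of the coding span (start
#' codon to stop codon); boundaries are inclusive at exactly \code{window}
#' bp. A mutation may affect several genes. The affected region is
#' classified strand-aware: promoter (between the upstream window edge and
#' the start codon), terminator (between the stop codon and the downstream
#' edge), exon (inside an annotated exon) or intron (inside the coding span
#' but outside every exon).
#'
#' @param mutations data.frame with contig, position (1-based), type,
#'   lineages; an optional \code{end} column makes a variant span an
#'   interval (it affects a gene when any covered base lies in the window,
#'   and is classified by its start position).
#' @param gene_models a \code{gene_models} object.
#' @param window window size in bp on each side of the coding span.
#' @return data.frame of impacts: mutation_id, contig, position, type,
#'   lineages, gene_id, region; mutations on contigs absent from the gene
#'   models are skipped with a warning and counted in
#'   \code{attr(, "skipped_contigs")}.
#' @export
window_assign <- function(mutations, gene_models, window = 800) {
  stopifnot(inherits(gene_models, "gene_models"))
  mut <- mutations
  if (is.null(mut$mutation_id))
    mut$mutation_id <- sprintf("m%04d", seq_len(nrow(mut)))
  g <- gene_models$genes
  known <- mut$contig %in% g$contig
  skipped <- sum(!known)
  if (skipped > 0) {
    warning(skipped, " mutation(s) on unknown contig(s) skipped",
            call. = FALSE)
    mut <- mut[known, , drop = FALSE]
  }
  win <- GenomicRanges::GRanges(
    g$contig, IRanges::IRanges(pmax(1L, g$start - window), g$end + window))
  mut_end <- if (!is.null(mut$end)) mut$end else mut$position
  mq <- GenomicRanges::GRanges(mut$contig,
                               IRanges::IRanges(mut$position, mut_end))
  hits <- GenomicRanges::findOverlaps(mq, win, ignore.strand = TRUE)
  mi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  region <- character(length(mi))
  exons_by_gene <- split(gene_models$exons, gene_models$exons$gene_id)
  for (k in seq_along(mi)) {
    pos <- mut$position[mi[k]]
    region[k] <- classify_region(pos, g[gi[k], ],
                                 exons_by_gene[[g$gene_id[gi[k]]]])
  }
  out <- data.frame(
    mutation_id = mut$mutation_id[mi],
    contig = mut$contig[mi],
    position = mut$position[mi],
    type = mut$type[mi],
    lineages = if (!is.null(mut$lineages)) mut$lineages[mi] else NA_character_,
    gene_id = g$gene_id[gi],
    region = region,
    stringsAsFactors = FALSE
  )
  attr(out, "skipped_contigs") <- skipped
  out
}

# region of a single position relative to one gene's coding span
classify_region <- function(pos, gene, exons) {
  if (pos < gene$start)
    return(if (gene$strand == "+") "promoter" else "terminator")
  if (pos > gene$end)
    return(if (gene$strand == "+") "terminator" else "promoter")
  in_exon <- any(pos >= exons$start & pos <= exons$end)
  if (in_exon) "exon" else "intron"
}

#' Keep impacts on regulated genes and attach cluster labels
#'
#' @param impacts data.frame from \code{\link{window_assign}}.
#' @param regulated_genes character vector: the regulated union across
#'   strains (\code{consolidate_and_venn()$per_strain} union).
#' @param assignment data.frame with gene_id and cluster (e.g.
#'   \code{consensus_clust$assignment}); genes absent from it, or
#'   unclustered, are labelled "Not clustered".
#' @return Impact records restricted to regulated genes, with a
#'   \code{cluster} column.
#' @export
intersect_regulated <- function(impacts, regulated_genes, assignment = NULL) {
  out <- impacts[impacts$gene_id %in% regulated_genes, , drop = FALSE]
  cl <- rep("Not clustered", nrow(out))
  if (!is.null(assignment) && nrow(out)) {
    idx <- match(out$gene_id, assignment$gene_id)
    lab <- assignment$cluster[idx]
    ok <- !is.na(lab) & lab != "unclustered"
    cl[ok] <- lab[ok]
  }
  out$cluster <- cl
  rownames(out) <- NULL
  out
}

#' Contingency table of mutation impacts by cluster and lineage group
#'
#' @param records data.frame with cluster and lineage columns (either
#'   \code{lineages} or \code{strain}).
#' @return Integer matrix cluster x lineage group with row/column margins
#'   ("Total").
#' @export
tabulate_by_cluster_and_lineage <- function(records) {
  lineage <- if (!is.null(records$lineages)) records$lineages else records$strain
  if (nrow(records) == 0) {
    tab <- matrix(0L, 1, 1, dimnames = list("Total", "Total"))
    return(tab)
  }
  tab <- table(cluster = records$cluster, lineage = lineage)
  out <- stats::addmargins(tab, FUN = list(Total = sum), quiet = TRUE)
  m <- matrix(as.integer(out), nrow = nrow(out), dimnames = dimnames(out))
  m
}
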