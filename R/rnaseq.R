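#' Compute RPKM from gene-level counts
#'
#' RPKM = reads x 1e9 / (exon_length x total_mapped_reads): reads per
#' kilobase of exon per million mapped reads.
#'
#' @param counts data.frame with gene_id, strain, reads, exon_length_bp.
#' @param totals named numeric vector of total mapped reads per strain;
#'   NULL sums the table's own reads per strain.
#' @return \code{counts} with an \code{rpkm} column.
#' @export
compute_rpkm <- function(counts, totals = NULL) {
  stopifnot(all(c("gene_id", "strain", "reads", "exon_length_bp") %in%
                  names(counts)))
  if (any(counts$exon_length_bp <= 0))
    stop("input error: non-positive exon length", call. = FALSE)
  if (is.null(totals))
    totals <- tapply(counts$reads, counts$strain, sum)
  tot <- totals[counts$strain]
  if (any(is.na(tot) | tot <= 0))
    stop("input error: zero or missing total mapped reads", call. = FALSE)
  counts$rpkm <- counts$reads * 1e9 / (counts$exon_length_bp * as.numeric(tot))
  counts
}

#' Compare basal (time-0) expression between strains
#'
#' Computes log2(RPKM_RUTC30 / RPKM_NG14) per gene and applies the dual
#' filter. Genes with a zero count in either strain get a pseudo-count of
#' 0.5 read-equivalents added to both strains' counts before RPKM, so zero
#' counts never give infinite ratios; non-zero genes use their raw counts.
#' A gene is
#' flagged when |log2 ratio| >= basal_logratio_min and the average of the
#' two strains' raw read counts exceeds basal_reads_min.
#'
#' @param counts data.frame with gene_id, strain, reads, exon_length_bp for
#'   both strains.
#' @param totals named total mapped reads per strain (NULL = column sums).
#' @param thresholds an \code{\link{analysis_thresholds}} object.
#' @param strains length-2 character vector: (denominator, numerator)
#'   strain, default \code{c("NG14", "RUTC30")}.
#' @return data.frame gene_id, log2_ratio, average_reads, flagged.
#' @export
basal_compare <- function(counts, totals = NULL,
                          thresholds = analysis_thresholds(),
                          strains = c("NG14", "RUTC30")) {
  validate_thresholds(thresholds)
  if (is.null(totals)) totals <- tapply(counts$reads, counts$strain, sum)
  a <- counts[counts$strain == strains[1], , drop = FALSE]
  b <- counts[counts$strain == strains[2], , drop = FALSE]
  genes <- union(a$gene_id, b$gene_id)
  len <- stats::setNames(a$exon_length_bp, a$gene_id)[genes]
  len[is.na(len)] <- stats::setNames(b$exon_length_bp, b$gene_id)[genes[is.na(len)]]
  reads_a <- stats::setNames(a$reads, a$gene_id)[genes]
  reads_b <- stats::setNames(b$reads, b$gene_id)[genes]
  reads_a[is.na(reads_a)] <- 0
  reads_b[is.na(reads_b)] <- 0
  pseudo <- ifelse(reads_a == 0 | reads_b == 0, 0.5, 0)
  rpkm_a <- (reads_a + pseudo) * 1e9 / (len * as.numeric(totals[strains[1]]))
  rpkm_b <- (reads_b + pseudo) * 1e9 / (len * as.numeric(totals[strains[2]]))
  lr <- log2(rpkm_b / rpkm_a)
  avg <- (reads_a + reads_b) / 2
  data.frame(
    gene_id = genes,
    log2_ratio = unname(lr),
    average_reads = unname(avg),
    flagged = unname(abs(lr) >= thresholds$basal_logratio_min &
                       avg > thresholds$basal_reads_min),
    stringsAsFactors = FALSE
  )
}

#' Per-cluster distribution of basal-expression differences
#'
#' For each cluster: how many genes have a higher basal level in the
#' numerator strain (flagged, positive ratio), a lower one (flagged,
#' negative) or an equal one (unflagged), with percentages of cluster size.
#'
#' @param basal data.frame from \code{\link{basal_compare}}.
#' @param assignment data.frame with gene_id and cluster columns (e.g.
#'   \code{consensus_clust$assignment}).
#' @return data.frame cluster, n, n_higher, n_lower, n_equal, pct_higher,
#'   pct_lower, pct_equal.
#' @export
cluster_distribution <- function(basal, assignment) {
  m <- merge(assignment[, c("gene_id", "cluster")],
             basal[, c("gene_id", "log2_ratio", "flagged")],
             by = "gene_id", all.x = TRUE)
  m$flagged[is.na(m$flagged)] <- FALSE
  out <- do.call(rbind, lapply(split(m, m$cluster), function(d) {
    n <- nrow(d)
    hi <- sum(d$flagged & d$log2_ratio > 0)
    lo <- sum(d$flagged & d$log2_ratio < 0)
    data.frame(cluster = d$cluster[1], n = n, n_higher = hi, n_lower = lo,
               n_equal = n - hi - lo,
               pct_higher = 100 * hi / n, pct_lower = 100 * lo / n,
               pct_equal = 100 * (n - hi - lo) / n,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Re-apply the dual basal filter to a published-style comparison table
#'
#' Takes a table of already-selected genes (columns log2_ratio and
#' average_reads, as printed in basal-comparison tables) and re-applies the
#' stated rule: |log2 ratio| >= basal_logratio_min with average reads
#' strictly greater than basal_reads_min. Rows violating the rule are
#' returned as a discrepancy report rather than silently kept.
#'
#' @param table data.frame with at least log2_ratio and average_reads.
#' @param thresholds an \code{\link{analysis_thresholds}} object.
#' @return List: \code{$kept} (rows passing), \code{$violations} (rows
#'   failing, with a \code{violation} reason column).
#' @export
audit_basal_table <- function(table, thresholds = analysis_thresholds()) {
  validate_thresholds(thresholds)
  ratio_ok <- abs(table$log2_ratio) >= thresholds$basal_logratio_min
  reads_ok <- table$average_reads > thresholds$basal_reads_min
  keep <- ratio_ok & reads_ok
  viol <- table[!keep, , drop = FALSE]
  if (nrow(viol)) {
    viol$violation <- ifelse(!ratio_ok[!keep] & !reads_ok[!keep],
                             "ratio and reads",
                             ifelse(!ratio_ok[!keep], "ratio", "reads"))
  } else viol$violation <- character(0)
  list(kept = table[keep, , drop = FALSE], violations = viol)
}
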