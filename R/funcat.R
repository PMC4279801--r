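#' Resolve one primary category per gene
#'
#' Genes carrying several functional-category annotations are counted once,
#' under the lowest category id (hierarchical numeric ids sort correctly as
#' zero-padded strings); resolved genes are reported with a message.
#'
#' @param entries data.frame gene_id, category_id, category_name, status.
#' @return One row per gene.
#' @export
resolve_primary_category <- function(entries) {
  dup <- duplicated(entries$gene_id) | duplicated(entries$gene_id, fromLast = TRUE)
  if (!any(dup)) return(entries)
  message(length(unique(entries$gene_id[dup])),
          " gene(s) with multiple annotations resolved to the lowest category id")
  ord <- order(entries$gene_id, entries$category_id, na.last = TRUE)
  sorted <- entries[ord, , drop = FALSE]
  out <- sorted[!duplicated(sorted$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Main functional categories
#'
#' Categories holding strictly more than \code{min_genes} classified genes
#' in the analyzed gene set.
#'
#' @param entries data.frame gene_id, category_id, category_name, status
#'   (one primary annotation per gene; see
#'   \code{\link{resolve_primary_category}}).
#' @param min_genes threshold; a category with exactly this many genes is
#'   excluded.
#' @return data.frame category_id, category_name, n, sorted by decreasing n.
#' @export
main_categories <- function(entries, min_genes = 10) {
  cl <- entries[entries$status == "classified" & !is.na(entries$category_id), ,
                drop = FALSE]
  if (nrow(cl) == 0)
    return(data.frame(category_id = character(0), category_name = character(0),
                      n = integer(0), stringsAsFactors = FALSE))
  tab <- table(cl$category_id)
  keep <- names(tab)[tab > min_genes]
  nm <- cl$category_name[match(keep, cl$category_id)]
  out <- data.frame(category_id = keep, category_name = nm,
                    n = as.integer(tab[keep]), stringsAsFactors = FALSE)
  out[order(-out$n, out$category_id), , drop = FALSE]
}

#' Category x cluster table with emphasis flags
#'
#' Counts clustered genes per (category, cluster), with row percentages of
#' each category total (rounded to the nearest integer, half away from
#' zero) and an emphasis flag on the cluster whose count leads the
#' runner-up by at least \code{funcat_bold_margin} genes. Non-main
#' classified genes are pooled as "Other categories"; unclassified and
#' unknown genes get their own rows; clustered genes with no annotation
#' entry are counted as unknown with a warning. Column totals equal cluster
#' sizes.
#'
#' @param entries annotation data.frame (gene_id, category_id,
#'   category_name, status).
#' @param assignment data.frame gene_id, cluster (from
#'   \code{consensus_clust$assignment}); only genes with a cluster (not
#'   "unclustered") are tabulated.
#' @param thresholds an \code{\link{analysis_thresholds}} object
#'   (funcat_main_min, funcat_bold_margin).
#' @return List of class \code{"funcat_table"}: \code{$counts} (matrix rows
#'   = category rows + "Total", cols = clusters + "Total"), \code{$pct}
#'   (integer percentages, category rows only), \code{$emphasis} (named
#'   character: emphasized cluster per category row, NA when no 2-gene
#'   lead), \code{$main} (the main-category list).
#' @export
cluster_category_table <- function(entries, assignment,
                                   thresholds = analysis_thresholds()) {
  validate_thresholds(thresholds)
  ass <- assignment[assignment$cluster != "unclustered" &
                      !is.na(assignment$cluster), , drop = FALSE]
  entries <- resolve_primary_category(entries)
  idx <- match(ass$gene_id, entries$gene_id)
  if (anyNA(idx))
    warning(sum(is.na(idx)), " clustered gene(s) without an annotation ",
            "entry counted as unknown", call. = FALSE)
  status <- ifelse(is.na(idx), "unknown", entries$status[idx])
  cat_id <- ifelse(status == "classified", entries$category_id[idx], NA)
  cat_name <- ifelse(status == "classified", entries$category_name[idx], NA)
  main <- main_categories(
    data.frame(gene_id = ass$gene_id, category_id = cat_id,
               category_name = cat_name, status = status,
               stringsAsFactors = FALSE),
    min_genes = thresholds$funcat_main_min)
  row_of <- ifelse(status == "unknown", "Unknown protein",
            ifelse(status == "unclassified", "Unclassified",
            ifelse(cat_id %in% main$category_id, cat_name,
                   "Other categories")))
  clusters <- sort(unique(suppressWarnings(as.numeric(ass$cluster))))
  clusters <- if (anyNA(clusters)) sort(unique(ass$cluster)) else as.character(clusters)
  rows <- c(main$category_name, "Other categories", "Unclassified",
            "Unknown protein")
  rows <- rows[rows %in% row_of | rows %in% main$category_name]
  counts <- matrix(0L, nrow = length(rows), ncol = length(clusters),
                   dimnames = list(rows, clusters))
  tab <- table(row_of, as.character(ass$cluster))
  counts[rownames(tab), colnames(tab)] <- tab
  row_tot <- rowSums(counts)
  pct <- round_half_up(100 * counts / row_tot)
  emphasis <- apply(counts, 1, function(x) {
    s <- sort(x, decreasing = TRUE)
    if (length(s) >= 2 && s[1] - s[2] >= thresholds$funcat_bold_margin)
      clusters[which.max(x)] else NA_character_
  })
  full <- rbind(cbind(counts, Total = row_tot),
                Total = c(colSums(counts), sum(counts)))
  out <- list(counts = full, pct = pct, emphasis = emphasis, main = main)
  class(out) <- "funcat_table"
  out
}

#' @export
print.funcat_table <- function(x, ...) {
  cat("Functional-category x cluster table (",
      nrow(x$counts) - 1, " rows x ", ncol(x$counts) - 1, " clusters)\n",
      sep = "")
  print(x$counts)
  invisible(x)
}

#' Render a funcat table to a TSV-ready data.frame
#'
#' One row per category with "count (pct%)" cells and a dedicated
#' \code{emphasis} column naming the emphasized cluster (empty when none).
#'
#' @param x a \code{funcat_table}.
#' @return data.frame.
#' @export
format_funcat_table <- function(x) {
  stopifnot(inherits(x, "funcat_table"))
  cl <- setdiff(colnames(x$counts), "Total")
  cats <- setdiff(rownames(x$counts), "Total")
  cells <- matrix("", length(cats), length(cl),
                  dimnames = list(cats, cl))
  for (r in cats) for (c in cl) {
    n <- x$counts[r, c]
    cells[r, c] <- if (n == 0) "" else sprintf("%d (%d%%)", n, x$pct[r, c])
  }
  data.frame(category = cats, cells,
             total = x$counts[cats, "Total"],
             emphasis = ifelse(is.na(x$emphasis[cats]), "",
                               paste("cluster", x$emphasis[cats])),
             check.names = FALSE, stringsAsFactors = FALSE)
}
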