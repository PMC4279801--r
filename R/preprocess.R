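#' Compute M/A values for two-channel probes
#'
#' M = log2(test/ref), A = mean of the two log2 intensities. Defined only
#' for "found" probes with positive intensities in both channels; other rows
#' get NA.
#'
#' @param probes probe data.frame (see \code{\link{generate_probe_signals}}
#'   for the column dialect).
#' @return \code{probes} with numeric columns \code{M} and \code{A} added.
#' @export
compute_ma <- function(probes) {
  ok <- probes$status == "found" &
    probes$intensity_test > 0 & probes$intensity_ref > 0
  probes$M <- ifelse(ok, log2(probes$intensity_test / probes$intensity_ref), NA_real_)
  probes$A <- ifelse(ok, (log2(probes$intensity_test) + log2(probes$intensity_ref)) / 2,
                     NA_real_)
  probes
}

#' Global lowess normalization of one hybridization
#'
#' Locally weighted regression of M on A over all found probes of the
#' hybridization; the residuals replace M. No background subtraction is
#' performed and A is left unchanged.
#'
#' @param probes probe rows of a single hybridization, with M/A columns
#'   (added if absent).
#' @param span lowess span as a fraction of the probes.
#' @return \code{probes} with M replaced by the lowess residual (found
#'   probes only; others keep NA).
#' @export
global_lowess_normalize <- function(probes, span = 0.3) {
  if (!all(c("M", "A") %in% names(probes))) probes <- compute_ma(probes)
  idx <- which(!is.na(probes$M) & !is.na(probes$A))
  if (length(idx) < 50)
    stop("normalization error: only ", length(idx),
         " found probes on hybridization (need >= 50)", call. = FALSE)
  fit <- stats::lowess(probes$A[idx], probes$M[idx], f = span)
  fitted <- stats::approx(fit$x, fit$y, xout = probes$A[idx], rule = 2,
                          ties = mean)$y
  probes$M[idx] <- probes$M[idx] - fitted
  probes
}

#' Background threshold from the "not found" population
#'
#' The detectability threshold is the mean intensity of all "not found"
#' features plus \code{sd_mult} sample standard deviations (n - 1
#' denominator).
#'
#' @param not_found_intensities numeric vector of background intensities
#'   (both channels of the not-found features pooled).
#' @param sd_mult number of standard deviations above the mean.
#' @return Threshold in fluorescence units.
#' @export
background_threshold <- function(not_found_intensities, sd_mult = 2) {
  x <- not_found_intensities[!is.na(not_found_intensities)]
  if (length(x) < 2)
    stop("insufficient data: need >= 2 not-found features for the ",
         "background threshold", call. = FALSE)
  mean(x) + sd_mult * stats::sd(x)
}

#' Flag detectable probes
#'
#' A probe is detectable iff its status is "found" and both channel
#' intensities exceed the background threshold. "Not found" features are
#' never detectable, whatever their intensities.
#'
#' @param probes probe data.frame.
#' @param threshold background threshold (fluorescence units).
#' @return \code{probes} with a logical \code{detectable} column.
#' @export
flag_detectable <- function(probes, threshold) {
  probes$detectable <- probes$status == "found" &
    probes$intensity_test > threshold & probes$intensity_ref > threshold
  probes
}

#' Summarize probes into transcript log2 ratios
#'
#' For every gene x condition x replicate, averages the normalized M values
#' of usable probes: detectable, located inside the coding sequence and on
#' the matching strand. Dye-swapped replicates are orientation-corrected by
#' a sign flip before averaging. Groups with no usable probe are discarded
#' (reported with NA ratio and 0 probes, never imputed).
#'
#' @param probes probe data.frame with \code{M} and \code{detectable}
#'   columns (from \code{\link{global_lowess_normalize}} and
#'   \code{\link{flag_detectable}}).
#' @return data.frame gene_id, strain, time_h, replicate, log2_ratio,
#'   n_probes_used; one row per group present in the input (NA log2_ratio
#'   marks a discarded transcript).
#' @export
summarize_transcripts <- function(probes) {
  stopifnot(all(c("M", "detectable") %in% names(probes)))
  p <- probes[!is.na(probes$gene_id), , drop = FALSE]
  m_corr <- ifelse(p$dye_orientation == "swapped", -p$M, p$M)
  usable <- p$detectable & p$in_cds & p$strand_match & !is.na(m_corr)
  key <- interaction(p$gene_id, p$strain, p$time_h, p$replicate,
                     drop = FALSE, sep = "\r")
  grid <- unique(data.frame(gene_id = p$gene_id, strain = p$strain,
                            time_h = p$time_h, replicate = p$replicate,
                            key = as.character(key),
                            stringsAsFactors = FALSE))
  sums <- tapply(ifelse(usable, m_corr, 0), key, sum)
  ns <- tapply(usable, key, sum)
  n_used <- as.integer(ns[grid$key])
  ratio <- as.numeric(sums[grid$key]) / n_used
  ratio[n_used == 0] <- NA_real_
  out <- data.frame(gene_id = grid$gene_id, strain = grid$strain,
                    time_h = grid$time_h, replicate = grid$replicate,
                    log2_ratio = ratio, n_probes_used = n_used,
                    stringsAsFactors = FALSE)
  out[order(out$gene_id, out$strain, out$time_h, out$replicate), ,
      drop = FALSE]
}

#' Assemble the per-replicate gene x condition ratio table
#'
#' @param ratios data.frame from \code{\link{summarize_transcripts}}.
#' @return Numeric matrix, genes in rows, one column per strain x time x
#'   replicate (e.g. \code{"NG14_1h_r1"}); discarded entries are NA and are
#'   never imputed.
#' @export
assemble_ratio_table <- function(ratios) {
  colkey <- sprintf("%s_%gh_r%d", ratios$strain, ratios$time_h,
                    ratios$replicate)
  if (anyDuplicated(paste(ratios$gene_id, colkey)))
    stop("input error: duplicate (gene, condition, replicate) entries",
         call. = FALSE)
  genes <- sort(unique(ratios$gene_id))
  reps <- sort(unique(ratios$replicate))
  cols <- as.vector(t(outer(condition_levels(),
                            paste0("r", reps), paste, sep = "_")))
  mat <- matrix(NA_real_, nrow = length(genes), ncol = length(cols),
                dimnames = list(genes, cols))
  mat[cbind(match(ratios$gene_id, genes), match(colkey, cols))] <-
    ratios$log2_ratio
  mat
}

#' Preprocess a probe table end to end
#'
#' Per hybridization (strain x time x replicate): estimates the background
#' threshold from that hybridization's "not found" features, lowess-
#' normalizes the found probes, and flags detectability; then summarizes
#' probes into transcript ratios and assembles the rectangular table.
#'
#' @param probes full probe data.frame (all hybridizations).
#' @param thresholds an \code{\link{analysis_thresholds}} object (uses
#'   \code{background_sd_mult} and \code{lowess_span}).
#' @return List: \code{$probes} (annotated), \code{$ratios} (long form),
#'   \code{$ratio_table} (genes x condition_replicate matrix),
#'   \code{$background} (per-hybridization thresholds).
#' @export
preprocess_probes <- function(probes, thresholds = analysis_thresholds()) {
  validate_thresholds(thresholds)
  hyb <- interaction(probes$strain, probes$time_h, probes$replicate,
                     drop = TRUE)
  pieces <- split(probes, hyb)
  bg <- numeric(length(pieces))
  names(bg) <- names(pieces)
  for (i in seq_along(pieces)) {
    p <- pieces[[i]]
    nf <- p[p$status == "not_found", , drop = FALSE]
    bg[i] <- background_threshold(c(nf$intensity_test, nf$intensity_ref),
                                  thresholds$background_sd_mult)
    p <- global_lowess_normalize(p, span = thresholds$lowess_span)
    pieces[[i]] <- flag_detectable(p, bg[i])
  }
  annotated <- do.call(rbind, pieces)
  rownames(annotated) <- NULL
  ratios <- summarize_transcripts(annotated)
  list(probes = annotated, ratios = ratios,
       ratio_table = assemble_ratio_table(ratios), background = bg)
}

#' Write / read a ratio table as TSV
#'
#' Genes in rows, strain_time_replicate columns, "NA" for missing entries.
#'
#' @param mat ratio matrix from \code{\link{assemble_ratio_table}}.
#' @param path TSV path.
#' @return The path (write) or the matrix (read).
#' @export
write_ratio_table <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_ratio_table
#' @export
read_ratio_table <- function(path) {
  df <- read_tsv(path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$gene_id
  storage.mode(mat) <- "double"
  mat
}
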