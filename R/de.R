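#' Per-gene linear fit for one contrast
#'
#' Each strain x time contrast has a handful of replicate log2 ratios per
#' gene; the fit is the replicate mean with its sample variance.
#'
#' @param values numeric vector of replicate log2 ratios (NA = missing).
#' @return List with \code{lfc} (mean), \code{residual_variance} (n - 1
#'   denominator) and \code{residual_df} (n - 1), or NULL when fewer than 2
#'   values are present (gene untestable for that contrast).
#' @export
fit_gene <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 2) return(NULL)
  list(lfc = mean(x), residual_variance = stats::var(x),
       residual_df = length(x) - 1L)
}

#' Fit every gene x contrast from a ratio table
#'
#' @param ratio_table genes x condition_replicate matrix from
#'   \code{\link{assemble_ratio_table}}.
#' @return data.frame gene_id, strain, time_h, n_reps, lfc,
#'   residual_variance, residual_df; untestable gene/contrast pairs (fewer
#'   than 2 replicates) carry NA statistics and residual_df 0.
#' @export
fit_contrasts <- function(ratio_table) {
  conds <- condition_levels()
  out <- vector("list", length(conds))
  for (i in seq_along(conds)) {
    cols <- grep(paste0("^", conds[i], "_r\\d+$"), colnames(ratio_table))
    x <- ratio_table[, cols, drop = FALSE]
    n <- rowSums(!is.na(x))
    m <- rowMeans(x, na.rm = TRUE)
    ss <- rowSums((x - m)^2, na.rm = TRUE)
    testable <- n >= 2
    out[[i]] <- data.frame(
      gene_id = rownames(ratio_table),
      strain = sub("_.*$", "", conds[i]),
      time_h = as.numeric(sub("h$", "", sub("^.*_", "", conds[i]))),
      n_reps = as.integer(n),
      lfc = ifelse(testable, m, NA_real_),
      residual_variance = ifelse(testable, ss / pmax(n - 1, 1), NA_real_),
      residual_df = ifelse(testable, as.integer(n) - 1L, 0L),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

# Newton inversion of the trigamma function (solves trigamma(x) = y)
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Estimate the variance prior across genes
#'
#' Method of moments on log variances under the scaled-F model for gene-wise
#' sample variances: s^2 ~ s0^2 * F(d, d0). The spread of log(s^2) in excess
#' of trigamma(d/2) identifies the prior df d0; the location identifies the
#' prior variance s0^2. A degenerate spread (at or below the sampling
#' floor, e.g. all variances equal) returns d0 = Inf with the pooled
#' variance and a warning.
#'
#' @param s2 gene-wise sample variances (only finite, positive values are
#'   used for the fit).
#' @param df residual df accompanying each variance (a common scalar is
#'   recycled).
#' @return List with \code{d0} (prior df, possibly Inf) and \code{s0sq}
#'   (prior variance).
#' @export
estimate_variance_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 10)
    stop("need >= 10 testable genes to estimate the variance prior",
         call. = FALSE)
  z <- log(s2[ok])
  d <- df[ok]
  # centre each log-variance by its chi-square sampling bias
  e <- z - digamma(d / 2) + log(d / 2)
  evar <- stats::var(z)
  if (evar < 1e-12) {
    warning("degenerate variance distribution (all variances equal); ",
            "falling back to the pooled variance", call. = FALSE)
    return(list(d0 = Inf, s0sq = sum(d * s2[ok]) / sum(d)))
  }
  excess <- evar - mean(trigamma(d / 2))
  if (!is.finite(excess) || excess <= 1e-8) {
    # spread no larger than the chi-square sampling floor: gene variances are
    # exchangeable, so shrink fully to the common variance (infinite prior df)
    return(list(d0 = Inf, s0sq = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s0sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0sq = s0sq)
}

#' Moderate gene-wise variances and compute moderated t statistics
#'
#' Shrinks each gene's residual variance towards the prior:
#' s2_post = (d0 * s0^2 + d * s^2) / (d0 + d); the moderated t is
#' lfc / sqrt(s2_post / n) on d0 + d df, with a two-sided p-value. With
#' prior df 0 this reduces to the ordinary t test; with prior df Inf every
#' posterior variance equals the prior variance.
#'
#' @param fits data.frame from \code{\link{fit_contrasts}}.
#' @param prior_df force the prior df (0, Inf, or a positive number); NULL
#'   estimates it from the data.
#' @param prior_var force the prior variance; NULL estimates it.
#' @return \code{fits} with columns s2_post, df_total, moderated_t, p_value
#'   added; the prior is attached as \code{attr(, "prior")}.
#' @export
moderate_variances <- function(fits, prior_df = NULL, prior_var = NULL) {
  est <- estimate_variance_prior(fits$residual_variance, fits$residual_df)
  d0 <- if (is.null(prior_df)) est$d0 else prior_df
  s0sq <- if (is.null(prior_var)) est$s0sq else prior_var
  d <- fits$residual_df
  s2 <- fits$residual_variance
  s2_post <- if (is.infinite(d0)) rep(s0sq, length(s2))
             else (d0 * s0sq + d * s2) / (d0 + d)
  s2_post[is.na(s2)] <- NA_real_
  df_total <- d0 + d
  tstat <- fits$lfc / sqrt(s2_post / fits$n_reps)
  pval <- 2 * stats::pt(-abs(tstat), df = df_total)
  fits$s2_post <- s2_post
  fits$df_total <- df_total
  fits$moderated_t <- tstat
  fits$p_value <- pval
  attr(fits, "prior") <- list(d0 = d0, s0sq = s0sq)
  fits
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR-adjusted p-values (monotone non-decreasing in p, capped at
#' 1), applied through \code{stats::p.adjust}.
#'
#' @param p numeric vector of p-values in [0, 1] (NA passed through).
#' @return Adjusted values of the same length.
#' @export
bh_adjust <- function(p) {
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad))
    stop("input error: p-values outside [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Select regulated genes per strain and time point
#'
#' FDR is computed within each strain x time contrast; a gene is regulated
#' when fdr <= fdr_cutoff and |lfc| > lfc_cutoff, with direction from the
#' sign of the fold change.
#'
#' @param de data.frame from \code{\link{moderate_variances}}.
#' @param thresholds an \code{\link{analysis_thresholds}} object.
#' @return \code{de} with columns fdr, regulated, direction added.
#' @export
select_regulated <- function(de, thresholds = analysis_thresholds()) {
  validate_thresholds(thresholds)
  de$fdr <- NA_real_
  for (key in unique(paste(de$strain, de$time_h))) {
    idx <- paste(de$strain, de$time_h) == key
    de$fdr[idx] <- bh_adjust(de$p_value[idx])
  }
  de$regulated <- !is.na(de$fdr) & de$fdr <= thresholds$fdr_cutoff &
    abs(de$lfc) > thresholds$lfc_cutoff
  de$direction <- ifelse(!de$regulated, "none",
                         ifelse(de$lfc > 0, "up", "down"))
  de
}

#' Up/down counts per strain and time point
#'
#' @param de data.frame from \code{\link{select_regulated}}.
#' @return data.frame strain, time_h, up, down.
#' @export
de_counts <- function(de) {
  grid <- expand.grid(strain = unique(de$strain),
                      time_h = sort(unique(de$time_h)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$up <- mapply(function(s, t) sum(de$strain == s & de$time_h == t &
                                         de$direction == "up"),
                    grid$strain, grid$time_h)
  grid$down <- mapply(function(s, t) sum(de$strain == s & de$time_h == t &
                                           de$direction == "down"),
                      grid$strain, grid$time_h)
  grid
}

#' Consolidate per-time regulated calls into strain gene sets
#'
#' A gene belongs to a strain's set when it is regulated at at least one
#' time point in that strain. The union is partitioned into strain-specific
#' and shared sets (pairwise disjoint, covering the union).
#'
#' @param de data.frame from \code{\link{select_regulated}} with exactly two
#'   strains.
#' @return List of class \code{"strain_gene_sets"}: \code{$per_strain}
#'   (named list of gene-id vectors), \code{$specific} (named list),
#'   \code{$shared}, \code{$total} (size of the union).
#' @export
consolidate_and_venn <- function(de) {
  strains <- unique(de$strain)
  if (length(strains) != 2)
    stop("venn partition requires exactly two strains", call. = FALSE)
  per_strain <- lapply(strains, function(s)
    sort(unique(de$gene_id[de$strain == s & de$regulated])))
  names(per_strain) <- strains
  shared <- intersect(per_strain[[1]], per_strain[[2]])
  specific <- list(setdiff(per_strain[[1]], shared),
                   setdiff(per_strain[[2]], shared))
  names(specific) <- strains
  out <- list(per_strain = per_strain, specific = specific, shared = shared,
              total = length(union(per_strain[[1]], per_strain[[2]])))
  class(out) <- "strain_gene_sets"
  out
}

#' @export
print.strain_gene_sets <- function(x, ...) {
  cat("Regulated gene sets:\n")
  for (s in names(x$specific))
    cat(sprintf("  %s-specific: %d\n", s, length(x$specific[[s]])))
  cat(sprintf("  shared: %d\n  total: %d\n", length(x$shared), x$total))
  invisible(x)
}

#' Full differential-expression stage
#'
#' Fits every contrast, estimates the variance prior (pooled across
#' contrasts), moderates, adjusts within contrast and selects regulated
#' genes.
#'
#' @param ratio_table genes x condition_replicate matrix.
#' @param thresholds an \code{\link{analysis_thresholds}} object.
#' @param prior_df optional forced prior df (see
#'   \code{\link{moderate_variances}}).
#' @return List: \code{$table} (per gene x contrast results),
#'   \code{$counts} (up/down per strain x time), \code{$venn}
#'   (\code{\link{consolidate_and_venn}} result), \code{$prior}.
#' @export
de_analysis <- function(ratio_table, thresholds = analysis_thresholds(),
                        prior_df = NULL) {
  fits <- fit_contrasts(ratio_table)
  mod <- moderate_variances(fits, prior_df = prior_df)
  sel <- select_regulated(mod, thresholds)
  list(table = sel, counts = de_counts(sel), venn = consolidate_and_venn(sel),
       prior = attr(mod, "prior"))
}
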