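#' Analysis thresholds
#'
#' Every fixed constant of the analysis lives in one validated configuration
#' object shared by all stages; no stage hard-codes a threshold.
#'
#' @param fdr_cutoff false-discovery-rate cut-off for calling a gene
#'   regulated (probability).
#' @param lfc_cutoff minimum absolute log2 fold change for a regulated gene.
#' @param missing_fraction_max maximum tolerated fraction of missing values
#'   per gene row in the clustering matrix.
#' @param background_sd_mult number of standard deviations added to the mean
#'   "not found" intensity to obtain the background threshold.
#' @param lowess_span span (fraction of probes) of the global lowess fit.
#' @param kmeans_runs number of independent K-means runs entering the
#'   consensus.
#' @param cooccurrence_threshold minimum co-clustering fraction for two genes
#'   to end up in the same final cluster.
#' @param basal_logratio_min minimum absolute log2 RPKM ratio for a basal
#'   expression difference.
#' @param basal_reads_min minimum average read count accompanying the basal
#'   log-ratio rule.
#' @param mutation_window distance in bp from the coding span (start codon to
#'   stop codon) within which a mutation is assigned to a gene.
#' @param bradford_factor_low,bradford_factor_high multiplicative range by
#'   which the Bradford assay underestimates Lowry-equivalent protein.
#' @param carbon_balance_min minimum acceptable gC produced per gC consumed.
#' @param funcat_main_min a functional category is "main" when it holds
#'   strictly more than this many genes.
#' @param funcat_bold_margin minimum lead (in genes) of the top cluster over
#'   the runner-up for a category count to be emphasised.
#'
#' @return An object of class \code{"analysis_thresholds"} (named list).
#' @export
#' @examples
#' th <- analysis_thresholds()
#' th$fdr_cutoff
analysis_thresholds <- function(fdr_cutoff = 0.05,
                                lfc_cutoff = 1.0,
                                missing_fraction_max = 0.30,
                                background_sd_mult = 2,
                                lowess_span = 0.3,
                                kmeans_runs = 5,
                                cooccurrence_threshold = 0.60,
                                basal_logratio_min = 4,
                                basal_reads_min = 100,
                                mutation_window = 800,
                                bradford_factor_low = 3.5,
                                bradford_factor_high = 5.0,
                                carbon_balance_min = 0.90,
                                funcat_main_min = 10,
                                funcat_bold_margin = 2) {
  x <- list(
    fdr_cutoff = fdr_cutoff,
    lfc_cutoff = lfc_cutoff,
    missing_fraction_max = missing_fraction_max,
    background_sd_mult = background_sd_mult,
    lowess_span = lowess_span,
    kmeans_runs = kmeans_runs,
    cooccurrence_threshold = cooccurrence_threshold,
    basal_logratio_min = basal_logratio_min,
    basal_reads_min = basal_reads_min,
    mutation_window = mutation_window,
    bradford_factor_low = bradford_factor_low,
    bradford_factor_high = bradford_factor_high,
    carbon_balance_min = carbon_balance_min,
    funcat_main_min = funcat_main_min,
    funcat_bold_margin = funcat_bold_margin
  )
  class(x) <- "analysis_thresholds"
  validate_thresholds(x)
  x
}

#' Validate an analysis_thresholds object
#'
#' Checks ranges: probabilities and fractions in [0, 1], counts and the
#' window strictly positive, factor_low < factor_high.
#'
#' @param x an \code{analysis_thresholds} object.
#' @return \code{x}, invisibly, if valid; otherwise an error naming the
#'   offending key.
#' @export
validate_thresholds <- function(x) {
  stopifnot(inherits(x, "analysis_thresholds"))
  num1 <- function(key) {
    v <- x[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("threshold '", key, "' must be a single finite number", call. = FALSE)
    v
  }
  for (key in c("fdr_cutoff", "missing_fraction_max", "cooccurrence_threshold")) {
    v <- num1(key)
    if (v < 0 || v > 1)
      stop("threshold '", key, "' out of range [0, 1]: ", v, call. = FALSE)
  }
  if (num1("lowess_span") <= 0 || x$lowess_span > 1)
    stop("threshold 'lowess_span' out of range (0, 1]: ", x$lowess_span, call. = FALSE)
  for (key in c("kmeans_runs", "basal_reads_min", "mutation_window", "funcat_main_min")) {
    v <- num1(key)
    if (v <= 0 || v != round(v))
      stop("threshold '", key, "' must be a positive integer: ", v, call. = FALSE)
  }
  for (key in c("lfc_cutoff", "background_sd_mult", "basal_logratio_min",
                "carbon_balance_min", "funcat_bold_margin")) {
    v <- num1(key)
    if (v < 0)
      stop("threshold '", key, "' must be non-negative: ", v, call. = FALSE)
  }
  if (num1("bradford_factor_low") >= num1("bradford_factor_high"))
    stop("threshold 'bradford_factor_low' must be < 'bradford_factor_high'",
         call. = FALSE)
  invisible(x)
}

#' Load analysis thresholds from a flat key-value file
#'
#' The file is a flat YAML document (\code{key: value} per line). Absent keys
#' take the package defaults; unknown keys and out-of-range values are
#' rejected with an error naming the key.
#'
#' @param path path to the configuration file. An empty file (or one that
#'   parses to nothing) yields the full default object.
#' @return An \code{analysis_thresholds} object.
#' @export
load_thresholds <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- tryCatch(yaml::read_yaml(path),
                   error = function(e) stop("config parse error in '", path,
                                            "': ", conditionMessage(e),
                                            call. = FALSE))
  if (is.null(vals)) vals <- list()
  if (!is.list(vals))
    stop("config file '", path, "' is not a flat key: value document",
         call. = FALSE)
  defaults <- analysis_thresholds()
  unknown <- setdiff(names(vals), names(unclass(defaults)))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(analysis_thresholds, vals)
}

#' Serialize analysis thresholds to a flat key-value file
#'
#' A copy of the configuration is written into every pipeline output
#' directory for provenance; \code{load_thresholds()} parses it back to an
#' equal object.
#'
#' @param x an \code{analysis_thresholds} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_thresholds <- function(x, path) {
  validate_thresholds(x)
  yaml::write_yaml(unclass(x), path)
  invisible(path)
}

#' @export
print.analysis_thresholds <- function(x, ...) {
  cat("Analysis thresholds:\n")
  for (key in names(unclass(x)))
    cat(sprintf("  %-24s %s\n", key, format(x[[key]])))
  invisible(x)
}
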