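#' Strain and time-point layout of the experiment
#'
#' Two strains (the moderate producer NG14 and the hyper-producer RUTC30)
#' sampled at 1, 3, 6 and 24 h of lactose feeding, each hybridized against
#' its own time-0 reference.
#'
#' @return Character vector of the 8 condition labels, strain first
#'   (e.g. \code{"NG14_1h"}), in canonical column order.
#' @export
condition_levels <- function() {
  as.vector(t(outer(strain_levels(), paste0(time_levels(), "h"), paste, sep = "_")))
}

#' @rdname condition_levels
#' @export
strain_levels <- function() c("NG14", "RUTC30")

#' @rdname condition_levels
#' @export
time_levels <- function() c(1, 3, 6, 24)

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items, used
#' for cluster-recovery checks against simulation ground truth. Items with
#' \code{NA} in either labeling are dropped.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return Numeric scalar in [-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- !(is.na(a) | is.na(b))
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2) stop("need at least 2 jointly labelled items", call. = FALSE)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

#' Round half away from zero
#'
#' Unlike base \code{round()} (banker's rounding), ties go away from zero,
#' matching how integer percentages are conventionally printed in tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# shared internal: write a data.frame as plain TSV
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
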