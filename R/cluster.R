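#' Build the regulated-gene expression matrix
#'
#' Averages replicate columns of the ratio table into one log2 ratio per
#' condition and keeps the genes regulated in at least one strain and time
#' point. A condition with no surviving replicate stays missing.
#'
#' @param ratio_table genes x condition_replicate matrix.
#' @param genes character vector of regulated gene ids (the union across
#'   strains from \code{\link{consolidate_and_venn}}).
#' @return genes x 8 matrix of log2 ratios with NAs where discarded.
#' @export
build_expression_matrix <- function(ratio_table, genes) {
  conds <- condition_levels()
  mat <- matrix(NA_real_, nrow = length(genes), ncol = length(conds),
                dimnames = list(genes, conds))
  sub <- ratio_table[genes, , drop = FALSE]
  for (i in seq_along(conds)) {
    cols <- grep(paste0("^", conds[i], "_r\\d+$"), colnames(sub))
    x <- sub[, cols, drop = FALSE]
    n <- rowSums(!is.na(x))
    m <- rowMeans(x, na.rm = TRUE)
    mat[, i] <- ifelse(n >= 1, m, NA_real_)
  }
  mat
}

#' Filter genes by missing-value fraction
#'
#' Retains genes whose fraction of missing conditions is at most
#' \code{max_fraction} (strictly more is removed). Missing values are kept
#' masked here; distance computations impute them as 0 (the no-change value
#' on the log2-ratio scale) via \code{\link{impute_zero}}.
#'
#' @param mat expression matrix with NAs.
#' @param max_fraction maximum tolerated missing fraction per gene.
#' @return The filtered matrix (still containing NAs).
#' @export
filter_missing <- function(mat, max_fraction = 0.30) {
  frac <- rowMeans(is.na(mat))
  out <- mat[frac <= max_fraction, , drop = FALSE]
  if (nrow(out) == 0)
    stop("pipeline error: no gene passes the missing-value filter",
         call. = FALSE)
  out
}

#' @rdname filter_missing
#' @export
impute_zero <- function(mat) {
  mat[is.na(mat)] <- 0
  mat
}

#' Choose the number of clusters from an average-linkage dendrogram
#'
#' Builds the Euclidean-distance, average-linkage dendrogram and returns the
#' K whose cut sits at the largest relative merge-height gap, scanned over
#' \code{k_range}. A structureless matrix (all merge heights ~0) returns the
#' lower scan bound with a warning.
#'
#' @param mat expression matrix (NAs imputed as 0 for distances).
#' @param k_range candidate cluster numbers.
#' @return Integer K; deterministic for a given matrix.
#' @export
choose_k <- function(mat, k_range = 2:15) {
  n <- nrow(mat)
  if (n < 20) stop("need >= 20 genes to choose K", call. = FALSE)
  hc <- stats::hclust(stats::dist(impute_zero(mat)), method = "average")
  h <- hc$height  # ascending
  ks <- k_range[k_range >= 2 & k_range < n]
  if (max(h) < 1e-12) {
    warning("degenerate structure: all merge heights are zero", call. = FALSE)
    return(min(ks))
  }
  eps <- 1e-12
  ratio <- (h[n - ks + 1] + eps) / (h[n - ks] + eps)
  ks[which.max(ratio)]
}

#' One K-means run (Lloyd iterations, Euclidean distance)
#'
#' Random-point initialization from the seed, distance-weighted (k-means++:
#' the first centre is a uniform random gene, each further centre a random
#' gene drawn with probability proportional to its squared distance from
#' the nearest centre chosen so far); assignments and centroids alternate
#' until the assignment stabilizes or 300 iterations pass. An emptied
#' cluster is re-seeded from the point farthest from its current centroid.
#'
#' @param mat numeric matrix (no NAs; impute first).
#' @param K number of clusters (<= number of rows).
#' @param seed RNG seed for the initialization.
#' @param max_iter iteration cap.
#' @return Integer label vector (1..K), named by rownames.
#' @export
kmeans_run <- function(mat, K, seed, max_iter = 300) {
  n <- nrow(mat)
  if (K > n) stop("input error: K exceeds the number of genes", call. = FALSE)
  if (anyNA(mat)) stop("input error: matrix contains NAs; impute first",
                       call. = FALSE)
  set.seed(seed)
  picked <- integer(K)
  picked[1] <- sample.int(n, 1)
  if (K > 1) {
    d2near <- rowSums(sweep(mat, 2, mat[picked[1], ])^2)
    for (k in 2:K) {
      if (all(d2near == 0)) picked[k] <- sample.int(n, 1)
      else picked[k] <- sample.int(n, 1, prob = d2near)
      d2near <- pmin(d2near, rowSums(sweep(mat, 2, mat[picked[k], ])^2))
    }
  }
  centers <- mat[picked, , drop = FALSE]
  labels <- integer(n)
  for (iter in seq_len(max_iter)) {
    d2 <- sapply(seq_len(K), function(k)
      rowSums(sweep(mat, 2, centers[k, ])^2))
    if (K == 1) d2 <- matrix(d2, ncol = 1)
    new_labels <- max.col(-d2, ties.method = "first")
    dmin <- d2[cbind(seq_len(n), new_labels)]
    for (k in setdiff(seq_len(K), unique(new_labels))) {
      j <- which.max(dmin)
      new_labels[j] <- k
      centers[k, ] <- mat[j, ]
      dmin[j] <- 0
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (k in seq_len(K))
      centers[k, ] <- colMeans(mat[labels == k, , drop = FALSE])
  }
  stats::setNames(labels, rownames(mat))
}

#' Aggregate K-means runs through co-occurrence
#'
#' The co-occurrence matrix C[i, j] is the fraction of runs in which genes i
#' and j share a label. Final clusters are the cut of an average-linkage
#' hierarchical clustering of the distance 1 - C at height 1 - threshold.
#' Singleton groups, and genes whose mean co-occurrence with the rest of
#' their group falls below the threshold, are marked unclustered. The final
#' cluster count may differ from the per-run K.
#'
#' @param labels_list list of >= 2 label vectors over identical gene sets.
#' @param threshold co-occurrence threshold in [0, 1].
#' @return List of class \code{"cluster_assignment"}: \code{$cluster}
#'   (named integer, NA = unclustered; ids renumbered by decreasing size),
#'   \code{$cooccurrence} (symmetric matrix), \code{$n_runs}.
#' @export
consensus_aggregate <- function(labels_list, threshold = 0.60) {
  if (length(labels_list) < 2)
    stop("need >= 2 K-means runs to aggregate", call. = FALSE)
  ids <- names(labels_list[[1]])
  for (l in labels_list)
    if (!identical(names(l), ids))
      stop("input error: inconsistent gene sets across runs", call. = FALSE)
  n <- length(ids)
  C <- matrix(0, n, n, dimnames = list(ids, ids))
  for (l in labels_list) C <- C + outer(l, l, "==")
  C <- C / length(labels_list)
  hc <- stats::hclust(stats::as.dist(1 - C), method = "average")
  # guard against tiny floating-point non-monotonicity in tied merge heights
  hc$height <- cummax(round(hc$height, 10))
  grp <- stats::cutree(hc, h = 1 - threshold)
  unclustered <- logical(n)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) == 1) {
      unclustered[idx] <- TRUE
    } else {
      mean_co <- (rowSums(C[idx, idx, drop = FALSE]) - 1) / (length(idx) - 1)
      unclustered[idx[mean_co < threshold]] <- TRUE
    }
  }
  cluster <- ifelse(unclustered, NA_integer_, grp)
  kept <- stats::na.omit(unique(cluster))
  sizes <- vapply(kept, function(g) sum(cluster == g, na.rm = TRUE), 0L)
  remap <- stats::setNames(order(order(-sizes, kept)), kept)
  cluster <- unname(remap[as.character(cluster)])
  names(cluster) <- ids
  out <- list(cluster = cluster, cooccurrence = C,
              n_runs = length(labels_list))
  class(out) <- "cluster_assignment"
  out
}

#' Direction of a cluster mean profile
#'
#' The sign of the mean-profile value with the largest magnitude; an exact
#' zero extremum is an error (reported, never guessed).
#'
#' @param profile numeric mean profile over the 8 conditions.
#' @return "up" or "down".
#' @export
classify_direction <- function(profile) {
  i <- which.max(abs(profile))
  if (profile[i] == 0)
    stop("tie error: cluster mean profile has a zero extremum", call. = FALSE)
  if (profile[i] > 0) "up" else "down"
}

#' Consensus clustering of the expression matrix
#'
#' Runs the full consensus procedure: K from the dendrogram gap rule,
#' \code{kmeans_runs} independent K-means runs under seeds derived from the
#' master seed, co-occurrence aggregation, then per-cluster mean profiles
#' (computed on the masked matrix, missing values excluded) and directions.
#'
#' @param mat filtered expression matrix (NAs allowed; distances use zero
#'   imputation).
#' @param thresholds an \code{\link{analysis_thresholds}} object.
#' @param seed master seed for the K-means initializations.
#' @param K optional forced K (skips \code{\link{choose_k}}).
#' @return Object of class \code{"consensus_clust"}: \code{$assignment}
#'   (data.frame gene_id, cluster, direction), \code{$cluster} (named
#'   vector), \code{$profiles} (cluster x condition matrix),
#'   \code{$directions}, \code{$K}, \code{$cooccurrence}, \code{$runs}.
#' @export
consensus_cluster <- function(mat, thresholds = analysis_thresholds(),
                              seed = 1L, K = NULL) {
  validate_thresholds(thresholds)
  imp <- impute_zero(mat)
  if (is.null(K)) K <- choose_k(mat)
  run_seeds <- seed + seq_len(thresholds$kmeans_runs)
  labels_list <- lapply(run_seeds, function(s) kmeans_run(imp, K, s))
  agg <- consensus_aggregate(labels_list, thresholds$cooccurrence_threshold)
  cl <- agg$cluster
  kept <- sort(unique(cl[!is.na(cl)]))
  profiles <- t(vapply(kept, function(g)
    colMeans(mat[names(cl)[!is.na(cl) & cl == g], , drop = FALSE],
             na.rm = TRUE), numeric(ncol(mat))))
  rownames(profiles) <- kept
  directions <- vapply(kept, function(g)
    classify_direction(profiles[as.character(g), ]), character(1))
  names(directions) <- kept
  assignment <- data.frame(
    gene_id = names(cl),
    cluster = ifelse(is.na(cl), "unclustered", as.character(cl)),
    direction = ifelse(is.na(cl), NA_character_,
                       directions[as.character(cl)]),
    stringsAsFactors = FALSE
  )
  out <- list(assignment = assignment, cluster = cl, profiles = profiles,
              directions = directions, K = K,
              cooccurrence = agg$cooccurrence,
              runs = thresholds$kmeans_runs)
  class(out) <- "consensus_clust"
  out
}

#' @export
print.consensus_clust <- function(x, ...) {
  n_ass <- sum(!is.na(x$cluster))
  cat("Consensus clustering:", length(x$cluster), "genes;",
      "K-means K =", x$K, "->", nrow(x$profiles), "final clusters\n")
  cat("  assigned:", n_ass, " unclustered:", sum(is.na(x$cluster)), "\n")
  tab <- table(x$cluster)
  for (g in names(tab))
    cat(sprintf("  cluster %s: %d genes, %s\n", g, tab[[g]],
                x$directions[[g]]))
  invisible(x)
}
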