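#' Default kinetic archetype profiles
#'
#' Nine hand-written step/ramp log2-ratio profiles over the 8 conditions
#' (2 strains x 4 time points vs. time 0) that qualitatively reproduce the
#' kinetic classes seen in lactose-induction time courses of cellulase
#' producer strains: early induction in the moderate producer only (1),
#' early/late repression classes (2-4, 6), late hyper-producer-specific
#' induction (5), 6-h induction in the moderate producer only (7), and
#' shared early induction at moderate and high amplitude (8, 9).
#'
#' They are configuration data, not code: pass a modified matrix through
#' \code{\link{synthetic_config}} to change the simulated biology.
#'
#' @return A 9 x 8 numeric matrix; rows are archetypes "1".."9", columns
#'   \code{\link{condition_levels}()}.
#' @export
default_archetypes <- function() {
  m <- rbind(
    #      NG14: 1h   3h   6h  24h  RUTC30: 1h   3h   6h  24h
    "1" = c(     1.5,  2.5, 2.5, 2.5,        0.0, 0.0, 0.0, 0.0),
    "2" = c(     0.0, -1.5,-2.0,-2.0,        0.0, 0.0,-1.5,-2.0),
    "3" = c(    -2.0, -2.0,-1.5,-1.5,        0.0, 0.0, 0.0, 0.0),
    "4" = c(     0.0, -2.5,-3.0,-3.0,        0.0, 0.0, 0.0, 0.0),
    "5" = c(     0.0,  0.0, 0.0, 0.0,        0.0, 0.0, 0.0, 2.0),
    "6" = c(     0.0,  0.0, 0.0, 0.0,        0.0, 0.0,-1.5,-2.0),
    "7" = c(     0.0,  0.0, 2.0, 2.0,        0.0, 0.0, 0.0, 0.0),
    "8" = c(     1.5,  2.0, 2.5, 2.5,        1.5, 2.0, 2.5, 2.5),
    "9" = c(     3.0,  4.0, 4.5, 5.0,        2.0, 2.5, 3.0, 3.5)
  )
  colnames(m) <- condition_levels()
  m
}

#' Synthetic dataset configuration
#'
#' Parameters of the ground-truth simulator that feeds every pipeline stage.
#' Defaults emulate the study conditions: two strains, four time points
#' against a time-0 reference, several hundred truly regulated genes drawn
#' from 9 kinetic archetypes, multiple probes per transcript with additive
#' Gaussian noise on the log2 scale plus a nondetectable background
#' population, negative-binomial time-0 counts with a small set of genes at
#' >= 16-fold basal difference between strains, and mutations placed inside
#' and outside 800-bp gene windows.
#'
#' @param n_genes total number of gene models.
#' @param n_regulated number of truly regulated genes (<= n_genes).
#' @param archetype_set 9 x 8 matrix of archetype log2 ratios.
#' @param archetype_weights relative sizes of the 9 archetype classes.
#' @param probe_per_gene probes per transcript on each hybridization.
#' @param noise_sd SD of additive Gaussian noise on the log2-ratio scale.
#' @param nondetectable_fraction fraction of probes drawn below background.
#' @param non_cds_fraction fraction of probes falling outside the CDS.
#' @param strand_mismatch_fraction fraction of probes on the wrong strand.
#' @param n_notfound "not found" features per hybridization (background
#'   population used for threshold estimation).
#' @param nb_dispersion negative-binomial dispersion of time-0 counts
#'   (variance = mu + dispersion * mu^2); values < 1e-8 give Poisson counts.
#' @param library_size total mapped reads per RNA-seq sample.
#' @param n_basal_genes number of genes given a true basal-expression offset.
#' @param basal_offset_range absolute log2 offset range for those genes
#'   (all >= 4, i.e. >= 16-fold).
#' @param n_mutations number of simulated mutations.
#' @param near_gene_fraction fraction of mutations placed inside some gene's
#'   +/- 800 bp window.
#' @param genome_length bp of the single simulated contig.
#' @param seed master seed; fixed seed implies byte-identical outputs.
#' @return An object of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(n_genes = 2000,
                             n_regulated = 550,
                             archetype_set = default_archetypes(),
                             archetype_weights = c(113, 67, 35, 124, 59, 50, 40, 32, 12),
                             probe_per_gene = 3,
                             noise_sd = 0.2,
                             nondetectable_fraction = 0.05,
                             non_cds_fraction = 0.05,
                             strand_mismatch_fraction = 0.02,
                             n_notfound = 300,
                             nb_dispersion = 0.05,
                             library_size = 5e6,
                             n_basal_genes = 25,
                             basal_offset_range = c(5, 7),
                             n_mutations = 150,
                             near_gene_fraction = 0.5,
                             genome_length = 9e6,
                             seed = 42L) {
  stopifnot(n_regulated <= n_genes, noise_sd >= 0,
            nrow(archetype_set) == 9, ncol(archetype_set) == 8,
            length(archetype_weights) == 9, all(archetype_weights > 0),
            probe_per_gene >= 1, nondetectable_fraction >= 0,
            nondetectable_fraction <= 1, nb_dispersion >= 0,
            library_size > 0, n_basal_genes <= n_genes,
            all(basal_offset_range >= 4), n_mutations >= 0,
            near_gene_fraction >= 0, near_gene_fraction <= 1,
            genome_length > 0)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate non-overlapping gene models on a single contig
#'
#' Places \code{n_genes} genes left to right with random coding-span lengths
#' (900-2400 bp) and intergenic gaps of at least 1700 bp, so that the
#' +/- 800 bp mutation windows of adjacent genes can never overlap. Each
#' gene has 1-3 exons tiling its coding span around short introns; the start
#' codon sits at the 5' end of the span (strand-aware).
#'
#' @param n_genes number of genes to place.
#' @param genome_length contig length in bp (1-based inclusive coordinates).
#' @param seed RNG seed; the same seed reproduces the collection exactly.
#' @return An object of class \code{"gene_models"}: list with data.frames
#'   \code{$genes} (gene_id, contig, start, end, strand, start_codon,
#'   stop_codon) and \code{$exons} (gene_id, start, end).
#' @export
generate_gene_models <- function(n_genes, genome_length, seed = 1L) {
  set.seed(seed)
  lens <- sample(seq(900L, 2400L, by = 3L), n_genes, replace = TRUE)
  gaps <- sample(1700:2600, n_genes, replace = TRUE)
  starts <- cumsum(c(gaps[1], lens[-n_genes] + gaps[-1]))
  ends <- starts + lens - 1L
  if (ends[n_genes] + 800L > genome_length)
    stop("capacity error: cannot place ", n_genes, " genes with >= 1700 bp ",
         "spacing on a ", genome_length, " bp contig", call. = FALSE)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("g%05d", seq_len(n_genes)),
    contig = "contig_1",
    start = starts, end = ends, strand = strand,
    start_codon = ifelse(strand == "+", starts, ends),
    stop_codon = ifelse(strand == "+", ends, starts),
    stringsAsFactors = FALSE
  )
  exon_list <- vector("list", n_genes)
  n_exons <- sample(1:3, n_genes, replace = TRUE)
  for (i in seq_len(n_genes)) {
    k <- n_exons[i]
    if (k > 1) {
      introns <- sample(60:200, k - 1, replace = TRUE)
      if (lens[i] - sum(introns) < 100L * k) k <- 1L
    }
    if (k == 1) {
      exon_list[[i]] <- data.frame(gene_id = genes$gene_id[i],
                                   start = starts[i], end = ends[i])
    } else {
      exon_total <- lens[i] - sum(introns)
      base <- exon_total %/% k
      elens <- rep(base, k)
      elens[k] <- elens[k] + exon_total - base * k
      es <- integer(k); ee <- integer(k)
      pos <- starts[i]
      for (j in seq_len(k)) {
        es[j] <- pos
        ee[j] <- pos + elens[j] - 1L
        pos <- ee[j] + 1L + if (j < k) introns[j] else 0L
      }
      exon_list[[i]] <- data.frame(gene_id = genes$gene_id[i],
                                   start = es, end = ee)
    }
  }
  out <- list(genes = genes, exons = do.call(rbind, exon_list))
  class(out) <- "gene_models"
  out
}

#' @export
print.gene_models <- function(x, ...) {
  cat("Gene models:", nrow(x$genes), "genes,", nrow(x$exons),
      "exons on", length(unique(x$genes$contig)), "contig(s)\n")
  invisible(x)
}

#' Generate true expression profiles and ground truth
#'
#' Regulated genes follow one of the 9 kinetic archetypes plus
#' Normal(0, noise_sd) noise; unregulated genes are pure noise. The returned
#' ground truth records each gene's archetype and its true regulation call
#' (up / down / none per strain x time, from the archetype value against the
#' default |log2 FC| > 1 rule).
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param seed RNG seed (defaults derive from the master seed).
#' @return List with \code{$matrix} (n_genes x 8 log2 ratios, rownames are
#'   gene ids), \code{$true_cluster} (named archetype id, NA when
#'   unregulated) and \code{$true_regulated} (n_genes x 8 character matrix).
#' @export
generate_profiles <- function(cfg, seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(seed)
  n <- cfg$n_genes
  ids <- sprintf("g%05d", seq_len(n))
  regulated <- sort(sample(n, cfg$n_regulated))
  arch <- rep(1:9, times = round_class_sizes(cfg$archetype_weights, cfg$n_regulated))
  arch <- sample(arch)  # shuffle archetype order over the regulated genes
  true_cluster <- rep(NA_integer_, n)
  true_cluster[regulated] <- arch
  mat <- matrix(stats::rnorm(n * 8, sd = cfg$noise_sd), nrow = n,
                dimnames = list(ids, condition_levels()))
  mat[regulated, ] <- mat[regulated, ] + cfg$archetype_set[arch, , drop = FALSE]
  true_mat <- matrix(0, nrow = n, ncol = 8,
                     dimnames = list(ids, condition_levels()))
  true_mat[regulated, ] <- cfg$archetype_set[arch, , drop = FALSE]
  reg_call <- matrix("none", nrow = n, ncol = 8,
                     dimnames = list(ids, condition_levels()))
  reg_call[true_mat > 1] <- "up"
  reg_call[true_mat < -1] <- "down"
  names(true_cluster) <- ids
  list(matrix = mat, true_matrix = true_mat,
       true_cluster = true_cluster, true_regulated = reg_call)
}

# split n items into 9 classes proportional to weights, exactly summing to n
round_class_sizes <- function(weights, n) {
  raw <- weights / sum(weights) * n
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  sizes
}

#' Generate probe-level two-channel hybridization tables
#'
#' For every gene x condition x replicate, \code{probe_per_gene} probes carry
#' the true log2 ratio plus probe-level noise; the second biological
#' replicate is dye-swapped, so its recorded log2 ratio is sign-flipped
#' until orientation correction at summarization. A configurable fraction of
#' probes falls below the background population, and each hybridization
#' carries a population of "not found" features from which the background
#' threshold is estimated downstream. An optional intensity-dependent dye
#' bias \code{bias_fun(A)} can be added to the recorded ratios to exercise
#' the lowess normalization.
#'
#' @param true_matrix n_genes x 8 matrix of true log2 ratios (from
#'   \code{\link{generate_profiles}}; use \code{$matrix} so probe noise sits
#'   on top of gene-level noise, or \code{$true_matrix} for the noise-free
#'   limit).
#' @param cfg a \code{\link{synthetic_config}}.
#' @param seed RNG seed.
#' @param bias_fun optional function of A (mean log2 intensity) returning a
#'   log2-ratio offset; NULL for no dye bias.
#' @return A data.frame with one row per feature: probe_id, gene_id, strain,
#'   time_h, replicate, dye_orientation, intensity_test, intensity_ref,
#'   in_cds, strand_match, status.
#' @export
generate_probe_signals <- function(true_matrix, cfg, seed = cfg$seed + 2L,
                                   bias_fun = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(seed)
  ids <- rownames(true_matrix)
  conds <- colnames(true_matrix)
  stopifnot(identical(conds, condition_levels()))
  grid <- expand.grid(probe = seq_len(cfg$probe_per_gene),
                      gene = seq_along(ids),
                      cond = seq_along(conds),
                      replicate = 1:2, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  strain <- sub("_.*$", "", conds[grid$cond])
  time_h <- as.numeric(sub("h$", "", sub("^.*_", "", conds[grid$cond])))
  m_true <- true_matrix[cbind(grid$gene, grid$cond)]
  noise <- if (cfg$noise_sd > 0) stats::rnorm(n, sd = cfg$noise_sd) else 0
  a_val <- stats::runif(n, 9, 14)
  orient <- ifelse(grid$replicate == 2L, "swapped", "forward")
  m_rec <- ifelse(orient == "swapped", -(m_true + noise), m_true + noise)
  if (!is.null(bias_fun)) m_rec <- m_rec + bias_fun(a_val)
  int_test <- 2^(a_val + m_rec / 2)
  int_ref <- 2^(a_val - m_rec / 2)
  nondet <- stats::runif(n) < cfg$nondetectable_fraction
  int_test[nondet] <- stats::runif(sum(nondet), 5, 25)
  int_ref[nondet] <- stats::runif(sum(nondet), 5, 25)
  probes <- data.frame(
    probe_id = sprintf("%s_p%d", ids[grid$gene], grid$probe),
    gene_id = ids[grid$gene],
    strain = strain, time_h = time_h, replicate = grid$replicate,
    dye_orientation = orient,
    intensity_test = int_test, intensity_ref = int_ref,
    in_cds = stats::runif(n) >= cfg$non_cds_fraction,
    strand_match = stats::runif(n) >= cfg$strand_mismatch_fraction,
    status = "found", stringsAsFactors = FALSE
  )
  # background ("not found") population, per hybridization
  hybs <- expand.grid(cond = seq_along(conds), replicate = 1:2,
                      KEEP.OUT.ATTRS = FALSE)
  nf_n <- nrow(hybs) * cfg$n_notfound
  nf <- data.frame(
    probe_id = sprintf("nf_%06d", seq_len(nf_n)),
    gene_id = NA_character_,
    strain = rep(sub("_.*$", "", conds[hybs$cond]), each = cfg$n_notfound),
    time_h = rep(as.numeric(sub("h$", "", sub("^.*_", "", conds[hybs$cond]))),
                 each = cfg$n_notfound),
    replicate = rep(hybs$replicate, each = cfg$n_notfound),
    dye_orientation = rep(ifelse(hybs$replicate == 2L, "swapped", "forward"),
                          each = cfg$n_notfound),
    intensity_test = pmax(abs(stats::rnorm(nf_n, 20, 5)), 1),
    intensity_ref = pmax(abs(stats::rnorm(nf_n, 20, 5)), 1),
    in_cds = FALSE, strand_match = FALSE,
    status = "not_found", stringsAsFactors = FALSE
  )
  rbind(probes, nf)
}

#' Generate per-strain time-0 RNA-seq count tables
#'
#' Negative-binomial counts with mean proportional to exon length x basal
#' expression x library size. A designated set of genes receives true basal
#' log2 offsets of at least 4 (>= 16-fold) between strains, with balanced
#' signs and high expression so that the downstream dual filter can recover
#' them; all other genes have a true offset of 0.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param true_cluster named archetype vector from
#'   \code{\link{generate_profiles}} (used to draw most basal-offset genes
#'   from the regulated population, as observed in practice).
#' @param gene_models a \code{\link{generate_gene_models}} result supplying
#'   exon lengths.
#' @param seed RNG seed.
#' @return List with \code{$counts} (data.frame gene_id, strain, reads,
#'   exon_length_bp), \code{$totals} (named total mapped reads per strain)
#'   and \code{$true_basal_logratio} (named log2 RUTC30/NG14 offsets; 0 for
#'   undesignated genes).
#' @export
generate_counts <- function(cfg, true_cluster, gene_models,
                            seed = cfg$seed + 3L) {
  stopifnot(inherits(cfg, "synthetic_config"), inherits(gene_models, "gene_models"))
  set.seed(seed)
  ids <- gene_models$genes$gene_id
  n <- length(ids)
  exon_len <- tapply(gene_models$exons$end - gene_models$exons$start + 1,
                     gene_models$exons$gene_id, sum)[ids]
  b <- stats::rlnorm(n, meanlog = 1, sdlog = 1)
  regulated <- names(true_cluster)[!is.na(true_cluster)]
  n_reg <- min(round(0.8 * cfg$n_basal_genes), length(regulated))
  designated <- c(sample(regulated, n_reg),
                  sample(setdiff(ids, regulated), cfg$n_basal_genes - n_reg))
  offset <- stats::setNames(rep(0, n), ids)
  signs <- sample(rep_len(c(1, -1), cfg$n_basal_genes))
  offset[designated] <- signs * stats::runif(cfg$n_basal_genes,
                                             cfg$basal_offset_range[1],
                                             cfg$basal_offset_range[2])
  # designated genes are forced into the well-expressed range so that the
  # read-count arm of the dual filter is informative, not limiting
  b[match(designated, ids)] <- stats::rlnorm(cfg$n_basal_genes,
                                             meanlog = 2.5, sdlog = 0.4)
  w_ng <- b * exon_len / 1e3
  w_rut <- w_ng * 2^offset
  mu_ng <- cfg$library_size * w_ng / sum(w_ng)
  mu_rut <- cfg$library_size * w_rut / sum(w_rut)
  draw <- function(mu) {
    if (cfg$nb_dispersion < 1e-8) stats::rpois(n, mu)
    else stats::rnbinom(n, mu = mu, size = 1 / cfg$nb_dispersion)
  }
  counts <- rbind(
    data.frame(gene_id = ids, strain = "NG14", reads = draw(mu_ng),
               exon_length_bp = as.integer(exon_len), stringsAsFactors = FALSE),
    data.frame(gene_id = ids, strain = "RUTC30", reads = draw(mu_rut),
               exon_length_bp = as.integer(exon_len), stringsAsFactors = FALSE)
  )
  totals <- tapply(counts$reads, counts$strain, sum)
  list(counts = counts, totals = c(totals),
       true_basal_logratio = offset)
}

#' Generate a mutation table with placement ground truth
#'
#' A \code{near_gene_fraction} of mutations is placed uniformly inside some
#' gene's [start - 800, end + 800] window (so across promoter, exon, intron
#' and terminator zones); the remainder is placed in intergenic space outside
#' every window. Types are drawn from SNV / InDel; lineage labels record the
#' mutagenesis branch carrying the variant.
#'
#' @param gene_models a \code{\link{generate_gene_models}} result.
#' @param cfg a \code{\link{synthetic_config}}.
#' @param seed RNG seed.
#' @return List with \code{$mutations} (data.frame contig, position, type,
#'   lineages) and \code{$mutation_target} (named by mutation id: the gene
#'   whose window contains the mutation, NA for intergenic placements).
#' @export
generate_mutations <- function(gene_models, cfg, seed = cfg$seed + 4L) {
  stopifnot(inherits(gene_models, "gene_models"), inherits(cfg, "synthetic_config"))
  set.seed(seed)
  g <- gene_models$genes
  window <- 800L
  n_near <- round(cfg$n_mutations * cfg$near_gene_fraction)
  n_far <- cfg$n_mutations - n_near
  target <- rep(NA_character_, cfg$n_mutations)
  pos <- integer(cfg$n_mutations)
  if (n_near > 0) {
    gi <- sample(nrow(g), n_near, replace = TRUE)
    pos[seq_len(n_near)] <- mapply(function(s, e)
      sample(seq(max(1L, s - window), e + window), 1L),
      g$start[gi], g$end[gi])
    target[seq_len(n_near)] <- g$gene_id[gi]
  }
  if (n_far > 0) {
    win_start <- pmax(1L, g$start - window)
    win_end <- g$end + window
    gap_start <- c(1L, win_end + 1L)
    gap_end <- c(win_start - 1L, cfg$genome_length)
    ok <- gap_end >= gap_start
    gap_start <- gap_start[ok]; gap_end <- gap_end[ok]
    if (!length(gap_start))
      stop("capacity error: no intergenic space outside gene windows",
           call. = FALSE)
    widths <- gap_end - gap_start + 1
    pick <- sample(length(gap_start), n_far, replace = TRUE,
                   prob = widths / sum(widths))
    pos[n_near + seq_len(n_far)] <- gap_start[pick] +
      floor(stats::runif(n_far) * widths[pick])
  }
  mut <- data.frame(
    mutation_id = sprintf("m%04d", seq_len(cfg$n_mutations)),
    contig = "contig_1",
    position = pos,
    type = sample(c("SNV", "InDel"), cfg$n_mutations, replace = TRUE,
                  prob = c(0.85, 0.15)),
    lineages = sample(c("NG14 & RUT C30", "RUT C30"), cfg$n_mutations,
                      replace = TRUE, prob = c(0.54, 0.46)),
    stringsAsFactors = FALSE
  )
  names(target) <- mut$mutation_id
  ord <- sample(cfg$n_mutations)  # shuffle so near/far placements interleave
  list(mutations = mut[ord, , drop = FALSE], mutation_target = target[ord])
}

#' Generate functional-category (FunCat-style) labels
#'
#' Every gene receives a status (classified / unclassified / unknown);
#' classified genes carry one numeric category id. Category assignment is
#' correlated with the kinetic archetype of regulated genes so that the
#' category-by-cluster table has visible structure.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param true_cluster named archetype vector from
#'   \code{\link{generate_profiles}}.
#' @param seed RNG seed.
#' @return data.frame gene_id, category_id, category_name, status.
#' @export
generate_funcat_labels <- function(cfg, true_cluster, seed = cfg$seed + 5L) {
  set.seed(seed)
  cats <- data.frame(
    category_id = c("12.01", "01.00", "01.25", "20.01", "01.01", "01.06",
                    "11.02.03.04", "01.25.03", "02.00", "32.01", "20.09.07",
                    "30.00", "01.20", "32.07"),
    category_name = c("Ribosome biogenesis", "Metabolism",
                      "Extracellular metabolism (CAZymes)",
                      "Transported compounds", "Amino acid metabolism",
                      "Lipid, fatty acid and isoprenoid metabolism",
                      "Transcriptional control",
                      "Extracellular protein degradation", "Energy metabolism",
                      "Stress response", "Vesicular transport (secretion)",
                      "Cellular communication, signal transduction",
                      "Secondary metabolism", "Detoxification"),
    stringsAsFactors = FALSE
  )
  ids <- names(true_cluster)
  n <- length(ids)
  status <- sample(c("classified", "unclassified", "unknown"), n,
                   replace = TRUE, prob = c(0.8, 0.1, 0.1))
  cat_idx <- sample(nrow(cats), n, replace = TRUE)
  reg <- !is.na(true_cluster)
  prefer <- ((true_cluster[reg] - 1L) %% nrow(cats)) + 1L
  use_pref <- stats::runif(sum(reg)) < 0.6
  cat_idx[reg][use_pref] <- prefer[use_pref]
  data.frame(
    gene_id = ids,
    category_id = ifelse(status == "classified", cats$category_id[cat_idx], NA),
    category_name = ifelse(status == "classified", cats$category_name[cat_idx], NA),
    status = status, stringsAsFactors = FALSE
  )
}

#' Simulate a fed-batch cultivation series with known specific productivity
#'
#' Protein accumulates at a constant specific productivity \code{q}
#' (mg protein per g cell per h) on a constant biomass, so inverting
#' \code{\link{specific_productivity}} on the result must recover \code{q}.
#' Carbon columns are per-interval increments at a fixed production yield.
#'
#' @param q true specific productivity, mg/g_cell/h.
#' @param biomass constant cell dry weight, g/L.
#' @param p0 protein concentration at feed start, g/L.
#' @param times sampling times in h (0 = feed start).
#' @param carbon_yield gC produced per gC consumed.
#' @param carbon_rate gC consumed per hour.
#' @return data.frame time_h, protein_bradford, biomass_dw, carbon_consumed,
#'   carbon_produced.
#' @export
simulate_cultivation <- function(q = 4, biomass = 20, p0 = 0.2,
                                 times = seq(0, 48, by = 2),
                                 carbon_yield = 0.95, carbon_rate = 0.5) {
  stopifnot(q >= 0, biomass > 0, !is.unsorted(times, strictly = TRUE))
  consumed <- c(0, diff(times)) * carbon_rate
  data.frame(
    time_h = times,
    protein_bradford = p0 + q * biomass * times / 1000,
    biomass_dw = biomass,
    carbon_consumed = consumed,
    carbon_produced = carbon_yield * consumed
  )
}

#' Simulate a complete synthetic dataset
#'
#' Runs every generator under seeds derived from the master seed and bundles
#' inputs plus ground truth for all downstream stages.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @return An object of class \code{"kinduce_sim"}: list with
#'   \code{gene_models}, \code{profiles} (matrix + truth), \code{probes},
#'   \code{counts}, \code{mutations}, \code{funcat}, \code{cultivation} and
#'   a merged \code{truth} list.
#' @export
simulate_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  gm <- generate_gene_models(cfg$n_genes, cfg$genome_length, seed = cfg$seed)
  prof <- generate_profiles(cfg)
  probes <- generate_probe_signals(prof$matrix, cfg)
  cnt <- generate_counts(cfg, prof$true_cluster, gm)
  mut <- generate_mutations(gm, cfg)
  funcat <- generate_funcat_labels(cfg, prof$true_cluster)
  cult <- simulate_cultivation()
  out <- list(
    config = cfg, gene_models = gm, profiles = prof, probes = probes,
    counts = cnt, mutations = mut$mutations, funcat = funcat,
    cultivation = cult,
    truth = list(true_cluster = prof$true_cluster,
                 true_regulated = prof$true_regulated,
                 true_basal_logratio = cnt$true_basal_logratio,
                 mutation_target = mut$mutation_target)
  )
  class(out) <- "kinduce_sim"
  out
}

#' @export
print.kinduce_sim <- function(x, ...) {
  cat("Synthetic lactose-induction dataset\n")
  cat("  genes:", x$config$n_genes, "(", x$config$n_regulated, "regulated )\n")
  cat("  probes:", nrow(x$probes), "rows;  mutations:", nrow(x$mutations), "\n")
  cat("  seed:", x$config$seed, "\n")
  invisible(x)
}

#' Write a synthetic dataset to disk in the pipeline's input formats
#'
#' GFF3 gene models, TSV probe/count/mutation/FunCat/cultivation tables, a
#' read-totals sidecar and the ground truth as JSON.
#'
#' @param sim a \code{\link{simulate_dataset}} result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_synthetic_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "kinduce_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gene_models_gff3(sim$gene_models, file.path(dir, "gene_models.gff3"))
  write_tsv(sim$probes, file.path(dir, "probes.tsv"))
  write_tsv(sim$counts$counts, file.path(dir, "counts.tsv"))
  write_tsv(data.frame(strain = names(sim$counts$totals),
                       total_mapped_reads = as.numeric(sim$counts$totals)),
            file.path(dir, "counts_totals.tsv"))
  write_tsv(sim$mutations, file.path(dir, "mutations.tsv"))
  write_tsv(sim$funcat, file.path(dir, "funcat.tsv"))
  write_tsv(sim$cultivation, file.path(dir, "cultivation.tsv"))
  jsonlite::write_json(
    list(true_cluster = as.list(sim$truth$true_cluster),
         true_basal_logratio = as.list(sim$truth$true_basal_logratio),
         mutation_target = as.list(sim$truth$mutation_target)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, na = "null",
    digits = NA)
  invisible(dir)
}

#' Write gene models as GFF3
#'
#' @param gene_models a \code{gene_models} object.
#' @param path output GFF3 path.
#' @return \code{path}, invisibly.
#' @export
write_gene_models_gff3 <- function(gene_models, path) {
  g <- gene_models$genes
  e <- gene_models$exons
  gr_g <- GenomicRanges::GRanges(g$contig,
                                 IRanges::IRanges(g$start, g$end),
                                 strand = g$strand, type = "gene",
                                 ID = g$gene_id)
  gr_e <- GenomicRanges::GRanges(
    g$contig[match(e$gene_id, g$gene_id)],
    IRanges::IRanges(e$start, e$end),
    strand = g$strand[match(e$gene_id, g$gene_id)],
    type = "exon",
    ID = sprintf("%s_exon%03d", e$gene_id, stats::ave(seq_len(nrow(e)),
                                                      e$gene_id, FUN = seq_along)),
    Parent = e$gene_id)
  rtracklayer::export(c(gr_g, gr_e), path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Accepts the layout written by \code{\link{write_gene_models_gff3}} (or any
#' GFF3 with \code{gene} and \code{exon} features whose exons carry a
#' \code{Parent} gene id).
#'
#' @param path GFF3 file path.
#' @return A \code{gene_models} object.
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gg <- gr[gr$type == "gene"]
  ee <- gr[gr$type == "exon"]
  strand_g <- as.character(GenomicRanges::strand(gg))
  genes <- data.frame(
    gene_id = gg$ID,
    contig = as.character(GenomicRanges::seqnames(gg)),
    start = GenomicRanges::start(gg), end = GenomicRanges::end(gg),
    strand = strand_g,
    start_codon = ifelse(strand_g == "+", GenomicRanges::start(gg),
                         GenomicRanges::end(gg)),
    stop_codon = ifelse(strand_g == "+", GenomicRanges::end(gg),
                        GenomicRanges::start(gg)),
    stringsAsFactors = FALSE
  )
  parent <- as.character(S4Vectors::unstrsplit(ee$Parent, ","))
  exons <- data.frame(gene_id = parent,
                      start = GenomicRanges::start(ee),
                      end = GenomicRanges::end(ee),
                      stringsAsFactors = FALSE)
  out <- list(genes = genes, exons = exons[order(exons$gene_id, exons$start), ])
  rownames(out$exons) <- NULL
  class(out) <- "gene_models"
  out
}
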