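test_that("gene models respect bounds, determinism and window-safe spacing", {
  gm1 <- generate_gene_models(1, 1e4, seed = 3)
  expect_equal(nrow(gm1$genes), 1)
  expect_gte(gm1$genes$start, 1)
  expect_lte(gm1$genes$end, 1e4)

  a <- generate_gene_models(50, 1e6, seed = 7)
  b <- generate_gene_models(50, 1e6, seed = 7)
  expect_identical(a, b)

  gm <- generate_gene_models(100, 1e6, seed = 11)
  g <- gm$genes[order(gm$genes$start), ]
  gaps <- g$start[-1] - g$end[-nrow(g)] - 1
  expect_true(all(gaps >= 1601))  # +/-800 bp windows can never span two genes
  expect_error(generate_gene_models(1000, 1e5, seed = 1), "capacity")
})

test_that("profiles follow the archetypes exactly at zero noise", {
  cfg <- synthetic_config(n_genes = 60, n_regulated = 45, noise_sd = 0)
  prof <- generate_profiles(cfg)
  reg <- names(prof$true_cluster)[!is.na(prof$true_cluster)]
  for (g in reg)
    expect_equal(unname(prof$matrix[g, ]),
                 unname(cfg$archetype_set[prof$true_cluster[g], ]))
  unreg <- setdiff(rownames(prof$matrix), reg)
  expect_true(all(prof$matrix[unreg, ] == 0))
})

test_that("the hyper-producer-specific late archetype is silent in NG14 and >1 only at 24 h", {
  a5 <- default_archetypes()["5", ]
  expect_true(all(a5[grep("^NG14", names(a5))] == 0))
  rut <- a5[grep("^RUTC30", names(a5))]
  expect_true(a5[["RUTC30_24h"]] > 1)
  expect_true(all(rut[names(rut) != "RUTC30_24h"] <= 1))
})

test_that("realized gene-level noise matches the configured SD", {
  cfg <- synthetic_config(n_genes = 1500, n_regulated = 800, noise_sd = 0.3,
                          seed = 5)
  prof <- generate_profiles(cfg)
  reg <- names(prof$true_cluster)[!is.na(prof$true_cluster)]
  resid <- prof$matrix[reg, ] - prof$true_matrix[reg, ]
  n <- length(resid)
  se <- cfg$noise_sd / sqrt(2 * (n - 1))  # SE of an SD estimate
  expect_lt(abs(sd(resid) - cfg$noise_sd), 3 * se)
})

test_that("probe signals encode the truth and the dye swap flips recorded M", {
  cfg <- synthetic_config(n_genes = 40, n_regulated = 20, noise_sd = 0,
                          nondetectable_fraction = 0, non_cds_fraction = 0,
                          strand_mismatch_fraction = 0)
  prof <- generate_profiles(cfg)
  probes <- compute_ma(generate_probe_signals(prof$true_matrix, cfg))
  found <- probes[probes$status == "found", ]
  truth <- prof$true_matrix[cbind(found$gene_id,
                                  paste0(found$strain, "_", found$time_h, "h"))]
  fwd <- found$dye_orientation == "forward"
  expect_equal(found$M[fwd], truth[fwd], tolerance = 1e-10)
  expect_equal(found$M[!fwd], -truth[!fwd], tolerance = 1e-10)
})

test_that("a fully nondetectable gene is discarded at summarization", {
  cfg <- synthetic_config(n_genes = 30, n_regulated = 10, noise_sd = 0,
                          nondetectable_fraction = 0)
  prof <- generate_profiles(cfg)
  probes <- generate_probe_signals(prof$true_matrix, cfg)
  victim <- rownames(prof$matrix)[1]
  low <- probes$gene_id %in% victim
  probes$intensity_test[low] <- 5
  probes$intensity_ref[low] <- 5
  pp <- preprocess_probes(probes)
  expect_true(all(is.na(pp$ratio_table[victim, ])))
  expect_false(anyNA(pp$ratio_table[rownames(pp$ratio_table) != victim, ]))
})

test_that("counts approach Poisson in the zero-dispersion limit", {
  # with no basal offsets the two strains share each gene's expected count,
  # so the paired statistic (a - b)^2 / (a + b) has mean ~ 1 under Poisson
  # and mean 1 + dispersion * mu under the negative binomial
  overdispersion <- function(disp, seed) {
    cfg <- synthetic_config(n_genes = 10000, n_regulated = 100,
                            nb_dispersion = disp, n_basal_genes = 0,
                            genome_length = 4.5e7, seed = seed)
    gm <- generate_gene_models(cfg$n_genes, cfg$genome_length, seed = seed)
    prof <- generate_profiles(cfg)
    cnt <- generate_counts(cfg, prof$true_cluster, gm)$counts
    a <- cnt$reads[cnt$strain == "NG14"]
    b <- cnt$reads[cnt$strain == "RUTC30"]
    keep <- a + b > 0
    mean((a[keep] - b[keep])^2 / (a[keep] + b[keep]))
  }
  expect_lt(abs(overdispersion(0, 9) - 1), 0.1)
  expect_gt(overdispersion(0.05, 9), 5)
})

test_that("designated basal genes are recovered by the dual filter at high expression", {
  cfg <- synthetic_config(seed = 21)
  gm <- generate_gene_models(cfg$n_genes, cfg$genome_length, seed = 21)
  prof <- generate_profiles(cfg)
  cnt <- generate_counts(cfg, prof$true_cluster, gm)
  basal <- basal_compare(cnt$counts, cnt$totals)
  designated <- names(cnt$true_basal_logratio)[cnt$true_basal_logratio != 0]
  flagged <- basal$gene_id[basal$flagged]
  expect_gt(length(intersect(designated, flagged)) / length(designated), 0.8)
  expect_true(all(flagged %in% designated))
})

test_that("mutation placement truth matches an exhaustive interval recomputation", {
  cfg <- synthetic_config(n_genes = 60, n_regulated = 20, n_mutations = 80,
                          genome_length = 3e5, near_gene_fraction = 0.6)
  gm <- generate_gene_models(cfg$n_genes, cfg$genome_length, seed = 13)
  mut <- generate_mutations(gm, cfg)
  oracle <- brute_force_window_scan(mut$mutations, gm)
  truth <- mut$mutation_target[order(names(mut$mutation_target))]
  recomputed <- setNames(rep(NA_character_, length(truth)), names(truth))
  recomputed[oracle$mutation_id] <- oracle$gene_id
  expect_identical(recomputed, truth)
})

test_that("near_gene_fraction = 0 places every mutation outside all windows", {
  cfg <- synthetic_config(n_genes = 40, n_regulated = 15, n_mutations = 50,
                          genome_length = 2e5, near_gene_fraction = 0)
  gm <- generate_gene_models(cfg$n_genes, cfg$genome_length, seed = 2)
  mut <- generate_mutations(gm, cfg)
  expect_true(all(is.na(mut$mutation_target)))
  expect_equal(nrow(suppressWarnings(window_assign(mut$mutations, gm))), 0)
})

test_that("the full simulated dataset is deterministic under the seed", {
  cfg <- synthetic_config(n_genes = 80, n_regulated = 30, n_mutations = 20,
                          genome_length = 4e5, seed = 77)
  expect_identical(simulate_dataset(cfg), simulate_dataset(cfg))
})
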