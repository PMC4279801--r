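test_that("background threshold is mean + k sample SDs of the not-found population", {
  expect_equal(background_threshold(c(100, 100, 100)), 100)
  expect_equal(background_threshold(c(90, 110)), 100 + 2 * sd(c(90, 110)),
               tolerance = 1e-12)
  expect_equal(background_threshold(c(90, 110)), 128.2843, tolerance = 1e-4)
  expect_equal(background_threshold(c(90, 110), sd_mult = 0), 100)
  expect_error(background_threshold(150), "insufficient")
})

test_that("detectability needs found status and both channels above threshold", {
  p <- make_probe_rows(n = 3)
  p$intensity_test <- c(200, 200, 400)
  p$intensity_ref <- c(300, 120, 500)
  p$status <- c("found", "found", "not_found")
  out <- flag_detectable(p, 150)
  expect_equal(out$detectable, c(TRUE, FALSE, FALSE))
})

test_that("raising the threshold never increases the number of detectable probes", {
  cfg <- synthetic_config(n_genes = 50, n_regulated = 20)
  prof <- generate_profiles(cfg)
  probes <- generate_probe_signals(prof$matrix, cfg)
  counts <- sapply(seq(0, 400, by = 50), function(thr)
    sum(flag_detectable(probes, thr)$detectable))
  expect_true(all(diff(counts) <= 0))
})

test_that("lowess normalization removes an injected intensity-dependent bias", {
  set.seed(42)
  n <- 5000
  A <- runif(n, 8, 14)
  p <- data.frame(
    probe_id = sprintf("p%d", 1:n), gene_id = "g", strain = "NG14",
    time_h = 1, replicate = 1, dye_orientation = "forward",
    intensity_test = 2^(A + 0.5 * sin(A) / 2),
    intensity_ref = 2^(A - 0.5 * sin(A) / 2),
    in_cds = TRUE, strand_match = TRUE, status = "found",
    stringsAsFactors = FALSE
  )
  out <- global_lowess_normalize(p)
  expect_lt(mean(abs(out$M)), 0.05)
  # independent local-regression oracle on the same probes
  oracle <- stats::loess(I(0.5 * sin(A)) ~ A, span = 0.3, degree = 1)
  expect_lt(mean(abs(out$M - (0.5 * sin(A) - predict(oracle)))), 0.05)
  expect_equal(out$A, compute_ma(p)$A)  # A untouched
})

test_that("lowess residuals of a zero signal are zero and the pass is idempotent", {
  set.seed(1)
  p <- make_probe_rows(n = 200, M = 0)
  p$intensity_test <- 2^runif(200, 8, 14)
  p$intensity_ref <- p$intensity_test
  once <- global_lowess_normalize(p)
  expect_true(all(abs(once$M) < 1e-12))
  # already-centred data: a second pass changes M by < 1e-6 on average
  twice <- global_lowess_normalize(once)
  expect_lt(mean(abs(twice$M - once$M)), 1e-6)
  expect_identical(global_lowess_normalize(p), global_lowess_normalize(p))
  expect_error(global_lowess_normalize(make_probe_rows(n = 10)),
               "normalization error")
})

test_that("transcript summarization averages usable probes and discards empty sets", {
  p <- make_probe_rows(n = 3)
  p$M <- c(1.0, 2.0, 9.0)
  p$detectable <- TRUE
  p$in_cds <- c(TRUE, TRUE, FALSE)  # probe outside the CDS is excluded
  out <- summarize_transcripts(p)
  expect_equal(out$log2_ratio, 1.5)
  expect_equal(out$n_probes_used, 2L)

  p$detectable <- FALSE  # all below threshold -> discarded, not an error
  out2 <- summarize_transcripts(p)
  expect_true(is.na(out2$log2_ratio))
  expect_equal(out2$n_probes_used, 0L)
})

test_that("dye-swapped replicates agree with forward ones after orientation correction", {
  cfg <- synthetic_config(n_genes = 300, n_regulated = 30, noise_sd = 0,
                          nondetectable_fraction = 0, non_cds_fraction = 0,
                          strand_mismatch_fraction = 0)
  prof <- generate_profiles(cfg)
  pp <- preprocess_probes(generate_probe_signals(prof$true_matrix, cfg))
  r1 <- pp$ratio_table[, grep("_r1$", colnames(pp$ratio_table))]
  r2 <- pp$ratio_table[, grep("_r2$", colnames(pp$ratio_table))]
  expect_equal(unname(r1), unname(r2), tolerance = 0.02)
})

test_that("the assembled table is rectangular, duplicate-safe and TSV round-trips", {
  ratios <- expand.grid(gene_id = c("ga", "gb"), strain = strain_levels(),
                        time_h = time_levels(), replicate = 1:2,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ratios$log2_ratio <- seq_len(nrow(ratios)) / 10
  ratios$n_probes_used <- 3L
  mat <- assemble_ratio_table(ratios)
  expect_equal(dim(mat), c(2L, 16L))
  expect_equal(sum(is.na(mat)), 0L)

  ratios$log2_ratio[5] <- NA  # one discarded entry -> exactly one missing cell
  mat2 <- assemble_ratio_table(ratios)
  expect_equal(sum(is.na(mat2)), 1L)

  expect_error(assemble_ratio_table(rbind(ratios, ratios[1, ])), "duplicate")

  f <- withr::local_tempfile(fileext = ".tsv")
  write_ratio_table(mat2, f)
  expect_equal(read_ratio_table(f), mat2)
})
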