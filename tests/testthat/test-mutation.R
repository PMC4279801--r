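test_that("the 800-bp window boundary is inclusive at 800 and exclusive at 801", {
  gm <- make_gene_models(5001, 6500)
  muts <- data.frame(mutation_id = c("m1", "m2"), contig = "contig_1",
                     position = c(5001 - 801, 5001 - 800), type = "SNV",
                     lineages = "RUT C30", stringsAsFactors = FALSE)
  out <- window_assign(muts, gm, 800)
  expect_false("m1" %in% out$mutation_id)
  expect_equal(out$mutation_id, "m2")
  expect_equal(out$region, "promoter")
})

test_that("regions are classified strand-aware and partition the window", {
  gm <- make_gene_models(c(2000, 9000), c(4000, 11000), strand = c("+", "-"))
  gm$exons <- data.frame(gene_id = c("g001", "g001", "g002"),
                         start = c(2000, 3000, 9000),
                         end = c(2500, 4000, 11000))
  muts <- data.frame(
    mutation_id = sprintf("m%d", 1:6), contig = "contig_1",
    position = c(1500, 2200, 2700, 4300, 8500, 11500),
    type = "SNV", lineages = "RUT C30", stringsAsFactors = FALSE)
  out <- window_assign(muts, gm, 800)
  got <- setNames(out$region, out$mutation_id)
  expect_equal(got[["m1"]], "promoter")    # upstream of + gene
  expect_equal(got[["m2"]], "exon")
  expect_equal(got[["m3"]], "intron")      # inside span, between exons
  expect_equal(got[["m4"]], "terminator")  # downstream of + gene
  expect_equal(got[["m5"]], "terminator")  # low side of - gene
  expect_equal(got[["m6"]], "promoter")    # high side of - gene
  expect_equal(as.integer(table(out$mutation_id)), rep(1L, 6))  # one region each
})

test_that("assignment ignores strand while the region label flips with it", {
  gm_plus <- make_gene_models(5000, 7000, strand = "+")
  gm_minus <- make_gene_models(5000, 7000, strand = "-")
  muts <- data.frame(mutation_id = sprintf("m%d", 1:3), contig = "contig_1",
                     position = c(4500, 6000, 7500), type = "SNV",
                     lineages = "x", stringsAsFactors = FALSE)
  p <- window_assign(muts, gm_plus, 800)
  m <- window_assign(muts, gm_minus, 800)
  expect_identical(p$mutation_id, m$mutation_id)  # same assignments
  expect_equal(setNames(p$region, p$mutation_id)[c("m1", "m3")],
               c(m1 = "promoter", m3 = "terminator"))
  expect_equal(setNames(m$region, m$mutation_id)[c("m1", "m3")],
               c(m1 = "terminator", m3 = "promoter"))
})

test_that("enlarging the window never removes an assignment", {
  cfg <- synthetic_config(n_genes = 40, n_regulated = 15, n_mutations = 60,
                          genome_length = 2e5)
  gm <- generate_gene_models(cfg$n_genes, cfg$genome_length, seed = 6)
  mut <- generate_mutations(gm, cfg)$mutations
  prev <- 0L
  for (w in c(200, 800, 1600, 3200)) {
    cur <- nrow(window_assign(mut, gm, w))
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("the window scan matches the exhaustive interval oracle at scale", {
  cfg <- synthetic_config(n_genes = 100, n_regulated = 40, n_mutations = 1000,
                          genome_length = 5e5, near_gene_fraction = 0.5)
  gm <- generate_gene_models(cfg$n_genes, cfg$genome_length, seed = 41)
  mut <- generate_mutations(gm, cfg)$mutations
  got <- window_assign(mut, gm, 800)
  got <- got[order(got$mutation_id, got$gene_id),
             c("mutation_id", "gene_id")]
  rownames(got) <- NULL
  oracle <- brute_force_window_scan(mut, gm, 800)
  rownames(oracle) <- NULL
  expect_equal(got, oracle)
})

test_that("unknown contigs are skipped with a warning and counted", {
  gm <- make_gene_models(2000, 3000)
  muts <- data.frame(mutation_id = c("m1", "m2"),
                     contig = c("contig_1", "contig_9"),
                     position = c(2500, 2500), type = "SNV", lineages = "x",
                     stringsAsFactors = FALSE)
  expect_warning(out <- window_assign(muts, gm), "unknown contig")
  expect_equal(attr(out, "skipped_contigs"), 1L)
  expect_equal(out$mutation_id, "m1")
})

test_that("only impacts on regulated genes survive, with cluster labels attached", {
  impacts <- data.frame(mutation_id = c("m1", "m2", "m3"),
                        contig = "contig_1", position = 1:3, type = "SNV",
                        lineages = "RUT C30",
                        gene_id = c("gA", "gB", "gC"), region = "promoter",
                        stringsAsFactors = FALSE)
  assignment <- data.frame(gene_id = c("gA", "gC"),
                           cluster = c("5", "unclustered"))
  rec <- intersect_regulated(impacts, c("gA", "gC"), assignment)
  expect_setequal(rec$gene_id, c("gA", "gC"))  # gB unregulated -> dropped
  expect_equal(rec$cluster[rec$gene_id == "gA"], "5")
  expect_equal(rec$cluster[rec$gene_id == "gC"], "Not clustered")
})

test_that("noise-free synthetic impacts equal the truth-regulated intersection", {
  cfg <- synthetic_config(n_genes = 250, n_regulated = 120, noise_sd = 0,
                          n_mutations = 120, genome_length = 1.2e6, seed = 15)
  gm <- generate_gene_models(cfg$n_genes, cfg$genome_length, seed = 15)
  prof <- generate_profiles(cfg)
  mut <- generate_mutations(gm, cfg)
  impacts <- window_assign(mut$mutations, gm)
  regulated <- names(prof$true_cluster)[!is.na(prof$true_cluster)]
  rec <- intersect_regulated(impacts, regulated)
  expected <- sum(mut$mutation_target %in% regulated)
  expect_equal(nrow(rec), expected)
})

test_that("an empty record set tabulates to an all-zero table", {
  empty <- data.frame(cluster = character(0), lineages = character(0))
  tab <- tabulate_by_cluster_and_lineage(empty)
  expect_true(all(tab == 0))
})
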