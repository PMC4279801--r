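# Shared builders and independent oracles for the test suite.

# tiny probe table: one gene, one condition, explicit intensities
make_probe_rows <- function(gene_id = "g1", strain = "NG14", time_h = 1,
                            replicate = 1, orientation = "forward",
                            M = 0, A = 12, n = 1, in_cds = TRUE,
                            strand_match = TRUE, status = "found") {
  data.frame(
    probe_id = sprintf("%s_p%d", gene_id, seq_len(n)),
    gene_id = gene_id, strain = strain, time_h = time_h,
    replicate = replicate, dye_orientation = orientation,
    intensity_test = 2^(A + M / 2), intensity_ref = 2^(A - M / 2),
    in_cds = in_cds, strand_match = strand_match, status = status,
    stringsAsFactors = FALSE
  )
}

# minimal gene_models object from explicit coordinates
make_gene_models <- function(starts, ends, strand = "+",
                             contig = "contig_1") {
  n <- length(starts)
  strand <- rep_len(strand, n)
  genes <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n)), contig = contig,
    start = starts, end = ends, strand = strand,
    start_codon = ifelse(strand == "+", starts, ends),
    stop_codon = ifelse(strand == "+", ends, starts),
    stringsAsFactors = FALSE
  )
  exons <- data.frame(gene_id = genes$gene_id, start = starts, end = ends,
                      stringsAsFactors = FALSE)
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

# independent oracle: exhaustive mutation-by-gene interval scan
brute_force_window_scan <- function(mutations, gene_models, window = 800) {
  g <- gene_models$genes
  hits <- list()
  for (i in seq_len(nrow(mutations))) {
    for (j in seq_len(nrow(g))) {
      if (mutations$contig[i] == g$contig[j] &&
          mutations$position[i] >= g$start[j] - window &&
          mutations$position[i] <= g$end[j] + window) {
        hits[[length(hits) + 1]] <- data.frame(
          mutation_id = mutations$mutation_id[i], gene_id = g$gene_id[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(mutation_id = character(0), gene_id = character(0)))
  out <- do.call(rbind, hits)
  out[order(out$mutation_id, out$gene_id), , drop = FALSE]
}

# ratio-table matrix with the canonical 16 column names
make_ratio_table <- function(values, genes = sprintf("g%05d", seq_len(nrow(values)))) {
  cols <- as.vector(t(outer(condition_levels(), c("r1", "r2"), paste,
                            sep = "_")))
  stopifnot(ncol(values) == length(cols))
  dimnames(values) <- list(genes, cols)
  values
}

extdata <- function(f) system.file("extdata", f, package = "kinduce")
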