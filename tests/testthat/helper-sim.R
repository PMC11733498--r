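# Small simulation configurations shared across module tests. The full-scale
# study conditions live in test-acceptance.R; these are deliberately tiny.
small_cfg <- function(seed = 1L, haploblocks = list(
                        hb_spec(
                          chrom = "chr1", start = 1e6, end = 2e6,
                          n_markers = 150L
                        )
                      )) {
  sim_config(
    n_pops = 6, n_per_pop = 10, latitudes = seq(10, 54, length.out = 6),
    n_chroms = 1, chrom_length = 4e6, n_neutral_snps = 2000,
    haploblocks = haploblocks,
    genes = list(
      n_genes = 6, cds_len = 300, n_coding_snps = 200,
      zerofold_downweight = 0.35
    ),
    seed = seed
  )
}

# Build a geno_matrix directly from a dosage matrix on one chromosome.
toy_gm <- function(dosages, chrom = "chr1", pos = NULL, ancestral = "ref") {
  m <- ncol(dosages)
  if (is.null(pos)) pos <- seq_len(m) * 10L
  geno_matrix(
    dosages,
    data.frame(
      chrom = chrom, pos = pos,
      ref = "A", alt = "C", ancestral = ancestral,
      stringsAsFactors = FALSE
    ),
    sample_ids = sprintf("s%03d", seq_len(nrow(dosages)))
  )
}

# Interval Jaccard on one chromosome.
interval_jaccard <- function(a_start, a_end, b_start, b_end) {
  inter <- max(0, min(a_end, b_end) - max(a_start, b_start))
  inter / (max(a_end, b_end) - min(a_start, b_start))
}

# Concordance of called arrangement genotypes with truth dosages, maximised
# over the (arbitrary) arrangement orientation.
genotype_concordance <- function(genotype, truth) {
  keep <- genotype != "unassigned"
  g <- genotype[keep]
  tr <- truth[names(g)]
  direct <- mean(c(AA = 0, AB = 1, BB = 2)[g] == tr)
  flipped <- mean(c(AA = 2, AB = 1, BB = 0)[g] == tr)
  max(direct, flipped)
}
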