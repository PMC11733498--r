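test_that("degeneracy classification matches an independent translation oracle", {
  expect_equal(classify_site("GGG", 3), "fourfold") # glycine GGN family
  expect_equal(classify_site("ATG", 1), "zerofold") # Met start
  expect_equal(classify_site("ATN", 2), "ambiguous")

  oracle <- function(codon, pos) {
    bases <- c("A", "C", "G", "T")
    tr <- function(cd) seqinr::translate(strsplit(cd, "")[[1]])
    aa0 <- tr(codon)
    ref <- substr(codon, pos, pos)
    ch <- vapply(setdiff(bases, ref), function(b) {
      alt <- codon
      substr(alt, pos, pos) <- b
      !identical(tr(alt), aa0)
    }, logical(1))
    if (all(ch)) "zerofold" else if (!any(ch)) "fourfold" else "other"
  }
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  for (cd in codons) {
    for (pos in 1:3) {
      expect_equal(classify_site(cd, pos), oracle(cd, pos),
        info = paste(cd, pos)
      )
    }
  }
  # in the standard code no second codon position is fourfold
  expect_false(any(vapply(codons, classify_site, "", codon_pos = 2) == "fourfold"))
})

test_that("strand mirror-image genes classify identically", {
  # plus-strand gene ATG GGA CCT TAA on a 20-bp contig, and its reverse
  # complement annotated on the minus strand of a second contig
  cds <- "ATGGGACCTTAA"
  left <- "ACGT"
  right <- "TGCA"
  plus_seq <- paste0(left, cds, right)
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  minus_seq <- rc(plus_seq)
  gff <- data.frame(
    seqid = c("cP", "cP", "cP", "cM", "cM", "cM"),
    source = "test",
    type = rep(c("gene", "mRNA", "CDS"), 2),
    start = c(5, 5, 5, 5, 5, 5),
    end = c(16, 16, 16, 16, 16, 16),
    score = ".",
    strand = rep(c("+", "-"), each = 3),
    phase = c(".", ".", "0", ".", ".", "0"),
    attributes = c(
      "ID=gp", "ID=gp.t;Parent=gp", "ID=gp.cds;Parent=gp.t",
      "ID=gm", "ID=gm.t;Parent=gm", "ID=gm.cds;Parent=gm.t"
    ),
    stringsAsFactors = FALSE
  )
  gff_path <- tempfile(fileext = ".gff3")
  write_gff3(gff, gff_path)
  map <- build_degeneracy_map(c(cP = plus_seq, cM = minus_seq), gff_path)
  plus <- map[map$chrom == "cP", ]
  minus <- map[map$chrom == "cM", ]
  # mirrored positions: position p on cP corresponds to 21 - p on cM
  m <- match(21 - plus$pos, minus$pos)
  expect_false(anyNA(m))
  expect_equal(minus$class[m], plus$class)
  # sanity: third positions of GGA (fourfold) and first of ATG (zerofold)
  expect_equal(plus$class[plus$pos == 10], "fourfold")
  expect_equal(plus$class[plus$pos == 5], "zerofold")
})

test_that("malformed and phased transcripts are handled", {
  seqs <- c(cX = paste0("AAAA", "ATGGGACCTTAA", "GAAAAATGGGACCTTAAAA"))
  gff <- data.frame(
    seqid = "cX", source = "test",
    type = c("mRNA", "CDS", "mRNA", "CDS"),
    start = c(5, 5, 5, 5),
    end = c(15, 15, 16, 16), # first CDS is 11 bp: not a codon multiple
    score = ".", strand = "+",
    phase = c(".", "0", ".", "0"),
    attributes = c(
      "ID=bad.t", "Parent=bad.t",
      "ID=ok.t", "Parent=ok.t"
    ),
    stringsAsFactors = FALSE
  )
  p <- tempfile(fileext = ".gff3")
  write_gff3(gff, p)
  expect_warning(map <- build_degeneracy_map(seqs, p), "multiple of 3")
  expect_setequal(unique(map$transcript), "ok.t")

  # a phase-1 CDS skips its first base before forming codons
  gff2 <- data.frame(
    seqid = "cX", source = "test", type = c("mRNA", "CDS"),
    start = c(4, 4), end = c(16, 16), score = ".", strand = "+",
    phase = c(".", "1"), # 13 bases, skip 1 -> the same 4 codons
    attributes = c("ID=ph.t", "Parent=ph.t"), stringsAsFactors = FALSE
  )
  p2 <- tempfile(fileext = ".gff3")
  write_gff3(gff2, p2)
  map2 <- build_degeneracy_map(seqs, p2)
  expect_equal(min(map2$pos), 5) # phase base excluded
  expect_equal(map2$class[map2$pos == 10], "fourfold")
})

test_that("derived frequency load averages polarized sites per group", {
  # all homozygous ancestral -> 0; all homozygous derived -> 1
  n <- 8L
  m <- 12L
  deg <- data.frame(
    chrom = "chr1", pos = (1:m) * 10L,
    class = rep(c("zerofold", "fourfold"), m / 2),
    transcript = "t", stringsAsFactors = FALSE
  )
  groups <- list(g1 = sprintf("s%03d", 1:4), g2 = sprintf("s%03d", 5:8))
  gm0 <- toy_gm(matrix(0L, n, m))
  est0 <- derived_frequency_load(gm0, deg, groups, n_down = 4)
  expect_true(all(est0$mean_derived_freq == 0))
  gm2 <- toy_gm(matrix(2L, n, m))
  est2 <- derived_frequency_load(gm2, deg, groups, n_down = 4)
  expect_true(all(est2$mean_derived_freq == 1))
  # ALT-ancestral sites flip polarity: dosage 2 means derived frequency 0
  gm_flip <- toy_gm(matrix(2L, n, m), ancestral = "alt")
  est_f <- derived_frequency_load(gm_flip, deg, groups, n_down = 4)
  expect_true(all(est_f$mean_derived_freq == 0))
  # unknown polarity sites are excluded
  gm_u <- toy_gm(matrix(2L, n, m), ancestral = rep(c("ref", "unknown"), m / 2))
  est_u <- derived_frequency_load(gm_u, deg, groups, n_down = 4)
  expect_equal(sum(est_u$n_sites), 2 * m / 2)
  # too-small groups error
  expect_error(
    derived_frequency_load(gm0, deg, groups, n_down = 5),
    "smaller than n_down"
  )
})

test_that("site-subsampling bootstrap behaves and reproduces under a seed", {
  # identical frequencies: zero-width CI at that value
  b0 <- bootstrap_load(rep(0.3, 50), seed = 1)
  expect_equal(b0$lower, 0.3)
  expect_equal(b0$upper, 0.3)
  # determinism
  set.seed(99)
  x <- runif(200)
  b1 <- bootstrap_load(x, seed = 5)
  b2 <- bootstrap_load(x, seed = 5)
  expect_identical(b1$means, b2$means)
  expect_lte(b1$lower, b1$mean)
  expect_gte(b1$upper, b1$mean)
  # CI width shrinks with the number of sites (averaged over draws)
  set.seed(100)
  widths <- vapply(c(100, 2500), function(S) {
    mean(vapply(1:8, function(r) {
      b <- bootstrap_load(runif(S), seed = r)
      b$upper - b$lower
    }, numeric(1)))
  }, numeric(1))
  expect_lt(widths[2], widths[1])
  # classical full-resample variant is available
  bc <- bootstrap_load(x, seed = 5, classical = TRUE)
  expect_false(identical(bc$means, b1$means))
})

test_that("purifying selection shows as lower zero-fold derived frequency", {
  cfg <- small_cfg(seed = 70)
  cg <- simulate_coding_genome(cfg)
  gmc <- simulate_coding_snps(cfg, cg)
  samples <- data.frame(
    sample = gmc$sample_ids,
    population = rep(sprintf("p%d", 1:6), each = 10),
    range = rep(c("native", "invaded"), c(30, 30)),
    stringsAsFactors = FALSE
  )
  groups <- split(samples$sample, samples$range)
  est <- load_estimates(gmc, cg$degeneracy, groups, seed = 3)
  for (g in names(groups)) {
    zf <- est[est$group == g & est$class == "zerofold", ]
    ff <- est[est$group == g & est$class == "fourfold", ]
    expect_lt(zf$mean_derived_freq, ff$mean_derived_freq)
  }
})
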