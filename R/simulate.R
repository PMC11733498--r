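#' Simulation configuration
#'
#' Collects the parameters of the synthetic study design: multi-population
#' samples along a latitudinal gradient with a drift-structured neutral SNP
#' background, optional planted haploblocks with suppressed recombination
#' (marker SNPs tied to a latent arrangement genotype), traits with
#' haploblock plus polygenic effects, and a toy coding contig with known
#' site degeneracy for load estimation.
#'
#' Defaults describe the study conditions every downstream stage is tested
#' under: 10 populations of 20 diploids spaced evenly between latitude 10 and
#' 54 degrees, 2 chromosomes of 20 Mbp carrying 20,000 unlinked neutral SNPs
#' with drift intensity `F = 0.1`, one 2-Mbp haploblock whose arrangement
#' frequency climbs a logit-linear cline (0.1 at the lowest latitude, slope
#' 0.1 per degree, i.e. ~0.9 at the highest), and 20 coding genes of 900-bp
#' CDS on a separate small contig.
#'
#' @param n_pops number of populations.
#' @param n_per_pop diploid individuals per population.
#' @param latitudes per-population latitudes (degrees).
#' @param n_chroms number of background chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_neutral_snps total neutral SNPs across background chromosomes.
#' @param drift_F per-population differentiation intensity; population allele
#'   frequencies are drawn `Beta(pi (1-F)/F, (1-pi)(1-F)/F)` around an
#'   ancestral frequency `pi ~ Uniform(0.05, 0.95)`.
#' @param haploblocks list of [hb_spec()] entries (may be empty).
#' @param traits list of [trait_spec()] entries (may be empty).
#' @param genes list with elements `n_genes`, `cds_len` (bp, multiple of 3),
#'   `n_coding_snps`, and `zerofold_downweight`, the multiplicative
#'   purifying-selection factor applied to derived allele frequencies at
#'   zero-fold sites.
#' @param miss_rate fraction of dosages set missing at random (default 0).
#' @param seed integer seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 10L, n_per_pop = 20L,
                       latitudes = seq(10, 54, length.out = n_pops),
                       n_chroms = 2L, chrom_length = 20e6,
                       n_neutral_snps = 20000L, drift_F = 0.1,
                       haploblocks = list(hb_spec()),
                       traits = list(trait_spec()),
                       genes = list(
                         n_genes = 20L, cds_len = 900L,
                         n_coding_snps = 1200L, zerofold_downweight = 0.35
                       ),
                       miss_rate = 0, seed = 1L) {
  stopifnot(
    length(latitudes) == n_pops, all(is.finite(latitudes)),
    drift_F > 0, drift_F < 1, n_neutral_snps > 0
  )
  for (hb in haploblocks) {
    stopifnot(hb$start >= 0, hb$end <= chrom_length, hb$end > hb$start)
  }
  if (length(haploblocks) > 1) {
    iv <- do.call(rbind, lapply(haploblocks, function(h) {
      data.frame(chrom = h$chrom, start = h$start, end = h$end)
    }))
    for (ch in unique(iv$chrom)) {
      x <- iv[iv$chrom == ch, ]
      x <- x[order(x$start), ]
      if (nrow(x) > 1 && any(x$start[-1] < x$end[-nrow(x)])) {
        stop("haploblock intervals overlap on ", ch)
      }
    }
  }
  structure(
    list(
      n_pops = n_pops, n_per_pop = n_per_pop, latitudes = latitudes,
      n_chroms = n_chroms, chrom_length = chrom_length,
      n_neutral_snps = n_neutral_snps, drift_F = drift_F,
      haploblocks = haploblocks, traits = traits, genes = genes,
      miss_rate = miss_rate, seed = seed
    ),
    class = "sim_config"
  )
}

#' Haploblock specification for simulation
#'
#' The arrangement frequency in population `j` follows a logit-linear cline,
#' `logit(q_j) = b0 + b1 |latitude_j|`, unless explicit per-population
#' frequencies are given. `slope` and `freq_at_min` parameterise the cline:
#' `freq_at_min` is the arrangement frequency at the lowest absolute
#' latitude.
#'
#' @param chrom chromosome carrying the haploblock.
#' @param start,end 0-based half-open interval (bp).
#' @param n_markers number of fixed-difference marker SNPs inside the block.
#' @param eps within-arrangement diversity: a marker dosage equals the
#'   arrangement dosage with probability `1 - eps`, else it is resampled
#'   (Binomial(2, 0.5)). Heterokaryotypes are therefore heterozygous at
#'   ~`1 - eps` of markers.
#' @param slope cline slope on the logit scale per degree of absolute
#'   latitude.
#' @param freq_at_min arrangement frequency at the minimum absolute latitude.
#' @param pop_freqs optional explicit per-population arrangement frequencies
#'   (overrides the cline).
#' @return a list of class `hb_spec`.
#' @export
hb_spec <- function(chrom = "chr1", start = 8e6, end = 10e6,
                    n_markers = 3000L, eps = 0.02,
                    slope = 0.1, freq_at_min = 0.1, pop_freqs = NULL) {
  stopifnot(eps >= 0, eps <= 1, n_markers > 0)
  if (!is.null(pop_freqs)) stopifnot(all(pop_freqs >= 0 & pop_freqs <= 1))
  structure(
    list(
      chrom = chrom, start = start, end = end, n_markers = n_markers,
      eps = eps, slope = slope, freq_at_min = freq_at_min,
      pop_freqs = pop_freqs
    ),
    class = "hb_spec"
  )
}

#' Trait specification for simulation
#'
#' Phenotypes are `y = a g_hb + sum_k b_k g_k + e` with `e ~ N(0, resid_sd^2)`:
#' an additive haploblock effect plus a polygenic background of background
#' SNPs with Normal effects.
#'
#' @param name trait name.
#' @param hb index of the haploblock (into the config's `haploblocks` list)
#'   whose arrangement dosage carries the additive effect, or NA for none.
#' @param effect additive effect `a` per arrangement copy.
#' @param n_polygenic number of background SNPs with polygenic effects.
#' @param poly_sd standard deviation of polygenic effect sizes `b_k`.
#' @param resid_sd residual standard deviation.
#' @return a list of class `trait_spec`.
#' @export
trait_spec <- function(name = "trait1", hb = 1L, effect = 1,
                       n_polygenic = 100L, poly_sd = 0.05, resid_sd = 1) {
  structure(
    list(
      name = name, hb = hb, effect = effect, n_polygenic = n_polygenic,
      poly_sd = poly_sd, resid_sd = resid_sd
    ),
    class = "trait_spec"
  )
}

# Sample metadata frame implied by a config.
.sim_samples <- function(cfg) {
  pop <- sprintf("pop%02d", seq_len(cfg$n_pops))
  data.frame(
    sample = sprintf(
      "%s_i%02d", rep(pop, each = cfg$n_per_pop),
      rep(seq_len(cfg$n_per_pop), cfg$n_pops)
    ),
    population = rep(pop, each = cfg$n_per_pop),
    range = rep(ifelse(seq_len(cfg$n_pops) <= ceiling(cfg$n_pops / 2),
      "native", "invaded"
    ), each = cfg$n_per_pop),
    latitude = rep(cfg$latitudes, each = cfg$n_per_pop),
    longitude = rep(seq(-100, -70, length.out = cfg$n_pops), each = cfg$n_per_pop),
    stringsAsFactors = FALSE
  )
}

#' Simulate the neutral SNP background
#'
#' Unlinked biallelic SNPs with drift-induced population covariance: per SNP
#' an ancestral frequency `pi ~ Uniform(0.05, 0.95)`, per-population
#' frequencies from the Beta drift model with intensity `F`, and
#' Hardy-Weinberg dosages `Binomial(2, p_j)` within populations.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return a [geno_matrix()]; the attribute `"pop_freqs"` carries the
#'   simulated per-population frequencies (sites x populations).
#' @export
simulate_neutral_background <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  S <- cfg$n_neutral_snps
  J <- cfg$n_pops
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  chrom <- sort(sample(chroms, S, replace = TRUE))
  pos <- unlist(lapply(
    table(chrom)[unique(chrom)],
    function(k) sort(sample.int(cfg$chrom_length, k))
  ), use.names = FALSE)

  pi0 <- stats::runif(S, 0.05, 0.95)
  F <- cfg$drift_F
  a <- pi0 * (1 - F) / F
  b <- (1 - pi0) * (1 - F) / F
  p <- matrix(stats::rbeta(S * J, rep(a, J), rep(b, J)), nrow = S) # SNP x pop

  n <- cfg$n_per_pop
  dos <- matrix(NA_integer_, nrow = J * n, ncol = S)
  for (j in seq_len(J)) {
    rows <- (j - 1L) * n + seq_len(n)
    dos[rows, ] <- matrix(
      stats::rbinom(n * S, 2L, rep(p[, j], each = n)),
      nrow = n
    )
  }
  if (cfg$miss_rate > 0) {
    drop <- which(stats::runif(length(dos)) < cfg$miss_rate)
    dos[drop] <- NA_integer_
  }
  ref_alt <- .random_ref_alt(S)
  gm <- geno_matrix(
    dos,
    data.frame(
      chrom = chrom, pos = pos, ref = ref_alt$ref, alt = ref_alt$alt,
      ancestral = "ref", stringsAsFactors = FALSE
    ),
    sample_ids = .sim_samples(cfg)$sample
  )
  attr(gm, "pop_freqs") <- p
  gm
}

.random_ref_alt <- function(S) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, S, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  list(ref = ref, alt = unname(alt))
}

#' Simulate a haploblock
#'
#' Each sample draws an arrangement genotype `Binomial(2, q_j)` from its
#' population's cline frequency; marker SNPs are fixed differences between
#' arrangements perturbed by within-arrangement diversity `eps` (with
#' probability `eps` a marker dosage is resampled as `Binomial(2, 0.5)`).
#'
#' @param cfg a [sim_config()].
#' @param hb an [hb_spec()].
#' @param seed integer seed.
#' @return list with `markers` (samples x markers dosage matrix), `sites`
#'   (marker site table), `arrangement` (named per-sample arrangement
#'   dosages), `pop_freqs` (per-population cline frequencies `q_j`), and
#'   `cline` (`b0`, `b1` on the logit-vs-|latitude| scale).
#' @export
simulate_haploblock <- function(cfg, hb, seed = cfg$seed + 1L) {
  set.seed(seed)
  samples <- .sim_samples(cfg)
  if (is.null(hb$pop_freqs)) {
    alat <- abs(cfg$latitudes)
    b1 <- hb$slope
    b0 <- stats::qlogis(hb$freq_at_min) - b1 * min(alat)
    q <- stats::plogis(b0 + b1 * alat)
  } else {
    q <- hb$pop_freqs
    b0 <- NA_real_
    b1 <- NA_real_
  }
  g <- stats::rbinom(nrow(samples), 2L, q[match(samples$population, unique(samples$population))])
  names(g) <- samples$sample

  m <- hb$n_markers
  pos <- sort(sample((hb$start + 1):hb$end, m))
  dos <- matrix(rep(g, m), ncol = m)
  flip <- stats::runif(length(dos)) < hb$eps
  dos[flip] <- stats::rbinom(sum(flip), 2L, 0.5)
  ref_alt <- .random_ref_alt(m)
  list(
    markers = dos,
    sites = data.frame(
      chrom = hb$chrom, pos = pos, ref = ref_alt$ref, alt = ref_alt$alt,
      ancestral = "ref", stringsAsFactors = FALSE
    ),
    arrangement = g, pop_freqs = q, cline = c(b0 = b0, b1 = b1)
  )
}

#' Simulate phenotypes with haploblock and polygenic effects
#'
#' @param cfg a [sim_config()].
#' @param arrangements matrix (samples x haploblocks) of arrangement dosages,
#'   or NULL when no haploblock effects are wanted.
#' @param background a [geno_matrix()] of background SNPs for polygenic
#'   effects.
#' @param seed integer seed.
#' @return list with `phenotypes` (data.frame, one column per trait) and
#'   `truth` (per-trait effect sizes and the indices/effects of polygenic
#'   SNPs).
#' @export
simulate_traits <- function(cfg, arrangements, background, seed = cfg$seed + 2L) {
  set.seed(seed)
  n <- cfg$n_pops * cfg$n_per_pop
  ph <- list()
  truth <- list()
  for (tr in cfg$traits) {
    y <- numeric(n)
    if (!is.null(arrangements) && !is.na(tr$hb) && tr$hb <= ncol(arrangements)) {
      y <- y + tr$effect * arrangements[, tr$hb]
    }
    idx <- integer(0)
    beta <- numeric(0)
    if (tr$n_polygenic > 0 && n_sites(background) > 0) {
      idx <- sample.int(n_sites(background), min(tr$n_polygenic, n_sites(background)))
      beta <- stats::rnorm(length(idx), 0, tr$poly_sd)
      d <- background$dosages[, idx, drop = FALSE]
      d[is.na(d)] <- 0
      y <- y + drop(d %*% beta)
    }
    y <- y + stats::rnorm(n, 0, tr$resid_sd)
    ph[[tr$name]] <- y
    truth[[tr$name]] <- list(
      hb = tr$hb, effect = tr$effect,
      polygenic_idx = idx, polygenic_beta = beta, resid_sd = tr$resid_sd
    )
  }
  list(
    phenotypes = as.data.frame(ph, row.names = .sim_samples(cfg)$sample),
    truth = truth
  )
}
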