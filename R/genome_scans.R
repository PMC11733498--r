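#' Per-population allele frequency table
#'
#' ALT allele frequencies and non-missing sample counts per SNP and
#' population; populations with fewer samples than `min_n` are excluded.
#'
#' @param gm a [geno_matrix()].
#' @param samples sample metadata data.frame (`sample`, `population`,
#'   `range`).
#' @param min_n minimum population size (default 3, i.e. populations with
#'   n > 2 are kept).
#' @return list with `p` (SNPs x populations frequency matrix), `n` (same
#'   shape, non-missing diploid counts), and `pops` (population metadata:
#'   `population`, `range`, `n_samples`, and mean `latitude`/`longitude`).
#' @export
pop_freq_table <- function(gm, samples, min_n = 3L) {
  samples <- samples[match(gm$sample_ids, samples$sample), ]
  tab <- table(samples$population)
  keep_pops <- names(tab)[tab >= min_n]
  if (!length(keep_pops)) stop("no populations with n >= ", min_n)
  p <- sapply(keep_pops, function(pp) {
    rows <- which(samples$population == pp)
    colMeans(gm$dosages[rows, , drop = FALSE], na.rm = TRUE) / 2
  })
  n <- sapply(keep_pops, function(pp) {
    rows <- which(samples$population == pp)
    colSums(!is.na(gm$dosages[rows, , drop = FALSE]))
  })
  pops <- do.call(rbind, lapply(keep_pops, function(pp) {
    s <- samples[samples$population == pp, ]
    data.frame(
      population = pp, range = s$range[1], n_samples = nrow(s),
      latitude = mean(s$latitude), longitude = mean(s$longitude),
      stringsAsFactors = FALSE
    )
  }))
  list(p = p, n = n, pops = pops)
}

# Standardize per-SNP population frequencies at the across-population mean.
# Rows with across-population mean 0 or 1 (monomorphic) come back as NA.
.standardize_freqs <- function(p) {
  p <- rbind(p)
  pbar <- rowMeans(p)
  s <- sqrt(pbar * (1 - pbar))
  pt <- (p - pbar) / s
  pt[pbar <= 0 | pbar >= 1, ] <- NA_real_
  pt
}

#' Estimate the Omega population covariance matrix
#'
#' Covariance across putatively neutral SNPs of the standardized population
#' frequency vectors `(p_j - pbar) / sqrt(pbar (1 - pbar))`, shrunk toward
#' its diagonal (weight `shrink`) so the matrix is invertible despite the
#' rank deficiency induced by per-SNP centering. Omega summarises the
#' drift/demographic covariance that the XtX and contrast surrogates whiten
#' out.
#'
#' @param p SNPs x populations frequency matrix (background SNPs only, e.g.
#'   selected via [sample_background_snps()]).
#' @param shrink diagonal shrinkage weight (default 0.05).
#' @param min_snps minimum background SNPs (default 100).
#' @return object of class `omega_matrix`: `omega` (J x J), `n_snps`,
#'   `shrink`.
#' @export
estimate_omega <- function(p, shrink = 0.05, min_snps = 100L) {
  stopifnot(nrow(p) >= min_snps)
  pt <- .standardize_freqs(p)
  pt <- pt[stats::complete.cases(pt), , drop = FALSE]
  om <- stats::cov(pt)
  om <- (1 - shrink) * om + shrink * diag(diag(om))
  if (!all(is.finite(om)) || rcond(om) < 1e-12) {
    stop("Omega is singular after shrinkage (degenerate frequency table)")
  }
  dimnames(om) <- list(colnames(p), colnames(p))
  structure(
    list(omega = om, n_snps = nrow(pt), shrink = shrink),
    class = "omega_matrix"
  )
}

# Whitened quadratic form ptilde' Omega^-1 ptilde, one value per row.
.whitened_quadform <- function(pt, omega) {
  pt <- rbind(pt)
  unname(rowSums((pt %*% solve(omega)) * pt))
}

#' XtX differentiation surrogate
#'
#' Moment-based, whitened measure of allele-frequency differentiation among
#' populations: the quadratic form of the standardized frequency vector in
#' the inverse Omega matrix, scaled by `J/(J-1)` to correct the degree of
#' freedom absorbed by centering at the across-population mean, so that the
#' statistic calibrates at `E[XtX*] ~ J` under neutrality. This is a
#' closed-form surrogate for the BayPass core-model XtX posterior, not an
#' MCMC estimate.
#'
#' @param p SNPs x populations frequency matrix (or a single vector).
#' @param omega an `omega_matrix` from [estimate_omega()] (or a plain J x J
#'   matrix).
#' @return numeric vector of XtX* values; NA for monomorphic SNPs.
#' @export
xtx_surrogate <- function(p, omega) {
  om <- if (inherits(omega, "omega_matrix")) omega$omega else omega
  pt <- .standardize_freqs(p)
  J <- ncol(pt)
  out <- rep(NA_real_, nrow(pt))
  ok <- stats::complete.cases(pt)
  out[ok] <- J / (J - 1) * .whitened_quadform(pt[ok, , drop = FALSE], om)
  out
}

#' Group-contrast surrogate statistic
#'
#' Standardized squared difference in mean standardized frequency between
#' two predefined population groups (e.g. native vs invaded):
#' `C* = (c' ptilde)^2 / (c' Omega c)` with contrast weights `1/J1` and
#' `-1/J2`. Under neutrality `C*` is approximately chi-squared with 1
#' degree of freedom. A closed-form surrogate for the BayPass contrast
#' statistic.
#'
#' @param p SNPs x populations frequency matrix (or a single vector).
#' @param omega an `omega_matrix` or plain J x J matrix.
#' @param groups vector of group labels over populations (exactly 2 distinct
#'   non-NA values).
#' @return numeric vector of C* values; NA for monomorphic SNPs.
#' @export
contrast_surrogate <- function(p, omega, groups) {
  om <- if (inherits(omega, "omega_matrix")) omega$omega else omega
  g <- factor(groups)
  if (nlevels(g) != 2 || any(table(g) == 0)) {
    stop("groups must define exactly two non-empty population groups")
  }
  cc <- ifelse(g == levels(g)[1], 1 / sum(g == levels(g)[1]),
    -1 / sum(g == levels(g)[2])
  )
  pt <- .standardize_freqs(p)
  num <- drop(pt %*% cc)^2
  num / drop(crossprod(cc, om %*% cc))
}

#' Kendall rank correlation between allele frequencies and an environment
#'
#' Tie-corrected tau-b between per-population allele frequencies and an
#' environmental variable (one value per population), with an empirical
#' p-value from the genome-wide rank of `|tau|`.
#'
#' @param p SNPs x populations frequency matrix.
#' @param env numeric environmental value per population.
#' @return data.frame with columns `tau` and `emp_p`.
#' @export
kendall_tau_eaa <- function(p, env) {
  p <- rbind(p)
  stopifnot(ncol(p) == length(env), ncol(p) >= 4)
  if (length(unique(env)) < 2) stop("environmental variable is constant")
  tau <- apply(p, 1, function(row) {
    if (length(unique(row)) < 2) {
      return(NA_real_)
    }
    suppressWarnings(stats::cor(row, env, method = "kendall"))
  })
  data.frame(tau = tau, emp_p = empirical_p(abs(tau)))
}

#' Empirical p-values from genome-wide ranks
#'
#' `p_i = rank(statistic, descending) / (N + 1)` over non-missing values, so
#' the most extreme statistic gets `1/(N+1)` and p-values never reach 0 or
#' 1. Ties share their average rank.
#'
#' @param stat numeric vector; larger values are treated as more extreme.
#' @return numeric vector of empirical p-values in (0, 1); NA propagates.
#' @export
empirical_p <- function(stat) {
  ok <- !is.na(stat)
  n <- sum(ok)
  out <- rep(NA_real_, length(stat))
  out[ok] <- (n + 1 - rank(stat[ok], ties.method = "average")) / (n + 1)
  out
}

#' Fay and Wu's H from an unfolded site frequency spectrum
#'
#' `H = theta_pi - theta_H` with
#' `theta_pi = sum_i S_i 2 i (n - i) / (n (n - 1))` and
#' `theta_H = sum_i S_i 2 i^2 / (n (n - 1))` over derived-allele counts
#' `i in [1, n-1]`. Strongly negative H signals an excess of high-frequency
#' derived alleles, the footprint of a recent selective sweep.
#'
#' @param derived_counts integer vector of per-site derived allele counts
#'   (one entry per polarized segregating site).
#' @param n number of sampled chromosomes.
#' @return list with `H`, `theta_pi`, `theta_H`, `n_sites`; `H` is NA when
#'   no polarized segregating sites are supplied.
#' @export
fay_wu_h <- function(derived_counts, n) {
  stopifnot(n >= 2)
  i <- derived_counts[!is.na(derived_counts)]
  if (any(i < 1 | i > n - 1)) stop("derived counts must lie in [1, n-1]")
  if (!length(i)) {
    return(list(H = NA_real_, theta_pi = 0, theta_H = 0, n_sites = 0L))
  }
  denom <- n * (n - 1)
  theta_pi <- sum(2 * i * (n - i) / denom)
  theta_h <- sum(2 * i^2 / denom)
  list(
    H = theta_pi - theta_h, theta_pi = theta_pi, theta_H = theta_h,
    n_sites = length(i)
  )
}

#' Windowed Fay and Wu's H over a genotype matrix
#'
#' Computes per-site derived counts from polarized sites (ancestral state
#' known) and evaluates H in each window. Sites with unknown ancestral
#' state are excluded and counted.
#'
#' @param gm a [geno_matrix()]; only sites without missing genotypes enter
#'   (H assumes a fixed number of sampled chromosomes).
#' @param windows window tiling from [tile_windows()].
#' @return data.frame per window: `window_id`, `chrom`, `start`, `end`, `H`,
#'   `n_sites`; the attribute `"n_unpolarized"` counts excluded sites.
#' @export
fay_wu_h_windows <- function(gm, windows) {
  n_chrom <- 2L * length(gm$sample_ids)
  derived <- colSums(gm$dosages)
  anc <- gm$sites$ancestral
  flip <- anc == "alt"
  derived[flip] <- n_chrom - derived[flip]
  polarized <- anc != "unknown" & !is.na(derived)
  seg <- polarized & derived >= 1 & derived <= n_chrom - 1
  res <- do.call(rbind, lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    idx <- which(
      seg & gm$sites$chrom == w$chrom &
        gm$sites$pos - 1L >= w$start & gm$sites$pos - 1L < w$end
    )
    fw <- fay_wu_h(derived[idx], n_chrom)
    data.frame(
      window_id = w$window_id, chrom = w$chrom, start = w$start, end = w$end,
      H = fw$H, n_sites = fw$n_sites, stringsAsFactors = FALSE
    )
  }))
  attr(res, "n_unpolarized") <- sum(!polarized)
  res
}

#' Principal components of a background genotype matrix
#'
#' Covariate PCs for association scans, computed from background SNPs
#' (outside genes and haploblocks) after mean imputation and centering.
#'
#' @param gm a [geno_matrix()].
#' @param site_idx indices of background SNPs (default: all sites).
#' @param n_pcs number of PCs (default 2).
#' @return samples x `n_pcs` matrix of PC scores.
#' @export
genotype_pcs <- function(gm, site_idx = seq_len(n_sites(gm)), n_pcs = 2L) {
  x <- .center_impute(gm$dosages[, site_idx, drop = FALSE])
  pc <- stats::prcomp(x, center = FALSE, rank. = n_pcs)
  pc$x[, seq_len(n_pcs), drop = FALSE]
}

#' Covariate-adjusted per-SNP association scan
#'
#' Linear regression of a quantitative phenotype on each SNP's dosage with
#' covariates (typically the first two genotype PCs) absorbed by projection;
#' two-sided t-test p-values per SNP. Missing dosages drop the affected
#' samples from that SNP's test.
#'
#' @param gm a [geno_matrix()].
#' @param phenotype numeric vector over samples (NA allowed).
#' @param covariates samples x q matrix (e.g. from [genotype_pcs()]), or
#'   NULL for an intercept-only adjustment.
#' @param min_n minimum phenotyped samples (default 30).
#' @return data.frame per SNP: `beta`, `se`, `t`, `p` (NA for SNPs constant
#'   after removing missing samples).
#' @export
gwas_scan <- function(gm, phenotype, covariates = NULL, min_n = 30L) {
  keep <- which(!is.na(phenotype))
  if (length(keep) < min_n) stop("need phenotype on at least ", min_n, " samples")
  y <- phenotype[keep]
  X <- cbind(
    intercept = rep(1, length(keep)),
    if (!is.null(covariates)) covariates[keep, , drop = FALSE]
  )
  q <- qr(X)
  resid_y <- qr.resid(q, y)
  D <- gm$dosages[keep, , drop = FALSE]
  m <- ncol(D)
  beta <- se <- tval <- pval <- rep(NA_real_, m)
  has_na <- anyNA(D)
  resid_D <- qr.resid(q, ifelse(is.na(D), 0, D))
  for (s in seq_len(m)) {
    if (has_na && anyNA(D[, s])) {
      ok <- !is.na(D[, s])
      if (sum(ok) < min_n) next
      qs <- qr(X[ok, , drop = FALSE])
      g <- qr.resid(qs, D[ok, s])
      yy <- qr.resid(qs, y[ok])
      df <- sum(ok) - ncol(X) - 1L
    } else {
      g <- resid_D[, s]
      yy <- resid_y
      df <- length(y) - ncol(X) - 1L
    }
    sxx <- sum(g^2)
    if (sxx < .Machine$double.eps || df < 1) next
    b <- sum(g * yy) / sxx
    rss <- sum((yy - b * g)^2)
    s2 <- rss / df
    beta[s] <- b
    se[s] <- sqrt(s2 / sxx)
    tval[s] <- b / se[s]
    pval[s] <- 2 * stats::pt(-abs(tval[s]), df)
  }
  data.frame(beta = beta, se = se, t = tval, p = pval)
}

#' Weighted-Z aggregation of per-SNP p-values into windows
#'
#' The weighted-Z analysis: per SNP `z_i = qnorm(1 - p_i)` with weight
#' `w_i = pbar_i (1 - pbar_i)` (across-population mean frequency
#' heterozygosity), aggregated per window as
#' `Z_W = sum(w z) / sqrt(sum(w^2))`; window significance is the empirical
#' rank of `Z_W` among all windows with at least `min_snps` SNPs.
#'
#' @param snps data.frame with columns `chrom`, `pos`, `emp_p` (in (0,1))
#'   and `pbar` (across-population mean allele frequency used for weights).
#' @param windows window tiling from [tile_windows()].
#' @param min_snps minimum SNPs per window for ranking (default 2); smaller
#'   windows are flagged and excluded from the empirical ranking.
#' @return data.frame per window: `window_id`, `chrom`, `start`, `end`,
#'   `n_snps`, `zw`, `emp_p`, `flagged`.
#' @export
wza_window <- function(snps, windows, min_snps = 2L) {
  stopifnot(all(c("chrom", "pos", "emp_p", "pbar") %in% names(snps)))
  ok <- !is.na(snps$emp_p)
  snps <- snps[ok, , drop = FALSE]
  if (any(snps$emp_p <= 0 | snps$emp_p >= 1)) {
    stop("emp_p must lie strictly inside (0, 1)")
  }
  z <- stats::qnorm(1 - snps$emp_p)
  w <- snps$pbar * (1 - snps$pbar)
  res <- do.call(rbind, lapply(seq_len(nrow(windows)), function(i) {
    wd <- windows[i, ]
    idx <- which(
      snps$chrom == wd$chrom &
        snps$pos - 1L >= wd$start & snps$pos - 1L < wd$end
    )
    zw <- if (length(idx)) {
      sum(w[idx] * z[idx]) / sqrt(sum(w[idx]^2))
    } else {
      NA_real_
    }
    data.frame(
      window_id = wd$window_id, chrom = wd$chrom, start = wd$start,
      end = wd$end, n_snps = length(idx), zw = zw,
      stringsAsFactors = FALSE
    )
  }))
  res$flagged <- res$n_snps < min_snps
  res$emp_p <- NA_real_
  res$emp_p[!res$flagged] <- empirical_p(res$zw[!res$flagged])
  res
}

#' Outlier windows at a tail of the window score distribution
#'
#' Windows whose empirical p-value falls inside the configured tail; the
#' presets mirror common scan choices (5% for XtX/EAA, 1% for contrasts,
#' 0.1% for trait associations).
#'
#' @param wza data.frame from [wza_window()].
#' @param tail tail fraction (default 0.05).
#' @return character vector of outlier `window_id`s.
#' @export
outlier_windows <- function(wza, tail = 0.05) {
  wza$window_id[!wza$flagged & !is.na(wza$emp_p) & wza$emp_p <= tail]
}
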