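# Vectorized binomial-logistic IRLS for many units sharing one predictor.
# D: units x samples matrix of dosages in {0,1,2,NA} (2 Bernoulli trials per
# sample); x: per-sample predictor. Returns per-unit intercept, slope and
# convergence/separation flags. `ridge` adds an L2 penalty to the
# information matrix (used to stabilise perfectly separated fits).
.cline_irls <- function(D, x, ridge = 0, max_iter = 50L, tol = 1e-8) {
  D <- rbind(D)
  m <- nrow(D)
  mask <- !is.na(D)
  Dm <- ifelse(mask, D, 0)
  xr <- matrix(rep(x, each = m), nrow = m)
  p0 <- pmin(pmax(rowSums(Dm) / (2 * rowSums(mask)), 1e-6), 1 - 1e-6)
  b0 <- stats::qlogis(p0)
  b1 <- rep(0, m)
  conv <- rep(FALSE, m)
  for (it in seq_len(max_iter)) {
    eta <- b0 + b1 * xr
    mu <- stats::plogis(eta)
    W <- 2 * mu * (1 - mu) * mask
    r <- (Dm - 2 * mu) * mask
    U0 <- rowSums(r) - 2 * ridge * b0
    U1 <- rowSums(r * xr) - 2 * ridge * b1
    I00 <- rowSums(W) + 2 * ridge
    I01 <- rowSums(W * xr)
    I11 <- rowSums(W * xr^2) + 2 * ridge
    det <- I00 * I11 - I01^2
    det[det <= 0 | !is.finite(det)] <- NA
    db0 <- (I11 * U0 - I01 * U1) / det
    db1 <- (I00 * U1 - I01 * U0) / det
    db0[is.na(db0)] <- 0
    db1[is.na(db1)] <- 0
    b0 <- b0 + db0
    b1 <- b1 + db1
    conv <- pmax(abs(db0), abs(db1)) < tol
    if (all(conv)) break
  }
  list(b0 = b0, b1 = b1, converged = conv)
}

#' Fit a latitudinal frequency cline by logistic regression
#'
#' Binomial GLM of per-individual allele dosage (2 trials) on absolute
#' latitude, fitted by iteratively reweighted least squares. On perfect
#' separation (non-convergence or runaway coefficients) the fit is repeated
#' with a small ridge penalty (`lambda = 1e-6`) and flagged.
#'
#' @param dosages numeric vector of dosages in `{0, 1, 2, NA}` (one per
#'   sample), or a units x samples matrix for many units at once.
#' @param latitudes per-sample latitudes (degrees); the model uses
#'   `|latitude|`.
#' @param abs_lat logical; use absolute latitude (default TRUE).
#' @return data.frame with columns `b0`, `b1`, `converged` (logical) and
#'   `separation` (TRUE when the ridge refit was needed).
#' @export
fit_cline <- function(dosages, latitudes, abs_lat = TRUE) {
  x <- if (abs_lat) abs(latitudes) else latitudes
  if (length(unique(x)) < 2) stop("latitude is constant; cline is undefined")
  D <- rbind(dosages)
  stopifnot(ncol(D) == length(x))
  fit <- .cline_irls(D, x)
  bad <- !fit$converged | abs(fit$b1) > 15 | abs(fit$b0) > 150 |
    !is.finite(fit$b0) | !is.finite(fit$b1)
  sep <- rep(FALSE, nrow(D))
  if (any(bad)) {
    refit <- .cline_irls(D[bad, , drop = FALSE], x, ridge = 1e-6)
    fit$b0[bad] <- refit$b0
    fit$b1[bad] <- refit$b1
    fit$converged[bad] <- refit$converged
    sep[bad] <- TRUE
  }
  data.frame(
    b0 = fit$b0, b1 = fit$b1, converged = fit$converged,
    separation = sep
  )
}

#' Empirical null distribution of SNP cline slopes
#'
#' Fits the latitudinal cline to `k` SNPs sampled from outside genes and
#' haploblocks and records the two-sided tail cutoffs of the slope
#' distribution. Haploblock (or SNP) slopes falling outside the cutoffs are
#' deemed significant relative to this genome-wide random-SNP null.
#'
#' @param gm a [geno_matrix()].
#' @param annotations list with `genes` and `haploblocks` interval
#'   data.frames (either may be NULL).
#' @param latitudes per-sample latitudes, aligned with `gm` samples.
#' @param k number of null SNPs (default 10000); if fewer are eligible, all
#'   are used with a warning.
#' @param seed integer seed for SNP sampling.
#' @param tail total tail mass (default 0.05). With
#'   `two_sided = TRUE` the cutoffs are the `tail/2` and `1 - tail/2` slope
#'   quantiles; one-sided mode puts `tail` in each direction.
#' @param two_sided logical (default TRUE).
#' @return object of class `cline_null`: `slopes`, `cutoffs`
#'   (`lower`/`upper`), `n_excluded` (non-converged or separated fits),
#'   `tail`, `two_sided`.
#' @export
null_slope_distribution <- function(gm, annotations, latitudes, k = 10000L,
                                    seed = 1L, tail = 0.05, two_sided = TRUE) {
  excl <- sites_in_intervals(gm, annotations$genes) |
    sites_in_intervals(gm, annotations$haploblocks)
  eligible <- which(!excl)
  if (k > length(eligible)) {
    warning(
      "only ", length(eligible), " eligible SNPs for a null of ", k,
      "; using all of them"
    )
    idx <- eligible
  } else {
    set.seed(seed)
    idx <- sort(sample(eligible, k))
  }
  fits <- fit_cline(t(gm$dosages[, idx, drop = FALSE]), latitudes)
  ok <- fits$converged & !fits$separation
  slopes <- fits$b1[ok]
  q <- if (two_sided) c(tail / 2, 1 - tail / 2) else c(tail, 1 - tail)
  cutoffs <- stats::quantile(slopes, q, names = FALSE)
  structure(
    list(
      slopes = slopes, cutoffs = c(lower = cutoffs[1], upper = cutoffs[2]),
      n_excluded = sum(!ok), tail = tail, two_sided = two_sided,
      snp_index = idx
    ),
    class = "cline_null"
  )
}

#' Significance of cline slopes against the SNP null
#'
#' @param fits data.frame from [fit_cline()] (columns `b1`, `converged`).
#' @param null a `cline_null` from [null_slope_distribution()].
#' @return the fits with added `significant` (slope outside the null
#'   cutoffs) and `direction` (`"+"`/`"-"`) columns.
#' @export
cline_significance <- function(fits, null) {
  fits$significant <- fits$b1 < null$cutoffs["lower"] |
    fits$b1 > null$cutoffs["upper"]
  fits$direction <- ifelse(fits$b1 >= 0, "+", "-")
  fits
}

#' Cross-range parallelism of cline slopes
#'
#' A unit (haploblock or SNP) shows parallel climate adaptation when its
#' cline slope is significant and of identical sign in at least two ranges.
#'
#' @param fits data.frame with one row per unit x range: columns `unit`,
#'   `range`, `significant`, `direction`.
#' @return data.frame per unit: `unit`, `n_significant`,
#'   `ranges_significant`, `parallel`, `shared_direction` (NA when not
#'   parallel).
#' @export
call_parallelism <- function(fits) {
  out <- lapply(split(fits, fits$unit), function(f) {
    sig <- f[f$significant, , drop = FALSE]
    par <- FALSE
    dir <- NA_character_
    if (nrow(sig) >= 2) {
      tab <- table(sig$direction)
      if (any(tab >= 2)) {
        par <- TRUE
        dir <- names(tab)[which.max(tab)]
      }
    }
    data.frame(
      unit = f$unit[1], n_significant = nrow(sig),
      ranges_significant = paste(sig$range, collapse = ","),
      parallel = par, shared_direction = dir, stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Joint cline model with range effects
#'
#' Optional cross-range fit: binomial GLM of dosage on `|latitude| * range`
#' (main effects plus interaction); when the interaction is nonsignificant
#' at `alpha` it is dropped and the additive model returned.
#'
#' @param dosages per-sample dosages in `{0,1,2,NA}`.
#' @param latitudes per-sample latitudes.
#' @param range per-sample range labels.
#' @param alpha significance level for retaining the interaction (default
#'   0.05).
#' @return list with the fitted [stats::glm()] object (`model`) and
#'   `interaction_kept`.
#' @export
cline_range_model <- function(dosages, latitudes, range, alpha = 0.05) {
  ok <- !is.na(dosages)
  df <- data.frame(
    y = dosages[ok], x = abs(latitudes)[ok],
    range = factor(range[ok])
  )
  full <- stats::glm(cbind(y, 2 - y) ~ x * range, stats::binomial(), data = df)
  reduced <- stats::glm(cbind(y, 2 - y) ~ x + range, stats::binomial(), data = df)
  p_int <- stats::anova(reduced, full, test = "Chisq")$`Pr(>Chi)`[2]
  keep <- !is.na(p_int) && p_int < alpha
  list(model = if (keep) full else reduced, interaction_kept = keep)
}
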