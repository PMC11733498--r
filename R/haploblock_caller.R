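# 1-D mean silhouette for a k-means partition of PC1 scores.
.silhouette_1d <- function(x, cluster) {
  ks <- sort(unique(cluster))
  if (length(ks) < 2) {
    return(0)
  }
  s <- vapply(seq_along(x), function(i) {
    own <- cluster[i]
    same <- x[cluster == own]
    if (length(same) < 2) {
      return(0)
    }
    a <- sum(abs(x[i] - same)) / (length(same) - 1)
    b <- min(vapply(
      ks[ks != own],
      function(kk) mean(abs(x[i] - x[cluster == kk])), numeric(1)
    ))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Genotype a candidate region from local PCA clustering
#'
#' PCA over the region's SNPs; 1-D k-means with k = 3 on PC1, centers
#' initialized at the minimum, median and maximum score. A call is accepted
#' only when three clusters are occupied and the clustering is discrete
#' (mean silhouette at least `min_silhouette`) — the signature of two
#' homozygous and one heterozygous arrangement genotype. The middle cluster
#' is labeled AB; orientation is fixed so that A is the globally more
#' frequent arrangement. Samples farther from every cluster center than
#' `unassign_frac` times the smallest gap between adjacent centers are left
#' unassigned.
#'
#' @param gm a [geno_matrix()].
#' @param region one-row data.frame (`chrom`, `start`, `end`), 0-based
#'   half-open.
#' @param min_sites minimum polymorphic SNPs in the region (default 20).
#' @param min_silhouette trimodality acceptance threshold (default 0.75).
#' @param unassign_frac distance fraction beyond which samples are
#'   unassigned (default 0.5).
#' @return list of class `haploblock_call` with `region`, `pc1`, `genotype`
#'   (named character, `AA`/`AB`/`BB`/`unassigned`), `centers`, `sizes`,
#'   `silhouette`, `rejected`, `reason`.
#' @export
region_pca_genotype <- function(gm, region, min_sites = 20L,
                                min_silhouette = 0.75, unassign_frac = 0.5) {
  idx <- which(
    gm$sites$chrom == region$chrom &
      gm$sites$pos - 1L >= region$start & gm$sites$pos - 1L < region$end
  )
  reject <- function(reason) {
    structure(
      list(
        region = region, pc1 = NULL, genotype = NULL, centers = NULL,
        sizes = NULL, silhouette = NA_real_, rejected = TRUE, reason = reason
      ),
      class = "haploblock_call"
    )
  }
  if (length(idx) < min_sites) {
    return(reject("too few SNPs"))
  }
  x <- .center_impute(gm$dosages[, idx, drop = FALSE])
  pc1 <- stats::prcomp(x, center = FALSE)$x[, 1]
  names(pc1) <- gm$sample_ids

  init <- c(min(pc1), stats::median(pc1), max(pc1))
  if (length(unique(init)) < 3) {
    return(reject("no trimodal structure"))
  }
  km <- suppressWarnings(stats::kmeans(pc1, centers = matrix(init)))
  if (length(unique(km$cluster)) < 3) {
    return(reject("no trimodal structure"))
  }
  sil <- .silhouette_1d(pc1, km$cluster)
  if (sil < min_silhouette) {
    return(reject("no trimodal structure"))
  }

  ord <- order(km$centers)
  lab <- c("AA", "AB", "BB")[match(km$cluster, ord)]
  centers <- sort(drop(km$centers))
  gaps <- diff(centers)
  dist_to_center <- abs(pc1 - centers[match(km$cluster, ord)])
  lab[dist_to_center > unassign_frac * min(gaps)] <- "unassigned"

  n_assigned <- sum(lab != "unassigned")
  freq_b <- (sum(lab == "AB") + 2 * sum(lab == "BB")) / (2 * n_assigned)
  names(centers) <- c("AA", "AB", "BB")
  if (freq_b > 0.5) { # A is defined as the more frequent arrangement
    lab[lab == "AA"] <- "zz"
    lab[lab == "BB"] <- "AA"
    lab[lab == "zz"] <- "BB"
    names(centers) <- c("BB", "AB", "AA")
  }
  names(lab) <- gm$sample_ids
  structure(
    list(
      region = region, pc1 = pc1, genotype = lab,
      centers = centers, sizes = table(factor(lab, c("AA", "AB", "BB", "unassigned"))),
      silhouette = sil, n_sites = length(idx), rejected = FALSE, reason = NA_character_
    ),
    class = "haploblock_call"
  )
}

#' Heterokaryotype heterozygosity test
#'
#' Computes each sample's observed heterozygosity over the region's SNPs
#' (fraction of non-missing genotypes that are heterozygous), summarises
#' each arrangement genotype class by its mean and standard error, and
#' passes when the heterozygote (AB) band `mean +- SEM` is disjoint from
#' both homozygote bands and the AB mean is the highest — the elevated
#' heterozygosity expected of inversion heterokaryotypes.
#'
#' @param gm a [geno_matrix()].
#' @param region one-row interval data.frame.
#' @param call a `haploblock_call` from [region_pca_genotype()].
#' @return list with `stats` (per-class mean, SEM, n) and `pass`
#'   (TRUE/FALSE, or NA when any class has fewer than 2 samples —
#'   "inconclusive").
#' @export
heterozygosity_test <- function(gm, region, call) {
  if (call$rejected) {
    return(list(stats = NULL, pass = NA))
  }
  idx <- which(
    gm$sites$chrom == region$chrom &
      gm$sites$pos - 1L >= region$start & gm$sites$pos - 1L < region$end
  )
  d <- gm$dosages[, idx, drop = FALSE]
  het <- rowMeans(d == 1L, na.rm = TRUE)
  cls <- call$genotype
  st <- do.call(rbind, lapply(c("AA", "AB", "BB"), function(cl) {
    h <- het[cls == cl]
    data.frame(
      class = cl, n = length(h), mean_het = mean(h),
      sem = stats::sd(h) / sqrt(length(h)), stringsAsFactors = FALSE
    )
  }))
  if (any(st$n < 2)) {
    return(list(stats = st, pass = NA))
  }
  lo <- st$mean_het - st$sem
  hi <- st$mean_het + st$sem
  ab <- which(st$class == "AB")
  hom <- which(st$class != "AB")
  disjoint <- all(lo[ab] > hi[hom] | hi[ab] < lo[hom])
  pass <- disjoint && all(st$mean_het[ab] > st$mean_het[hom])
  list(stats = st, pass = pass)
}

#' Linkage-disequilibrium validation of a haploblock call
#'
#' Composite-genotype r^2 (squared Pearson correlation of dosages) over all
#' pairs among up to `n_snps` region SNPs with MAF > 0.05, computed on all
#' samples and again within the subset homozygous for the more common
#' arrangement (AA). A true haploblock shows high LD overall (arrangement
#' segregation couples all markers) that collapses within homokaryotypes,
#' where recombination is free.
#'
#' @param gm a [geno_matrix()].
#' @param region one-row interval data.frame.
#' @param call a `haploblock_call`.
#' @param n_snps maximum SNPs used (default 5000).
#' @param seed seed for SNP subsampling.
#' @param delta required drop in median r^2 (all samples minus homozygote
#'   subset) for a pass (default 0.2).
#' @param min_hom minimum AA-subset size (default 10); below it the test is
#'   inconclusive.
#' @return list with `median_r2_all`, `median_r2_hom`, `n_snps`, `n_hom`,
#'   `pass` (TRUE/FALSE/NA).
#' @export
ld_validation <- function(gm, region, call, n_snps = 5000L, seed = 1L,
                          delta = 0.2, min_hom = 10L) {
  if (call$rejected) {
    return(list(
      median_r2_all = NA, median_r2_hom = NA, n_snps = 0,
      n_hom = 0, pass = NA
    ))
  }
  idx <- which(
    gm$sites$chrom == region$chrom &
      gm$sites$pos - 1L >= region$start & gm$sites$pos - 1L < region$end
  )
  maf <- site_maf(subset_geno(gm, sites = idx))
  idx <- idx[!is.na(maf) & maf > 0.05]
  if (length(idx) > n_snps) {
    set.seed(seed)
    idx <- sort(sample(idx, n_snps))
  }
  hom <- which(call$genotype == "AA")
  if (length(idx) < 2) {
    return(list(
      median_r2_all = NA, median_r2_hom = NA, n_snps = length(idx),
      n_hom = length(hom), pass = NA
    ))
  }
  med_r2 <- function(rows) {
    x <- gm$dosages[rows, idx, drop = FALSE]
    r <- if (anyNA(x)) {
      suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
    } else {
      xc <- sweep(x, 2L, colMeans(x))
      cc <- crossprod(xc)
      sd0 <- sqrt(diag(cc))
      sd0[sd0 == 0] <- NA
      cc / tcrossprod(sd0)
    }
    v <- r[upper.tri(r)]^2
    stats::median(v, na.rm = TRUE)
  }
  r2_all <- med_r2(seq_along(gm$sample_ids))
  if (length(hom) < min_hom) {
    return(list(
      median_r2_all = r2_all, median_r2_hom = NA, n_snps = length(idx),
      n_hom = length(hom), pass = NA
    ))
  }
  r2_hom <- med_r2(hom)
  list(
    median_r2_all = r2_all, median_r2_hom = r2_hom, n_snps = length(idx),
    n_hom = length(hom),
    pass = isTRUE(r2_all - r2_hom >= delta)
  )
}

#' Arrangement frequencies per population and range
#'
#' Frequency of the B arrangement, `(n_AB + 2 n_BB) / (2 n_assigned)`,
#' within each grouping; unassigned samples are excluded.
#'
#' @param call a `haploblock_call`.
#' @param samples sample metadata data.frame (`sample`, `population`,
#'   `range`).
#' @return list with `overall`, `by_population`, `by_range` (named numeric;
#'   `NA` for groups with no assigned samples).
#' @export
haploblock_frequencies <- function(call, samples) {
  if (call$rejected) stop("cannot compute frequencies for a rejected call")
  g <- call$genotype[match(samples$sample, names(call$genotype))]
  freq <- function(gg) {
    gg <- gg[gg != "unassigned" & !is.na(gg)]
    if (!length(gg)) {
      return(NA_real_)
    }
    (sum(gg == "AB") + 2 * sum(gg == "BB")) / (2 * length(gg))
  }
  list(
    overall = freq(g),
    by_population = vapply(split(g, samples$population), freq, numeric(1)),
    by_range = vapply(split(g, samples$range), freq, numeric(1))
  )
}

#' Genotype and validate candidate regions as haploblocks
#'
#' Runs [region_pca_genotype()], [heterozygosity_test()], optionally
#' [ld_validation()], and [haploblock_frequencies()] over each candidate
#' region. A region is confirmed as a haploblock when it shows trimodal PC1
#' structure and passes the heterozygosity test; LD is reported as a
#' diagnostic.
#'
#' @param gm a [geno_matrix()].
#' @param candidates data.frame of candidate regions (`chrom`, `start`,
#'   `end`), e.g. from [find_candidate_regions()].
#' @param samples sample metadata data.frame.
#' @param run_ld logical; also compute the LD diagnostic (default TRUE).
#' @param ... passed to [region_pca_genotype()].
#' @return list with `calls` (list of augmented `haploblock_call` objects)
#'   and `summary` (one row per candidate: genotype counts, test outcomes,
#'   `confirmed`).
#' @export
call_haploblocks <- function(gm, candidates, samples, run_ld = TRUE, ...) {
  calls <- list()
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    region <- candidates[i, , drop = FALSE]
    call <- region_pca_genotype(gm, region, ...)
    het <- heterozygosity_test(gm, region, call)
    ld <- if (run_ld) ld_validation(gm, region, call) else NULL
    call$het_stats <- het$stats
    call$het_test_pass <- het$pass
    call$ld_stats <- ld
    call$ld_test_pass <- if (is.null(ld)) NA else ld$pass
    call$confirmed <- !call$rejected && isTRUE(het$pass)
    if (call$confirmed) call$frequencies <- haploblock_frequencies(call, samples)
    calls[[i]] <- call
    rows[[i]] <- data.frame(
      chrom = region$chrom, start = region$start, end = region$end,
      rejected = call$rejected, reason = call$reason,
      silhouette = call$silhouette,
      n_AA = if (call$rejected) NA else unname(call$sizes["AA"]),
      n_AB = if (call$rejected) NA else unname(call$sizes["AB"]),
      n_BB = if (call$rejected) NA else unname(call$sizes["BB"]),
      het_pass = het$pass,
      ld_pass = if (is.null(ld)) NA else ld$pass,
      confirmed = call$confirmed, stringsAsFactors = FALSE
    )
  }
  list(calls = calls, summary = do.call(rbind, rows))
}
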