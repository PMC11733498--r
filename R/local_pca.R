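#' Sample covariance of a genomic window
#'
#' Dosages of the window's polymorphic sites are mean-imputed (missing
#' entries only) and centered per site, optionally scaled by
#' `sqrt(p(1-p))`; the samples x samples covariance is averaged over sites.
#'
#' @param gm a [geno_matrix()].
#' @param window one-row data.frame (`chrom`, `start`, `end`), 0-based
#'   half-open.
#' @param min_sites minimum polymorphic SNPs required; windows below this
#'   return NULL (skipped).
#' @param scale logical; scale sites by `sqrt(p(1-p))`.
#' @return samples x samples covariance matrix with attribute `"n_sites"`,
#'   or NULL if the window has too few sites.
#' @export
window_covariance <- function(gm, window, min_sites = 25L, scale = FALSE) {
  idx <- which(
    gm$sites$chrom == window$chrom &
      gm$sites$pos - 1L >= window$start & gm$sites$pos - 1L < window$end
  )
  if (length(idx)) {
    p <- colMeans(gm$dosages[, idx, drop = FALSE], na.rm = TRUE) / 2
    idx <- idx[!is.na(p) & p > 0 & p < 1]
  }
  if (length(idx) < min_sites) {
    return(NULL)
  }
  x <- .center_impute(gm$dosages[, idx, drop = FALSE], scale = scale)
  cov <- tcrossprod(x) / length(idx)
  attr(cov, "n_sites") <- length(idx)
  cov
}

# Trace-normalized rank-k eigen-decomposition of a covariance matrix,
# stored as W = U_k diag(sqrt(lambda_k)) so that A_k = W W'.
.rank_k_factor <- function(cov, k) {
  cov <- cov / sum(diag(cov))
  e <- eigen(cov, symmetric = TRUE)
  lam <- pmax(e$values[seq_len(k)], 0)
  list(W = e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k),
       lam = lam)
}

#' Distance between two windows' population structures
#'
#' Frobenius norm of the difference between the rank-`k`, trace-normalized
#' covariance approximations of the two windows. Zero iff the truncated
#' maps coincide; symmetric in its arguments.
#'
#' @param cov_a,cov_b samples x samples covariances over the same sample set
#'   (from [window_covariance()]).
#' @param k rank of the truncation (default 2).
#' @return nonnegative scalar.
#' @export
window_distance <- function(cov_a, cov_b, k = 2L) {
  if (!all(dim(cov_a) == dim(cov_b))) {
    stop("windows computed over different sample sets")
  }
  fa <- .rank_k_factor(cov_a, k)
  fb <- .rank_k_factor(cov_b, k)
  sa <- sum(fa$lam^2)
  sb <- sum(fb$lam^2)
  cross <- sum(crossprod(fa$W, fb$W)^2)
  sqrt(max(sa + sb - 2 * cross, 0))
}

#' Windowed local PCA over a genotype matrix
#'
#' Computes per-window covariances, their rank-`k` spectral summaries, and
#' the full window-to-window distance matrix used for MDS embedding.
#'
#' @param gm a [geno_matrix()].
#' @param windows window tiling from [tile_windows()].
#' @param k truncation rank for window distances (default 2).
#' @param min_sites minimum polymorphic SNPs per window (default 25).
#' @param scale logical; passed to [window_covariance()].
#' @return list with `windows` (retained windows, with `n_sites`),
#'   `skipped` (window ids below `min_sites`), and `dist` (distance matrix
#'   over retained windows).
#' @export
local_pca_windows <- function(gm, windows, k = 2L, min_sites = 25L,
                              scale = FALSE) {
  n <- length(gm$sample_ids)
  covs <- lapply(seq_len(nrow(windows)), function(i) {
    window_covariance(gm, windows[i, ], min_sites = min_sites, scale = scale)
  })
  keep <- !vapply(covs, is.null, logical(1))
  if (sum(keep) < 2) stop("fewer than 2 windows with >= min_sites SNPs")
  facs <- lapply(covs[keep], .rank_k_factor, k = k)
  m <- length(facs)
  big <- do.call(cbind, lapply(facs, `[[`, "W")) # n x (m*k)
  G2 <- crossprod(big)^2
  grp <- rep(seq_len(m), each = k)
  cross <- t(rowsum(t(rowsum(G2, grp)), grp))
  s <- vapply(facs, function(f) sum(f$lam^2), numeric(1))
  D2 <- outer(s, s, "+") - 2 * cross
  D <- sqrt(pmax(D2, 0))
  diag(D) <- 0
  ret <- windows[keep, , drop = FALSE]
  ret$n_sites <- vapply(covs[keep], attr, numeric(1), which = "n_sites")
  dimnames(D) <- list(ret$window_id, ret$window_id)
  list(windows = ret, skipped = windows$window_id[!keep], dist = D)
}

#' Classical MDS embedding of window distances
#'
#' Torgerson double-centering MDS (via [stats::cmdscale()]) onto `n_axes`
#' axes ordered by eigenvalue. Axis signs are fixed deterministically: the
#' loading with the largest magnitude on each axis is made positive.
#'
#' @param D square symmetric nonnegative distance matrix.
#' @param n_axes number of axes (default 5).
#' @return list of class `mds_map` with `coords` (windows x axes, centered),
#'   `eig` (eigenvalue spectrum) and `degenerate` (TRUE when all distances
#'   are zero).
#' @export
mds_embed <- function(D, n_axes = 5L) {
  stopifnot(nrow(D) == ncol(D))
  m <- nrow(D)
  n_axes <- min(n_axes, m - 1L)
  if (all(D == 0)) {
    warning("all window distances are zero; degenerate MDS map")
    coords <- matrix(0, m, n_axes, dimnames = list(rownames(D), NULL))
    return(structure(
      list(coords = coords, eig = rep(0, m), degenerate = TRUE),
      class = "mds_map"
    ))
  }
  fit <- stats::cmdscale(stats::as.dist(D), k = n_axes, eig = TRUE)
  coords <- fit$points
  if (ncol(coords) < n_axes) { # pad axes lost to non-positive eigenvalues
    coords <- cbind(coords, matrix(0, m, n_axes - ncol(coords)))
  }
  for (a in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, a]))
    if (coords[i, a] < 0) coords[, a] <- -coords[, a]
  }
  colnames(coords) <- paste0("mds", seq_len(ncol(coords)))
  structure(
    list(coords = coords, eig = fit$eig, degenerate = FALSE),
    class = "mds_map"
  )
}

#' Corner outliers of an MDS map
#'
#' For each unordered pair of axes and each of the four diagonal directions
#' `(+-1, +-1)/sqrt(2)`, flags windows whose projection onto the direction
#' exceeds the `1 - tail` quantile of all projections. The union over
#' corners is returned with corner labels.
#'
#' @param mds an `mds_map` from [mds_embed()].
#' @param tail corner tail fraction (default 0.05).
#' @return data.frame with columns `window_id`, `axis_i`, `axis_j`, `corner`
#'   (e.g. `"++"`), `projection`.
#' @export
corner_outliers <- function(mds, tail = 0.05) {
  co <- mds$coords
  m <- nrow(co)
  if (m < 20) warning("corner outliers from fewer than 20 windows")
  axes <- seq_len(ncol(co))
  out <- list()
  dirs <- list("++" = c(1, 1), "+-" = c(1, -1), "-+" = c(-1, 1), "--" = c(-1, -1))
  for (i in axes) {
    for (j in axes[axes > i]) {
      for (d in names(dirs)) {
        u <- dirs[[d]] / sqrt(2)
        proj <- co[, i] * u[1] + co[, j] * u[2]
        if (tail >= 1) {
          hit <- rep(TRUE, m)
        } else {
          hit <- proj > stats::quantile(proj, 1 - tail)
        }
        if (any(hit)) {
          out[[length(out) + 1L]] <- data.frame(
            window_id = rownames(co)[hit], axis_i = i, axis_j = j,
            corner = d, projection = proj[hit], stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(
      window_id = character(), axis_i = integer(), axis_j = integer(),
      corner = character(), projection = numeric(), stringsAsFactors = FALSE
    )
  }
  rownames(res) <- NULL
  res
}

#' Merge corner-outlier windows into candidate haploblock regions
#'
#' Same-chromosome outlier windows from the same corner (axis pair and
#' direction) are merged when separated by at most `max_gap` intervening
#' windows; runs supported by fewer than `min_windows` outlier windows are
#' dropped. Overlapping regions arising from different corners are unioned.
#'
#' @param outliers data.frame from [corner_outliers()].
#' @param windows the full window tiling from [tile_windows()] (gaps are
#'   measured on this tiling, so windows skipped for low SNP counts still
#'   count toward gaps).
#' @param max_gap maximum intervening non-outlier windows within a run
#'   (default 1).
#' @param min_windows minimum outlier windows per region (default 3).
#' @return data.frame of candidate regions: `chrom`, `start`, `end`,
#'   `n_windows`, `corners`.
#' @export
merge_candidates <- function(outliers, windows, max_gap = 1L, min_windows = 3L) {
  empty <- data.frame(
    chrom = character(), start = numeric(), end = numeric(),
    n_windows = integer(), corners = character(), stringsAsFactors = FALSE
  )
  if (nrow(outliers) == 0) {
    return(empty)
  }
  widx <- match(outliers$window_id, windows$window_id)
  outliers$chrom <- windows$chrom[widx]
  outliers$widx <- widx
  regions <- list()
  by <- split(
    outliers,
    paste(outliers$chrom, outliers$axis_i, outliers$axis_j, outliers$corner)
  )
  for (g in by) {
    idx <- sort(unique(g$widx))
    runs <- cumsum(c(1, diff(idx) > max_gap + 1L))
    for (r in split(idx, runs)) {
      if (length(r) < min_windows) next
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = windows$chrom[r[1]],
        start = windows$start[r[1]],
        end = windows$end[r[length(r)]],
        n_windows = length(r),
        corners = paste0(g$axis_i[1], "-", g$axis_j[1], g$corner[1]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(regions)) {
    return(empty)
  }
  reg <- do.call(rbind, regions)
  # union overlapping regions found from different corners
  reg <- reg[order(reg$chrom, reg$start), ]
  merged <- list()
  cur <- reg[1, ]
  for (i in seq_len(nrow(reg))[-1]) {
    nxt <- reg[i, ]
    if (nxt$chrom == cur$chrom && nxt$start < cur$end) {
      cur$end <- max(cur$end, nxt$end)
      cur$n_windows <- max(cur$n_windows, nxt$n_windows)
      cur$corners <- paste(unique(c(
        strsplit(cur$corners, ",")[[1]], nxt$corners
      )), collapse = ",")
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- nxt
    }
  }
  merged[[length(merged) + 1L]] <- cur
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out
}

#' Candidate haploblock regions from local PCA
#'
#' End-to-end discovery stage: 100-kbp window covariances, rank-`k`
#' distances, 5-axis MDS, 5% corner outliers, and merging into candidate
#' regions.
#'
#' @param gm a [geno_matrix()].
#' @param contig_lengths named vector of contig lengths; inferred from the
#'   largest site position per chromosome (rounded up to `width`) if NULL.
#' @param width window width in bp (default 1e5).
#' @param n_axes MDS axes (default 5).
#' @param tail corner tail (default 0.05).
#' @param k rank for window distances (default 2).
#' @param min_sites minimum polymorphic SNPs per window (default 25).
#' @param max_gap,min_windows merging parameters, see [merge_candidates()].
#' @return list with `candidates`, `mds`, `windows`, `outliers`, `skipped`.
#' @export
find_candidate_regions <- function(gm, contig_lengths = NULL, width = 1e5,
                                   n_axes = 5L, tail = 0.05, k = 2L,
                                   min_sites = 25L, max_gap = 1L,
                                   min_windows = 3L) {
  if (is.null(contig_lengths)) {
    mx <- tapply(gm$sites$pos, gm$sites$chrom, max)
    contig_lengths <- stats::setNames(
      ceiling(as.numeric(mx) / width) * width, names(mx)
    )
  }
  windows <- tile_windows(contig_lengths, width)
  lp <- local_pca_windows(gm, windows, k = k, min_sites = min_sites)
  mds <- mds_embed(lp$dist, n_axes = n_axes)
  outl <- corner_outliers(mds, tail = tail)
  cand <- merge_candidates(outl, windows, max_gap = max_gap, min_windows = min_windows)
  list(
    candidates = cand, mds = mds, windows = lp$windows,
    outliers = outl, skipped = lp$skipped
  )
}
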