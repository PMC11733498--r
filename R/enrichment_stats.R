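#' Which windows fall inside haploblocks
#'
#' A window belongs to a haploblock when its midpoint lies inside the
#' haploblock interval (default), or when the overlap fraction exceeds
#' `min_overlap` with `rule = "overlap"`.
#'
#' @param windows window tiling data.frame (`chrom`, `start`, `end`,
#'   `window_id`).
#' @param haploblocks interval data.frame (`chrom`, `start`, `end`), 0-based
#'   half-open.
#' @param rule `"midpoint"` (default) or `"overlap"`.
#' @param min_overlap minimum overlap fraction for `rule = "overlap"`
#'   (default 0.5).
#' @return logical vector over windows.
#' @export
windows_in_haploblocks <- function(windows, haploblocks, rule = c("midpoint", "overlap"),
                                   min_overlap = 0.5) {
  rule <- match.arg(rule)
  if (is.null(haploblocks) || nrow(haploblocks) == 0) {
    return(rep(FALSE, nrow(windows)))
  }
  hit <- rep(FALSE, nrow(windows))
  for (i in seq_len(nrow(haploblocks))) {
    h <- haploblocks[i, ]
    same <- windows$chrom == h$chrom
    if (rule == "midpoint") {
      mid <- (windows$start + windows$end) / 2
      hit <- hit | (same & mid >= h$start & mid < h$end)
    } else {
      ov <- pmax(0, pmin(windows$end, h$end) - pmax(windows$start, h$start))
      hit <- hit | (same & ov / (windows$end - windows$start) >= min_overlap)
    }
  }
  hit
}

#' Hypergeometric enrichment of outlier windows in haploblocks
#'
#' Upper-tail hypergeometric test `P(X >= k)` of the overlap `k` between an
#' outlier window set (`n` draws) and a haploblock's windows (`K`
#' successes) in a universe of `N` windows, Bonferroni-corrected across the
#' haploblocks tested.
#'
#' @param outlier_ids character vector of outlier window ids.
#' @param haploblock_windows named list mapping haploblock names to their
#'   window id vectors.
#' @param total_windows total number of windows in the universe, or a
#'   vector of all universe window ids.
#' @param alpha significance level applied to the adjusted p (default
#'   0.05).
#' @return data.frame per haploblock: `haploblock`, `K`, `n`, `k`, `p`,
#'   `p_adj`, `enriched`.
#' @export
hypergeom_enrichment <- function(outlier_ids, haploblock_windows, total_windows,
                                 alpha = 0.05) {
  N <- if (length(total_windows) == 1 && is.numeric(total_windows)) {
    as.integer(total_windows)
  } else {
    length(unique(total_windows))
  }
  n <- length(unique(outlier_ids))
  n_tests <- length(haploblock_windows)
  out <- do.call(rbind, lapply(names(haploblock_windows), function(hb) {
    K <- length(unique(haploblock_windows[[hb]]))
    k <- length(intersect(outlier_ids, haploblock_windows[[hb]]))
    if (k > min(K, n) || K > N || n > N) {
      stop("inconsistent window counts for haploblock ", hb)
    }
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(
      haploblock = hb, K = K, n = n, k = k, p = p,
      p_adj = min(1, p * n_tests), stringsAsFactors = FALSE
    )
  }))
  out$enriched <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Overlap between two outlier window sets
#'
#' Intersection count with its expectation under independence and an
#' upper-tail hypergeometric p-value — the parallelism test for outlier
#' sets from two ranges.
#'
#' @param a_ids,b_ids window id vectors.
#' @param total_windows universe size (count) or vector of universe ids.
#' @return data.frame: `n_a`, `n_b`, `overlap`, `expected`, `p`.
#' @export
outlier_overlap <- function(a_ids, b_ids, total_windows) {
  N <- if (length(total_windows) == 1 && is.numeric(total_windows)) {
    as.integer(total_windows)
  } else {
    length(unique(total_windows))
  }
  a <- unique(a_ids)
  b <- unique(b_ids)
  k <- length(intersect(a, b))
  data.frame(
    n_a = length(a), n_b = length(b), overlap = k,
    expected = length(a) * length(b) / N,
    p = stats::phyper(k - 1, length(a), N - length(a), length(b),
      lower.tail = FALSE
    )
  )
}

#' Rank-sum shift test of haploblock vs non-haploblock window scores
#'
#' Two-sided Mann-Whitney U test comparing window scores (e.g. weighted-Z
#' values) inside haploblocks against the rest of the genome, reporting
#' which group ranks higher and the conventional significance stars
#' (0.05 / 0.01 / 0.001).
#'
#' @param scores numeric vector of per-window scores.
#' @param in_haploblock logical vector over windows.
#' @return data.frame: `U`, `p`, `direction` (`"haploblock"` or
#'   `"background"`, the higher-ranked group), `stars`.
#' @export
haploblock_shift_test <- function(scores, in_haploblock) {
  stopifnot(length(scores) == length(in_haploblock))
  ok <- !is.na(scores)
  x <- scores[ok & in_haploblock]
  y <- scores[ok & !in_haploblock]
  if (!length(x) || !length(y)) stop("both window groups must be non-empty")
  if (length(unique(c(x, y))) == 1) {
    return(data.frame(
      U = length(x) * length(y) / 2, p = 1,
      direction = NA_character_, stars = "", stringsAsFactors = FALSE
    ))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
  dir <- if (mean(rank(c(x, y))[seq_along(x)]) >= mean(rank(c(x, y))[-seq_along(x)])) {
    "haploblock"
  } else {
    "background"
  }
  p <- wt$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  data.frame(
    U = unname(wt$statistic), p = p, direction = dir, stars = stars,
    stringsAsFactors = FALSE
  )
}
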