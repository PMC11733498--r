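#' Genotype matrix container
#'
#' Holds per-sample biallelic SNP dosages together with per-site metadata and
#' ancestral-allele polarity. Dosages count copies of the ALT allele
#' (0, 1, 2, or `NA` for missing). Sites must be biallelic SNPs with strictly
#' increasing positions within each chromosome.
#'
#' @param dosages integer matrix, samples x sites; entries in `{0, 1, 2, NA}`.
#' @param sites data.frame with columns `chrom`, `pos` (1-based, as in VCF),
#'   `ref`, `alt`, and optionally `ancestral` (one of `"ref"`, `"alt"`,
#'   `"unknown"`).
#' @param sample_ids character vector of sample identifiers (defaults to the
#'   rownames of `dosages`).
#' @return An object of class `geno_matrix` with elements `dosages`, `sites`
#'   (including a `missing_frac` column), and `sample_ids`.
#' @export
geno_matrix <- function(dosages, sites, sample_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(sample_ids)) {
    sample_ids <- paste0("sample", seq_len(nrow(dosages)))
  }
  stopifnot(
    nrow(dosages) == length(sample_ids),
    ncol(dosages) == nrow(sites),
    all(c("chrom", "pos", "ref", "alt") %in% names(sites))
  )
  bad <- !(dosages %in% c(0L, 1L, 2L) | is.na(dosages))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  sites$pos <- as.integer(sites$pos)
  if (is.null(sites$ancestral)) sites$ancestral <- "unknown"
  if (!all(sites$ancestral %in% c("ref", "alt", "unknown"))) {
    stop("ancestral must be 'ref', 'alt' or 'unknown'")
  }
  ord <- order(sites$chrom, sites$pos)
  if (is.unsorted(ord)) {
    sites <- sites[ord, , drop = FALSE]
    dosages <- dosages[, ord, drop = FALSE]
  }
  dup <- unlist(tapply(sites$pos, sites$chrom, function(p) c(FALSE, diff(p) <= 0)))
  if (any(dup)) stop("site positions must be strictly increasing within chromosomes")
  sites$missing_frac <- colMeans(is.na(dosages))
  rownames(sites) <- NULL
  dimnames(dosages) <- list(sample_ids, NULL)
  structure(
    list(dosages = dosages, sites = sites, sample_ids = sample_ids),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "geno_matrix: %d samples x %d sites on %d chromosome(s)\n",
    length(x$sample_ids), nrow(x$sites), length(unique(x$sites$chrom))
  ))
  invisible(x)
}

#' Number of samples / sites in a genotype matrix
#' @param gm a [geno_matrix()].
#' @return integer count.
#' @export
n_samples <- function(gm) length(gm$sample_ids)

#' @rdname n_samples
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' Subset a genotype matrix by site or sample index
#' @param gm a [geno_matrix()].
#' @param sites integer or logical index over sites.
#' @param samples integer, logical or character index over samples.
#' @return a new `geno_matrix`.
#' @export
subset_geno <- function(gm, sites = NULL, samples = NULL) {
  d <- gm$dosages
  s <- gm$sites
  ids <- gm$sample_ids
  if (!is.null(sites)) {
    d <- d[, sites, drop = FALSE]
    s <- s[sites, , drop = FALSE]
  }
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, ids)
    d <- d[samples, , drop = FALSE]
    ids <- ids[samples]
  }
  geno_matrix(d, s, ids)
}

#' Per-site ALT allele frequency
#' @param gm a [geno_matrix()].
#' @return numeric vector over sites, computed from non-missing genotypes.
#' @export
alt_freq <- function(gm) colMeans(gm$dosages, na.rm = TRUE) / 2

#' Per-site minor allele frequency
#' @param gm a [geno_matrix()].
#' @return numeric vector over sites.
#' @export
site_maf <- function(gm) {
  p <- alt_freq(gm)
  pmin(p, 1 - p)
}

# Mean-impute missing dosages and center columns. Used only inside
# PCA/covariance computations; frequency statistics always use the raw calls.
.center_impute <- function(d, scale = FALSE) {
  mu <- colMeans(d, na.rm = TRUE)
  na <- which(is.na(d))
  if (length(na)) d[na] <- mu[(na - 1L) %/% nrow(d) + 1L]
  d <- sweep(d, 2L, mu)
  if (scale) {
    p <- mu / 2
    s <- sqrt(pmax(p * (1 - p), .Machine$double.eps))
    d <- sweep(d, 2L, s, "/")
  }
  d
}

#' Which sites fall inside a set of genomic intervals
#'
#' Intervals use 0-based half-open coordinates (`start`, `end`); site
#' positions are 1-based as in VCF, so site `pos` is inside `[start, end)`
#' when `pos - 1 >= start` and `pos - 1 < end`.
#'
#' @param gm a [geno_matrix()].
#' @param intervals data.frame with columns `chrom`, `start`, `end` (or NULL).
#' @return logical vector over sites.
#' @export
sites_in_intervals <- function(gm, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) {
    return(rep(FALSE, n_sites(gm)))
  }
  q <- GenomicRanges::GRanges(
    gm$sites$chrom,
    IRanges::IRanges(start = gm$sites$pos, width = 1L)
  )
  s <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
  )
  IRanges::overlapsAny(q, s)
}
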