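#' Read a VCF into a genotype matrix
#'
#' Parses a VCF 4.x file with GT fields, keeps biallelic SNPs only
#' (multi-allelic sites are dropped, not split), applies minor-allele
#' frequency and per-site missingness filters, and resolves ancestral-allele
#' polarity. Resolution order: `ancestral` sidecar table, then the configured
#' INFO tag, then `"unknown"`.
#'
#' @param vcf_path path to a VCF file.
#' @param min_maf minimum minor allele frequency (computed from non-missing
#'   genotypes); default 0.05.
#' @param max_missing maximum per-site fraction of missing genotypes; default
#'   0.25 (sites callable in >75% of samples are kept).
#' @param ancestral optional data.frame with columns `chrom`, `pos`, `allele`
#'   giving the ancestral base per site.
#' @param anc_tag optional name of an INFO tag (e.g. `"AA"`) holding the
#'   ancestral base.
#' @return a [geno_matrix()].
#' @export
read_genotypes <- function(vcf_path, min_maf = 0.05, max_missing = 0.25,
                           ancestral = NULL, anc_tag = NULL) {
  v <- tryCatch(
    vcfR::read.vcfR(vcf_path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", vcf_path, "': ", conditionMessage(e))
  )
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  bases <- c("A", "C", "G", "T")
  snp <- fix$REF %in% bases & fix$ALT %in% bases
  if (!any(snp)) stop("no biallelic SNPs in VCF '", vcf_path, "'")
  v <- v[snp, ]
  fix <- fix[snp, , drop = FALSE]

  gt <- vcfR::extract.gt(v, element = "GT")
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  dos <- (a1 == "1") + (a2 == "1")
  dos[a1 == "." | a2 == "." | is.na(gt)] <- NA
  dos <- t(dos) # samples x sites

  sites <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    ancestral = "unknown", stringsAsFactors = FALSE
  )

  anc_base <- rep(NA_character_, nrow(sites))
  if (!is.null(anc_tag)) {
    info <- vcfR::extract.info(v, element = anc_tag)
    anc_base <- ifelse(is.na(info), anc_base, toupper(info))
  }
  if (!is.null(ancestral)) {
    key <- paste(sites$chrom, sites$pos)
    m <- match(key, paste(ancestral$chrom, ancestral$pos))
    hit <- !is.na(m)
    anc_base[hit] <- toupper(ancestral$allele[m[hit]])
  }
  sites$ancestral <- ifelse(
    is.na(anc_base), "unknown",
    ifelse(anc_base == sites$ref, "ref",
      ifelse(anc_base == sites$alt, "alt", "unknown")
    )
  )

  miss <- colMeans(is.na(dos))
  p <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- miss <= max_missing & !is.na(maf) & maf >= min_maf
  if (!any(keep)) stop("no sites survive MAF/missingness filters in '", vcf_path, "'")
  geno_matrix(dos[, keep, drop = FALSE], sites[keep, , drop = FALSE],
    sample_ids = colnames(gt)
  )
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits an uncompressed VCF 4.2 file with GT genotypes and, where polarity
#' is known, an `AA` INFO tag carrying the ancestral base. Round-trips
#' through [read_genotypes()] preserve genotypes for retained sites.
#'
#' @param gm a [geno_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(gm, path) {
  s <- gm$sites
  gt_codes <- c("0/0", "0/1", "1/1")
  d <- gm$dosages
  gt <- matrix("./.", nrow(d), ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gt_codes[d[ok] + 1L]
  anc <- ifelse(s$ancestral == "ref", s$ref,
    ifelse(s$ancestral == "alt", s$alt, NA)
  )
  info <- ifelse(is.na(anc), ".", paste0("AA=", anc))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", gm$sample_ids
    ), collapse = "\t")
  ), con)
  body <- cbind(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS", info, "GT", t(gt))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Tile chromosomes into nonoverlapping windows
#'
#' Produces half-open `[start, end)` windows of a fixed physical width that
#' tile each contig exactly; the last window is truncated at the contig end.
#'
#' @param contig_lengths named numeric vector of contig lengths (bp).
#' @param width window width in bp (e.g. 1e5 for haploblock discovery,
#'   1e4 for genome scans).
#' @return data.frame with columns `chrom`, `start`, `end`, `window_id`.
#' @export
tile_windows <- function(contig_lengths, width) {
  stopifnot(width > 0, !is.null(names(contig_lengths)))
  out <- lapply(names(contig_lengths), function(chrom) {
    len <- contig_lengths[[chrom]]
    if (len <= 0) {
      return(NULL)
    }
    start <- seq(0, len - 1, by = width)
    data.frame(
      chrom = chrom, start = start, end = pmin(start + width, len),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(
      chrom = character(), start = numeric(), end = numeric(),
      window_id = character(), stringsAsFactors = FALSE
    ))
  }
  out$window_id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  out
}

#' Sample background SNPs outside genes and haploblocks
#'
#' Uniform sampling without replacement from sites located outside annotated
#' genes and called haploblocks, as used for the empirical cline null and
#' the Omega covariance matrix.
#'
#' @param gm a [geno_matrix()].
#' @param annotations list with optional elements `genes` and `haploblocks`,
#'   each a data.frame of 0-based half-open intervals (`chrom`, `start`,
#'   `end`).
#' @param k number of sites to draw.
#' @param seed integer seed for reproducibility.
#' @return integer vector of site indices into `gm`.
#' @export
sample_background_snps <- function(gm, annotations, k, seed = 1L) {
  excl <- sites_in_intervals(gm, annotations$genes) |
    sites_in_intervals(gm, annotations$haploblocks)
  eligible <- which(!excl)
  if (k > length(eligible)) {
    stop(
      "requested ", k, " background SNPs but only ", length(eligible),
      " sites lie outside genes and haploblocks"
    )
  }
  set.seed(seed)
  sort(sample(eligible, k))
}

#' Write haploblock calls as BED plus per-sample genotypes
#'
#' Writes a 0-based half-open BED file (one record per haploblock, sorted by
#' chromosome and start) and a companion TSV of per-sample arrangement
#' genotypes at `paste0(path, ".genotypes.tsv")`.
#'
#' @param calls list of haploblock calls from [call_haploblocks()], or a
#'   data.frame of intervals with columns `chrom`, `start`, `end` (and
#'   optionally `name`).
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_haploblocks_bed <- function(calls, path) {
  if (is.data.frame(calls)) {
    iv <- calls
    geno <- NULL
  } else {
    if (length(calls) == 0) stop("no haploblock calls to write")
    iv <- do.call(rbind, lapply(calls, function(cl) {
      data.frame(
        chrom = cl$region$chrom, start = cl$region$start,
        end = cl$region$end, stringsAsFactors = FALSE
      )
    }))
    geno <- do.call(cbind, lapply(calls, function(cl) cl$genotype))
  }
  ord <- order(iv$chrom, iv$start)
  iv <- iv[ord, , drop = FALSE]
  if (!is.null(geno)) geno <- geno[, ord, drop = FALSE]
  if (is.null(iv$name)) {
    idx <- stats::ave(seq_len(nrow(iv)), iv$chrom, FUN = seq_along)
    iv$name <- paste0("hb-", iv$chrom, letters[idx])
  }
  bed <- iv[, c("chrom", "start", "end", "name")]
  bed$start <- trimws(format(bed$start, scientific = FALSE, trim = TRUE))
  bed$end <- trimws(format(bed$end, scientific = FALSE, trim = TRUE))
  utils::write.table(
    bed, path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  if (!is.null(geno)) {
    colnames(geno) <- iv$name
    g <- data.frame(
      sample = rownames(geno) %||% paste0("sample", seq_len(nrow(geno))),
      geno,
      check.names = FALSE, stringsAsFactors = FALSE
    )
    utils::write.table(g, paste0(path, ".genotypes.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(path)
}

#' Read a haploblock BED file
#' @param path BED path as written by [write_haploblocks_bed()].
#' @return data.frame with columns `chrom`, `start`, `end`, `name`.
#' @export
read_haploblocks_bed <- function(path) {
  b <- utils::read.table(path,
    sep = "\t", header = FALSE,
    stringsAsFactors = FALSE
  )
  names(b)[1:3] <- c("chrom", "start", "end")
  if (ncol(b) >= 4) names(b)[4] <- "name" else b$name <- NA_character_
  b[, c("chrom", "start", "end", "name")]
}

#' Read a sample metadata table
#'
#' TSV with columns `sample`, `population`, `range`, `latitude`, `longitude`,
#' followed by optional named phenotype/environment columns.
#'
#' @param path TSV path.
#' @param gm optional [geno_matrix()]; if given, checks that every genotyped
#'   sample is present exactly once.
#' @param min_n populations with fewer samples than this are flagged in the
#'   `small_pop` column (default 3, i.e. populations with n > 2 are unflagged).
#' @return data.frame of sample metadata.
#' @export
read_samples <- function(path, gm = NULL, min_n = 3L) {
  s <- utils::read.table(path,
    sep = "\t", header = TRUE,
    stringsAsFactors = FALSE
  )
  req <- c("sample", "population", "range", "latitude", "longitude")
  if (!all(req %in% names(s))) {
    stop("sample table must have columns: ", paste(req, collapse = ", "))
  }
  if (!all(is.finite(s$latitude))) stop("latitude must be finite")
  if (anyDuplicated(s$sample)) stop("duplicated sample ids in sample table")
  if (!is.null(gm) && !all(gm$sample_ids %in% s$sample)) {
    stop("sample table is missing genotyped samples")
  }
  tab <- table(s$population)
  s$small_pop <- as.vector(tab[s$population] < min_n)
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
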