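#' Classify a codon position by degeneracy
#'
#' Substitutes each of the three alternative bases at the given codon
#' position and translates under the standard genetic code: the site is
#' zero-fold degenerate if every substitution changes the amino acid
#' (substitutions creating or destroying a stop codon count as changes),
#' four-fold degenerate if none does, and `"other"` otherwise. Codons
#' containing ambiguous bases classify as `"ambiguous"`.
#'
#' @param codon 3-letter codon string (in transcript orientation).
#' @param codon_pos position within the codon, 1, 2 or 3.
#' @return one of `"zerofold"`, `"fourfold"`, `"other"`, `"ambiguous"`.
#' @export
classify_site <- function(codon, codon_pos) {
  stopifnot(codon_pos %in% 1:3, nchar(codon) == 3)
  codon <- toupper(codon)
  bases <- c("A", "C", "G", "T")
  if (!all(strsplit(codon, "")[[1]] %in% bases)) {
    return("ambiguous")
  }
  aa0 <- Biostrings::GENETIC_CODE[[codon]]
  ref_base <- substr(codon, codon_pos, codon_pos)
  changed <- vapply(setdiff(bases, ref_base), function(b) {
    alt <- codon
    substr(alt, codon_pos, codon_pos) <- b
    Biostrings::GENETIC_CODE[[alt]] != aa0
  }, logical(1))
  if (all(changed)) "zerofold" else if (!any(changed)) "fourfold" else "other"
}

#' @rdname classify_site
#' @param codons character vector of codons.
#' @param codon_positions integer vector of positions (recycled).
#' @export
classify_sites <- function(codons, codon_positions) {
  n <- max(length(codons), length(codon_positions))
  codons <- rep_len(codons, n)
  codon_positions <- rep_len(codon_positions, n)
  key <- paste(codons, codon_positions)
  u <- !duplicated(key)
  cls <- vapply(
    which(u),
    function(i) classify_site(codons[i], codon_positions[i]), ""
  )
  unname(cls[match(key, key[u])])
}

#' Build a per-site degeneracy map from FASTA + GFF3
#'
#' Resolves CDS features to in-frame codons using strand and phase, maps
#' codon positions back through the exon structure to genomic coordinates,
#' and classifies each CDS site. Transcripts whose CDS length is not a
#' multiple of 3 after phase adjustment are skipped with a warning; sites
#' with conflicting classifications across overlapping transcripts are
#' `"ambiguous"`.
#'
#' @param fasta path to a FASTA file, or a named character vector of contig
#'   sequences.
#' @param gff path to a GFF3 file with CDS features carrying `Parent` and
#'   `phase`.
#' @return data.frame with columns `chrom`, `pos` (1-based), `class`,
#'   `transcript`.
#' @export
build_degeneracy_map <- function(fasta, gff) {
  if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta)) {
    seqs <- Biostrings::readDNAStringSet(fasta)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    seqs <- vapply(as.character(seqs), identity, "")
  } else {
    seqs <- fasta
  }
  g <- rtracklayer::import(gff)
  cds <- g[g$type == "CDS"]
  if (length(cds) == 0) stop("no CDS features in ", gff)
  parent <- vapply(as.list(cds$Parent), function(p) p[1] %||% NA_character_, "")
  out <- list()
  for (tx in unique(parent)) {
    seg <- cds[parent == tx]
    strand <- as.character(GenomicRanges::strand(seg))[1]
    st <- GenomicRanges::start(seg)
    en <- GenomicRanges::end(seg)
    chrom <- as.character(GenomicRanges::seqnames(seg))[1]
    ord <- if (strand == "-") order(-st) else order(st)
    st <- st[ord]
    en <- en[ord]
    ph <- seg$phase[ord][1]
    if (is.na(ph)) ph <- 0L
    # genomic positions in translation order
    pos <- unlist(lapply(seq_along(st), function(i) {
      p <- st[i]:en[i]
      if (strand == "-") rev(p) else p
    }))
    if (ph > 0) pos <- pos[-seq_len(ph)]
    if (length(pos) %% 3 != 0) {
      warning("CDS of ", tx, " is not a multiple of 3 after phase; skipped")
      next
    }
    base <- substring(seqs[[chrom]], pos, pos)
    if (strand == "-") base <- chartr("ACGT", "TGCA", toupper(base))
    idx <- seq_along(pos)
    codon_idx <- (idx - 1L) %/% 3L + 1L
    codon <- vapply(
      split(base, codon_idx),
      paste,
      collapse = "", FUN.VALUE = ""
    )[as.character(codon_idx)]
    codon_pos <- (idx - 1L) %% 3L + 1L
    out[[tx]] <- data.frame(
      chrom = chrom, pos = pos,
      class = classify_sites(codon, codon_pos),
      transcript = tx, stringsAsFactors = FALSE
    )
  }
  map <- do.call(rbind, out)
  rownames(map) <- NULL
  key <- paste(map$chrom, map$pos)
  conflicting <- vapply(
    split(map$class, key),
    function(cl) length(unique(cl)) > 1, logical(1)
  )
  if (any(conflicting)) {
    map$class[key %in% names(conflicting)[conflicting]] <- "ambiguous"
  }
  map[order(map$chrom, map$pos), ]
}

#' Mean derived allele frequency per group and degeneracy class
#'
#' For each group, downsamples to `n_down` individuals (so groups are
#' compared at equal sample size), computes the per-site derived allele
#' frequency among non-missing genotypes at polarized zero-fold and
#' four-fold sites, and averages across sites within each class. The mean at
#' zero-fold sites is the genetic-load proxy.
#'
#' @param gm a [geno_matrix()]; sites with `ancestral == "unknown"` are
#'   excluded.
#' @param degeneracy_map data.frame from [build_degeneracy_map()].
#' @param groups named list mapping group labels to sample id vectors.
#' @param n_down number of individuals retained per group (defaults to the
#'   smallest group size).
#' @param seed integer seed for the downsampling.
#' @return data.frame with one row per group x class (`group`, `class`,
#'   `mean_derived_freq`, `n_sites`, `n_down`); the attribute
#'   `"site_freqs"` holds the per-site frequency vectors used by
#'   [bootstrap_load()].
#' @export
derived_frequency_load <- function(gm, degeneracy_map, groups,
                                   n_down = NULL, seed = 1L) {
  if (is.null(n_down)) n_down <- min(lengths(groups))
  small <- lengths(groups) < n_down
  if (any(small)) {
    stop(
      "groups smaller than n_down = ", n_down, ": ",
      paste(names(groups)[small], collapse = ", ")
    )
  }
  key <- paste(gm$sites$chrom, gm$sites$pos)
  m <- match(key, paste(degeneracy_map$chrom, degeneracy_map$pos))
  cls <- degeneracy_map$class[m]
  use <- !is.na(cls) & cls %in% c("zerofold", "fourfold") &
    gm$sites$ancestral != "unknown"
  if (!any(use)) stop("no polarized zero-fold/four-fold sites in genotype matrix")
  cls <- cls[use]
  d <- gm$dosages[, use, drop = FALSE]
  # derived dosage: flip when ALT is ancestral
  flip <- gm$sites$ancestral[use] == "alt"
  set.seed(seed)
  res <- list()
  site_freqs <- list()
  for (grp in names(groups)) {
    ids <- sample(groups[[grp]], n_down)
    dg <- d[match(ids, gm$sample_ids), , drop = FALSE]
    f <- colMeans(dg, na.rm = TRUE) / 2
    f[flip] <- 1 - f[flip]
    for (cl in c("zerofold", "fourfold")) {
      fv <- f[cls == cl & !is.nan(f)]
      res[[paste(grp, cl)]] <- data.frame(
        group = grp, class = cl, mean_derived_freq = mean(fv),
        n_sites = length(fv), n_down = n_down, stringsAsFactors = FALSE
      )
      site_freqs[[paste(grp, cl, sep = ".")]] <- fv
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "site_freqs") <- site_freqs
  out
}

#' Site-subsampling bootstrap confidence interval for a load mean
#'
#' Each replicate draws `ceiling(fraction * S)` of the `S` site-level
#' frequencies without replacement and recomputes the mean; the CI is the
#' 2.5%/97.5% quantile band of replicate means. This mirrors a
#' subsample-of-sites bootstrap (20% of sites, 100 replicates); a classical
#' full-size resample with replacement is available via
#' `classical = TRUE`.
#'
#' @param site_freqs numeric vector of per-site derived frequencies.
#' @param fraction fraction of sites per replicate (default 0.2).
#' @param reps number of replicates (default 100).
#' @param seed integer seed.
#' @param classical logical; if TRUE, resample S sites with replacement
#'   instead.
#' @return list with `lower`, `upper`, `mean`, and the replicate `means`.
#' @export
bootstrap_load <- function(site_freqs, fraction = 0.2, reps = 100L,
                           seed = 1L, classical = FALSE) {
  S <- length(site_freqs)
  stopifnot(S >= 10)
  set.seed(seed)
  means <- vapply(seq_len(reps), function(r) {
    if (classical) {
      mean(site_freqs[sample.int(S, S, replace = TRUE)])
    } else {
      mean(site_freqs[sample.int(S, ceiling(fraction * S))])
    }
  }, numeric(1))
  ci <- stats::quantile(means, c(0.025, 0.975), names = FALSE)
  list(lower = ci[1], upper = ci[2], mean = mean(site_freqs), means = means)
}

#' Per-group load estimates with bootstrap CIs
#'
#' Convenience wrapper combining [derived_frequency_load()] and
#' [bootstrap_load()].
#'
#' @inheritParams derived_frequency_load
#' @inheritParams bootstrap_load
#' @return data.frame with columns `group`, `class`, `mean_derived_freq`,
#'   `ci_lower`, `ci_upper`, `n_sites`, `n_down`.
#' @export
load_estimates <- function(gm, degeneracy_map, groups, n_down = NULL,
                           fraction = 0.2, reps = 100L, seed = 1L) {
  est <- derived_frequency_load(gm, degeneracy_map, groups,
    n_down = n_down, seed = seed
  )
  sf <- attr(est, "site_freqs")
  ci <- t(vapply(paste(est$group, est$class, sep = "."), function(k) {
    b <- bootstrap_load(sf[[k]], fraction = fraction, reps = reps, seed = seed)
    c(b$lower, b$upper)
  }, numeric(2)))
  est$ci_lower <- ci[, 1]
  est$ci_upper <- ci[, 2]
  attr(est, "site_freqs") <- sf
  est
}
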