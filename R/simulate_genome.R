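#' Simulate a toy coding genome with known degeneracy
#'
#' Generates a small coding contig (`chrC`) carrying random intact CDS
#' sequences (ATG start, no internal stops, TAA stop), writesable as
#' FASTA/GFF3, together with the true per-site degeneracy classification
#' obtained directly from the codons the generator laid down. The gene set
#' always includes minus-strand genes and multi-exon genes whose second CDS
#' segment has nonzero phase, so coordinate arithmetic through strand and
#' phase is exercised.
#'
#' @param cfg a [sim_config()] (uses `cfg$genes`).
#' @param seed integer seed.
#' @return list with `seqs` (named character vector of contig sequences),
#'   `gff` (data.frame in GFF3 column layout), `degeneracy` (truth
#'   data.frame: `chrom`, `pos`, `class`, `transcript`), and `genes`
#'   (gene span intervals, 0-based half-open).
#' @export
simulate_coding_genome <- function(cfg, seed = cfg$seed + 3L) {
  set.seed(seed)
  gs <- cfg$genes
  n_genes <- gs$n_genes
  cds_len <- gs$cds_len
  stopifnot(cds_len %% 3 == 0, cds_len >= 9)

  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  stops <- c("TAA", "TAG", "TGA")
  internal <- setdiff(codons, stops)

  flank <- 300L
  intron <- 100L
  seq_parts <- character(0)
  cursor <- 0L # 0-based length so far
  gff <- list()
  truth <- list()
  gene_iv <- list()

  rand_seq <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")

  for (i in seq_len(n_genes)) {
    strand <- if (i %% 2 == 0) "-" else "+"
    multi <- i %% 3 == 0
    cds <- paste0(
      "ATG",
      paste(sample(internal, cds_len / 3 - 2, replace = TRUE), collapse = ""),
      "TAA"
    )
    # split point chosen off the codon grid so the second segment has phase
    L1 <- if (multi) (cds_len %/% 2) + 1L else cds_len
    L2 <- cds_len - L1
    gene_id <- sprintf("gene%02d", i)
    tx_id <- paste0(gene_id, ".t1")

    seq_parts <- c(seq_parts, rand_seq(flank))
    cursor <- cursor + flank
    gstart <- cursor # 0-based start of the first CDS segment on the contig

    ex1 <- substr(cds, 1L, L1)
    ex2 <- if (multi) substr(cds, L1 + 1L, cds_len) else ""
    body_tx <- if (multi) paste0(ex1, rand_seq(intron), ex2) else ex1
    body_len <- nchar(body_tx)
    if (strand == "+") {
      body_genomic <- body_tx
      # genomic positions (1-based) of CDS bases in translation order
      pos1 <- gstart + seq_len(L1)
      pos2 <- if (multi) gstart + L1 + intron + seq_len(L2) else integer(0)
      tpos <- c(pos1, pos2)
      seg <- rbind(
        c(gstart + 1L, gstart + L1, 0L),
        if (multi) c(gstart + L1 + intron + 1L, gstart + body_len, (3L - L1 %% 3L) %% 3L)
      )
    } else {
      body_genomic <- .revcomp(body_tx)
      # 5' CDS end sits at the high-coordinate end of the segment
      gend <- gstart + body_len
      tpos <- gend - seq_len(cds_len) + 1L
      if (multi) tpos <- c(gend - seq_len(L1) + 1L, gend - L1 - intron - seq_len(L2) + 1L)
      seg <- rbind(
        c(gend - L1 + 1L, gend, 0L),
        if (multi) c(gstart + 1L, gstart + L2, (3L - L1 %% 3L) %% 3L)
      )
    }
    seq_parts <- c(seq_parts, body_genomic)
    cursor <- cursor + body_len

    codon_idx <- (seq_len(cds_len) - 1L) %/% 3L + 1L
    codon_pos <- (seq_len(cds_len) - 1L) %% 3L + 1L
    codon_seq <- substring(cds, (codon_idx - 1L) * 3L + 1L, codon_idx * 3L)
    truth[[i]] <- data.frame(
      chrom = "chrC", pos = as.integer(tpos),
      class = classify_sites(codon_seq, codon_pos),
      transcript = tx_id, stringsAsFactors = FALSE
    )
    gene_iv[[i]] <- data.frame(
      chrom = "chrC", start = gstart, end = cursor, name = gene_id,
      stringsAsFactors = FALSE
    )
    gff[[i]] <- rbind(
      data.frame(
        seqid = "chrC", source = "haploscan", type = c("gene", "mRNA"),
        start = gstart + 1L, end = cursor, score = ".", strand = strand,
        phase = ".",
        attributes = c(
          paste0("ID=", gene_id),
          paste0("ID=", tx_id, ";Parent=", gene_id)
        ),
        stringsAsFactors = FALSE
      ),
      data.frame(
        seqid = "chrC", source = "haploscan", type = "CDS",
        start = seg[, 1], end = seg[, 2], score = ".", strand = strand,
        phase = as.character(seg[, 3]),
        attributes = paste0("ID=", tx_id, ".cds;Parent=", tx_id),
        stringsAsFactors = FALSE
      )
    )
  }
  seq_parts <- c(seq_parts, rand_seq(flank))
  genome <- paste(seq_parts, collapse = "")
  list(
    seqs = c(chrC = genome),
    gff = do.call(rbind, gff),
    degeneracy = do.call(rbind, truth),
    genes = do.call(rbind, gene_iv)
  )
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Simulate coding-site SNPs with purifying selection at zero-fold sites
#'
#' Draws SNPs at known zero-fold and four-fold degenerate positions of a
#' simulated coding genome. The ancestral allele is the reference base;
#' derived allele frequencies are `Beta(0.5, 2)` (mean 0.2) at four-fold
#' sites and the same draw multiplied by `zerofold_downweight` at zero-fold
#' sites, emulating purifying selection against nonsynonymous variants.
#' Dosages are `Binomial(2, f)`, independent across individuals.
#'
#' @param cfg a [sim_config()].
#' @param coding result of [simulate_coding_genome()].
#' @param seed integer seed.
#' @return a [geno_matrix()] on `chrC` with `ancestral = "ref"` everywhere;
#'   attribute `"derived_freq"` records the true derived frequencies.
#' @export
simulate_coding_snps <- function(cfg, coding, seed = cfg$seed + 4L) {
  set.seed(seed)
  deg <- coding$degeneracy
  n_snps <- cfg$genes$n_coding_snps
  n_each <- n_snps %/% 2
  z <- deg[deg$class == "zerofold", ]
  f4 <- deg[deg$class == "fourfold", ]
  stopifnot(nrow(z) >= n_each, nrow(f4) >= n_each)
  pick <- rbind(
    z[sample.int(nrow(z), n_each), c("chrom", "pos", "class")],
    f4[sample.int(nrow(f4), n_each), c("chrom", "pos", "class")]
  )
  f <- stats::rbeta(nrow(pick), 0.5, 2)
  f[pick$class == "zerofold"] <- f[pick$class == "zerofold"] *
    cfg$genes$zerofold_downweight

  n <- cfg$n_pops * cfg$n_per_pop
  dos <- matrix(stats::rbinom(n * nrow(pick), 2L, rep(f, each = n)), nrow = n)
  ref <- substring(coding$seqs[["chrC"]], pick$pos, pick$pos)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
  ord <- order(pick$pos)
  gm <- geno_matrix(
    dos[, ord, drop = FALSE],
    data.frame(
      chrom = "chrC", pos = pick$pos[ord], ref = ref[ord],
      alt = unname(alt)[ord], ancestral = "ref", stringsAsFactors = FALSE
    ),
    sample_ids = .sim_samples(cfg)$sample
  )
  attr(gm, "derived_freq") <- f[ord]
  gm
}

#' Simulate a complete synthetic dataset
#'
#' Orchestrates the neutral background, planted haploblocks, phenotypes, and
#' the coding contig into one genotype matrix, sample table and truth set.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed overriding `cfg$seed`.
#' @param coding logical; simulate the coding contig and coding SNPs
#'   (default TRUE).
#' @return list of class `haploscan_sim` with elements `gm`, `samples`,
#'   `phenotypes`, `annotations` (gene and haploblock intervals for
#'   background-SNP sampling), `genome` (`seqs`, `gff`) and `truth`
#'   (haploblock intervals, per-sample arrangement dosages, per-population
#'   arrangement frequencies, cline coefficients, degeneracy map, trait
#'   effects).
#' @export
simulate_dataset <- function(cfg = sim_config(), seed = cfg$seed, coding = TRUE) {
  cfg$seed <- seed
  gm <- simulate_neutral_background(cfg, seed = seed)
  samples <- .sim_samples(cfg)

  hb_iv <- NULL
  arr <- NULL
  pop_freqs <- NULL
  clines <- NULL
  parts_d <- list(gm$dosages)
  parts_s <- list(gm$sites)
  if (length(cfg$haploblocks)) {
    hb_iv <- do.call(rbind, lapply(seq_along(cfg$haploblocks), function(i) {
      h <- cfg$haploblocks[[i]]
      data.frame(
        chrom = h$chrom, start = h$start, end = h$end,
        name = sprintf("hb%d", i), stringsAsFactors = FALSE
      )
    }))
    sims <- lapply(seq_along(cfg$haploblocks), function(i) {
      simulate_haploblock(cfg, cfg$haploblocks[[i]], seed = seed + 1000L * i)
    })
    arr <- do.call(cbind, lapply(sims, `[[`, "arrangement"))
    colnames(arr) <- hb_iv$name
    pop_freqs <- do.call(rbind, lapply(sims, `[[`, "pop_freqs"))
    rownames(pop_freqs) <- hb_iv$name
    clines <- do.call(rbind, lapply(sims, `[[`, "cline"))
    rownames(clines) <- hb_iv$name
    for (s in sims) {
      parts_d <- c(parts_d, list(s$markers))
      parts_s <- c(parts_s, list(s$sites))
    }
  }

  genome <- NULL
  deg <- NULL
  gene_iv <- NULL
  if (coding) {
    genome <- simulate_coding_genome(cfg, seed = seed + 7L)
    cgm <- simulate_coding_snps(cfg, genome, seed = seed + 8L)
    deg <- genome$degeneracy
    gene_iv <- genome$genes
    parts_d <- c(parts_d, list(cgm$dosages))
    parts_s <- c(parts_s, list(cgm$sites))
  }

  cols <- c("chrom", "pos", "ref", "alt", "ancestral")
  all_s <- do.call(rbind, lapply(parts_s, function(s) s[, cols]))
  all_d <- do.call(cbind, parts_d)
  dup <- duplicated(paste(all_s$chrom, all_s$pos))
  if (any(dup)) { # neutral site landed on a marker position: keep the marker
    first_dup <- duplicated(paste(all_s$chrom, all_s$pos), fromLast = TRUE)
    drop <- first_dup & !dup
    all_s <- all_s[!drop, , drop = FALSE]
    all_d <- all_d[, !drop, drop = FALSE]
  }
  full <- geno_matrix(all_d, all_s, sample_ids = samples$sample)

  tr <- NULL
  if (length(cfg$traits)) {
    tr <- simulate_traits(cfg, arr, gm, seed = seed + 9L)
    samples <- cbind(samples, tr$phenotypes)
  }

  structure(
    list(
      gm = full, samples = samples,
      phenotypes = if (is.null(tr)) NULL else tr$phenotypes,
      annotations = list(genes = gene_iv, haploblocks = hb_iv),
      genome = genome,
      truth = list(
        haploblocks = hb_iv, arrangements = arr, pop_freqs = pop_freqs,
        clines = clines, degeneracy = deg,
        traits = if (is.null(tr)) NULL else tr$truth
      ),
      config = cfg
    ),
    class = "haploscan_sim"
  )
}

#' Write a simulated dataset to disk
#'
#' Emits `genotypes.vcf`, `samples.tsv`, `reference.fa` (the coding contig),
#' `genes.gff3`, and `truth.json` under `dir`.
#'
#' @param sim a `haploscan_sim` from [simulate_dataset()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes_vcf(sim$gm, file.path(dir, "genotypes.vcf"))
  utils::write.table(sim$samples, file.path(dir, "samples.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  if (!is.null(sim$genome)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(sim$genome$seqs),
      file.path(dir, "reference.fa")
    )
    write_gff3(sim$genome$gff, file.path(dir, "genes.gff3"))
  }
  truth <- sim$truth
  truth$arrangements <- as.data.frame(truth$arrangements)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
    dataframe = "columns", digits = NA, auto_unbox = TRUE
  )
  invisible(dir)
}

#' Write a GFF3 table
#' @param gff data.frame in 9-column GFF3 layout (as produced by
#'   [simulate_coding_genome()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(gff, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  lines <- do.call(paste, c(
    lapply(gff[, c(
      "seqid", "source", "type", "start", "end", "score",
      "strand", "phase", "attributes"
    )], function(x) trimws(format(x, scientific = FALSE, trim = TRUE))),
    sep = "\t"
  ))
  writeLines(lines, con)
  invisible(path)
}
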