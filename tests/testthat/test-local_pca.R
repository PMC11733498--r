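test_that("window covariance equals the direct per-site formula", {
  dos <- matrix(c(
    0, 1, 2,
    1, 1, 0,
    2, 0, 1,
    0, 2, 2
  ), nrow = 4, byrow = TRUE)
  gm <- toy_gm(dos, pos = c(10L, 20L, 30L))
  w <- data.frame(chrom = "chr1", start = 0, end = 100)
  C <- window_covariance(gm, w, min_sites = 1)
  # brute-force oracle: sum over sites of centered outer products / n_sites
  xc <- sweep(dos, 2, colMeans(dos))
  oracle <- Reduce(`+`, lapply(1:3, function(s) outer(xc[, s], xc[, s]))) / 3
  expect_equal(unname(C), oracle, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(C), unname(t(C)), ignore_attr = TRUE)
  expect_equal(attr(C, "n_sites"), 3)

  # two identical samples give identical covariance rows
  dos2 <- rbind(dos, dos[1, ])
  gm2 <- toy_gm(dos2, pos = c(10L, 20L, 30L))
  C2 <- window_covariance(gm2, w, min_sites = 1)
  expect_equal(C2[1, ], C2[5, ])

  # monomorphic-after-filter windows are skipped
  gm3 <- toy_gm(matrix(2L, 4, 3), pos = c(10L, 20L, 30L))
  expect_null(window_covariance(gm3, w, min_sites = 1))
})

test_that("window distances match brute-force truncated-covariance norms", {
  set.seed(21)
  gms <- lapply(1:3, function(i) matrix(rbinom(80, 2, 0.5), nrow = 8))
  covs <- lapply(gms, function(x) {
    xc <- sweep(x, 2, colMeans(x))
    tcrossprod(xc) / ncol(x)
  })
  brute <- function(a, b, k) {
    tr <- function(C) {
      C <- C / sum(diag(C))
      e <- eigen(C, symmetric = TRUE)
      e$vectors[, 1:k] %*% diag(e$values[1:k], k) %*% t(e$vectors[, 1:k])
    }
    sqrt(sum((tr(a) - tr(b))^2))
  }
  for (k in 1:2) {
    for (i in 1:3) {
      for (j in 1:3) {
        # the Gram-trick evaluation cancels catastrophically only at
        # distances near zero, hence the absolute floor
        expect_lt(
          abs(
            window_distance(covs[[i]], covs[[j]], k = k) -
              brute(covs[[i]], covs[[j]], k)
          ),
          1e-7
        )
      }
    }
  }
  expect_equal(window_distance(covs[[1]], covs[[1]]), 0, tolerance = 1e-10)
  expect_equal(
    window_distance(covs[[1]], covs[[2]]),
    window_distance(covs[[2]], covs[[1]])
  )
  expect_error(window_distance(covs[[1]], covs[[1]][1:4, 1:4]), "sample")
})

test_that("the pairwise distance matrix agrees with pairwise evaluation", {
  set.seed(22)
  dos <- matrix(rbinom(10 * 60, 2, 0.4), nrow = 10)
  gm <- toy_gm(dos, pos = seq_len(60) * 50L)
  w <- tile_windows(c(chr1 = 3000), 1000) # 3 windows x 20 SNPs
  lp <- local_pca_windows(gm, w, k = 2, min_sites = 5)
  covs <- lapply(seq_len(3), function(i) {
    window_covariance(gm, w[i, ], min_sites = 5)
  })
  for (i in 1:3) {
    for (j in 1:3) {
      expect_lt(
        abs(lp$dist[i, j] - window_distance(covs[[i]], covs[[j]], 2)),
        1e-7
      )
    }
  }
  # permuting sample order leaves distances invariant
  perm <- sample(10)
  lp_p <- local_pca_windows(subset_geno(gm, samples = perm), w, k = 2, min_sites = 5)
  expect_equal(lp_p$dist, lp$dist, tolerance = 1e-10)
})

test_that("classical MDS reproduces double-centering algebra and line order", {
  # 4x4 worked example: oracle diagonalizes B = -1/2 J D^2 J directly
  pts <- c(0, 1, 3, 7)
  D <- as.matrix(dist(pts))
  mds <- mds_embed(D, n_axes = 2)
  J <- diag(4) - matrix(1 / 4, 4, 4)
  B <- -0.5 * J %*% D^2 %*% J
  e <- eigen(B, symmetric = TRUE)
  oracle1 <- e$vectors[, 1] * sqrt(e$values[1])
  got <- unname(mds$coords[, 1])
  expect_equal(abs(got), abs(oracle1), tolerance = 1e-8)
  # axis 1 recovers the line order up to reflection
  expect_true(all(diff(order(got)) == 1) || all(diff(order(-got)) == 1))
  # exact line: embedding reproduces the original spacings
  expect_equal(as.matrix(dist(got)), as.matrix(dist(pts)),
    tolerance = 1e-8, ignore_attr = TRUE
  )

  # all-equal distances among 3 windows: equilateral, equal eigenvalues
  D3 <- matrix(1, 3, 3) - diag(3)
  m3 <- mds_embed(D3, n_axes = 2)
  expect_equal(m3$eig[1], m3$eig[2], tolerance = 1e-10)

  # degenerate all-zero distances flagged
  expect_warning(m0 <- mds_embed(matrix(0, 5, 5)), "degenerate")
  expect_true(m0$degenerate)

  # deterministic sign convention: largest-magnitude loading positive
  expect_gt(got[which.max(abs(got))], 0)
})

test_that("corner outliers are the diagonal-projection tails", {
  co <- matrix(0, 100, 5)
  co[7, 1] <- 10
  co[7, 2] <- 10
  rownames(co) <- sprintf("w%03d", 1:100)
  mds <- structure(list(coords = co, degenerate = FALSE), class = "mds_map")
  out <- corner_outliers(mds, tail = 0.05)
  hits <- out[out$axis_i == 1 & out$axis_j == 2 & out$corner == "++", ]
  expect_equal(hits$window_id, "w007")
  # the displaced window projects to zero on the off-diagonal: not "+-"
  expect_false("w007" %in% out$window_id[out$corner == "+-" &
    out$axis_i == 1 & out$axis_j == 2])
  # tail = 1 returns every window in every corner
  all_out <- corner_outliers(mds, tail = 1)
  expect_equal(sum(all_out$axis_i == 1 & all_out$axis_j == 2 & all_out$corner == "++"), 100)

  # symmetric cloud: each corner captures ~ the tail fraction
  set.seed(30)
  co2 <- matrix(rnorm(500 * 5), 500, 5)
  rownames(co2) <- sprintf("w%03d", 1:500)
  mds2 <- structure(list(coords = co2, degenerate = FALSE), class = "mds_map")
  out2 <- corner_outliers(mds2, tail = 0.05)
  per_corner <- table(paste(out2$axis_i, out2$axis_j, out2$corner))
  expect_equal(length(per_corner), 40) # 10 axis pairs x 4 directions
  expect_true(all(per_corner >= 10 & per_corner <= 40)) # ~25 of 500
})

test_that("outlier windows merge into candidate regions by run and gap", {
  w <- tile_windows(c(chr1 = 1e6), 1e5) # 10 windows
  mk <- function(widx) {
    data.frame(
      window_id = w$window_id[widx], axis_i = 1, axis_j = 2,
      corner = "++", projection = 1, stringsAsFactors = FALSE
    )
  }
  # consecutive windows 3,4,5 -> one region spanning them
  r1 <- merge_candidates(mk(3:5), w, max_gap = 0, min_windows = 3)
  expect_equal(nrow(r1), 1)
  expect_equal(r1$start, w$start[3])
  expect_equal(r1$end, w$end[5])
  # windows 3 and 7 with max_gap = 1 stay separate (and die to min_windows)
  r2 <- merge_candidates(mk(c(3, 7)), w, max_gap = 1, min_windows = 1)
  expect_equal(nrow(r2), 2)
  r3 <- merge_candidates(mk(c(3, 5, 7)), w, max_gap = 1, min_windows = 3)
  expect_equal(nrow(r3), 1) # gaps of one window are bridged
  expect_equal(nrow(merge_candidates(mk(c(3, 4)), w, max_gap = 1, min_windows = 3)), 0)
})

test_that("a planted haploblock is recovered as a candidate region", {
  cfg <- sim_config(
    n_pops = 6, n_per_pop = 10, latitudes = seq(10, 54, length.out = 6),
    n_chroms = 1, chrom_length = 10e6, n_neutral_snps = 5000,
    haploblocks = list(hb_spec(
      chrom = "chr1", start = 4e6, end = 5e6,
      n_markers = 800L
    )),
    seed = 23
  )
  sim <- simulate_dataset(cfg, coding = FALSE)
  fc <- find_candidate_regions(sim$gm,
    contig_lengths = c(chr1 = 10e6),
    min_sites = 10, tail = 0.1
  )
  tr <- sim$truth$haploblocks
  jac <- vapply(seq_len(nrow(fc$candidates)), function(i) {
    if (fc$candidates$chrom[i] != tr$chrom[1]) {
      return(0)
    }
    interval_jaccard(
      fc$candidates$start[i], fc$candidates$end[i],
      tr$start[1], tr$end[1]
    )
  }, numeric(1))
  expect_gte(max(jac), 0.8)
})
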