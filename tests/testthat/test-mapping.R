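test_that("bin grids tile chromosomes with a retained partial bin", {
  b <- makeBins(1250000, width = 500000)
  expect_equal(nrow(b), 3)
  expect_equal(b$bp_start[3], 1000001)
  expect_equal(b$bp_end[3], 1250000)
  b2 <- makeBins(2e6, width = 5e5)
  expect_true(all(b2$bp_end - b2$bp_start + 1 == 5e5))
  set.seed(91)
  for (i in 1:10) {
    L <- floor(runif(4, 1e6, 2.5e8))
    expect_equal(nrow(makeBins(L)), sum(ceiling(L / 5e5)))
  }
  expect_error(makeBins(1e6, width = 0), "positive")
})

test_that("carriage matrix marks any-overlap and matches brute force", {
  bins <- makeBins(c(5e6, 3e6))
  expect_true(all(rohBinMatrix(rohTable(), bins, c("a", "b")) == 0))
  # one ROH spanning 3 bins -> exactly three 1s in that row
  roh <- rohTable("a", 1L, 9e5, 1.6e6, 70L)
  m <- rohBinMatrix(roh, bins, c("a", "b"))
  expect_equal(sum(m["a", ]), 3)
  expect_equal(sum(m["b", ]), 0)
  # random ROHs: row sums equal brute-force interval intersection counts
  set.seed(92)
  chrom <- sample(1:2, 60, TRUE)
  L <- ifelse(chrom == 1, 5e6, 3e6)
  start <- floor(runif(60, 1, L - 2e5))
  rohs <- rohTable(sample(c("a", "b"), 60, TRUE), chrom, start,
                   pmin(start + floor(runif(60, 1e5, 2e6)), L),
                   rep(65L, 60))
  m2 <- rohBinMatrix(rohs, bins, c("a", "b"))
  for (s in c("a", "b")) {
    rs <- rohs[rohs$sample_id == s, ]
    brute <- sapply(seq_len(nrow(bins)), function(i)
      any(rs$chrom == bins$chrom[i] & rs$bp_start <= bins$bp_end[i] &
            rs$bp_end >= bins$bp_start[i]))
    expect_equal(unname(m2[s, ]), as.integer(brute))
  }
})

test_that("per-bin scan finds a planted risk bin and skips degenerate bins", {
  set.seed(93)
  n <- 600
  nb <- 40
  mat <- matrix(rbinom(n * nb, 1, 0.10), n, nb)
  mat[, 7] <- 0                                   # empty bin
  y <- rbinom(n, 1, 0.4)
  # carried far more often by cases than controls (not fully separated)
  mat[, 20] <- rbinom(n, 1, ifelse(y == 1, 0.45, 0.05))
  scan <- perBinScan(mat, y)
  expect_true(scan$skipped[7])
  expect_true(is.na(scan$p[7]))
  expect_equal(which.min(scan$p), 20L)
  expect_gt(scan$beta[20], 0)
  expect_equal(scan$sign[20], 1)
})

test_that("per-bin p-values are uniform under label permutation", {
  set.seed(94)
  n <- 800
  nb <- 150
  mat <- matrix(rbinom(n * nb, 1, 0.25), n, nb)
  y <- sample(rep(c(0, 1), n / 2))
  scan <- perBinScan(mat, y)
  ks <- suppressWarnings(ks.test(scan$p[!scan$skipped], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("within-dataset permutation preserves case counts", {
  set.seed(95)
  dataset <- rep(c("a", "b", "c"), times = c(30, 50, 20))
  y <- rbinom(100, 1, 0.4)
  for (i in 1:20) {
    yp <- permuteWithinDataset(y, dataset)
    for (d in unique(dataset))
      expect_equal(sum(yp[dataset == d]), sum(y[dataset == d]))
  }
})

test_that("order-statistic thresholds follow the stated ranks", {
  minima <- (1:1000) / 1000
  expect_equal(permThresholdFromMinima(minima, 50), 0.050)
  expect_equal(permThresholdFromMinima(minima, 100), 0.100)
  expect_equal(permThresholdFromMinima(0.31, 1), 0.31)
  expect_error(permThresholdFromMinima(minima, 1001), "rank")
  set.seed(96)
  n <- 300; nb <- 25
  mat <- matrix(rbinom(n * nb, 1, 0.3), n, nb)
  y <- rbinom(n, 1, 0.5)
  dataset <- rep(c("a", "b"), each = n / 2)
  th <- permutationThresholds(mat, y, dataset = dataset, n_perm = 30,
                              rank_gw = 3, rank_sugg = 6, seed = 5)
  expect_lte(th$genomewide_p, th$suggestive_p)
  expect_length(th$minima, 30)
  th2 <- permutationThresholds(mat, y, dataset = dataset, n_perm = 30,
                               rank_gw = 3, rank_sugg = 6, seed = 5)
  expect_identical(th, th2)                      # seeded determinism
  expect_error(permutationThresholds(mat, y, dataset = dataset,
                                     n_perm = 5, rank_gw = 3,
                                     rank_sugg = 6, seed = 1), "n_perm")
})

test_that("Froh recomputation with excluded regions subtracts overlap", {
  rohs <- rohTable("s", 1L, 1e6, 3.3e6, 80L)     # 2.3 Mb
  base <- computeFroh(rohs)
  expect_equal(frohExcluding(rohs, rohs[0, c("chrom", "bp_start", "bp_end")])$froh,
               base$froh)
  whole <- data.frame(chrom = 1L, bp_start = 5e5, bp_end = 4e6)
  expect_equal(frohExcluding(rohs, whole)$froh, 0)
  part <- data.frame(chrom = 1L, bp_start = 2e6, bp_end = 2.3e6)
  expect_equal(frohExcluding(rohs, part)$froh,
               (2.3e6 - 3e5) / 2.77e9)
})

test_that("end-to-end mapping result is assembled coherently", {
  cfg <- simConfig(n_datasets = 2, samples_per_dataset = 80,
                   chrom_lengths_bp = 6e7, seed = 97,
                   f_point_mass = 0.2, f_point_value = 0.02,
                   f_exp_mean = 0.06, beta_froh = 25)
  x <- simulateCohort(cfg)
  rohs <- callRohsCohort(x)
  mr <- rohMapping(x, rohs, chrom_lengths_bp = 6e7, n_perm = 25,
                   rank_gw = 2, rank_sugg = 4, seed = 3)
  expect_s4_class(mr, "MappingResult")
  expect_equal(nrow(mr@bins), ceiling(6e7 / 5e5))
  expect_true(all(mr@results$roh_frequency >= 0 &
                    mr@results$roh_frequency <= 1))
  expect_lte(mr@genomewideP, mr@suggestiveP)
})
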