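test_that("tract lengths follow the exponential 1/(2g) Morgan law", {
  expect_equal(haldaneMeanLength(10), 0.05)    # 5 Mb at 1 cM/Mb
  expect_equal(haldaneMeanLength(1), 0.5)
  set.seed(21)
  lens <- sampleTractLengths(10000, g = 6)
  mu <- 1 / 12
  se <- mu / sqrt(10000)                        # exponential: sd == mean
  expect_lt(abs(mean(lens) - mu), 2 * se)
  expect_gt(stats::ks.test(lens, "pexp", rate = 12)$p.value, 0.01)
})

test_that("tract placement respects f_target, truncation and merging", {
  expect_equal(nrow(sampleTractSet(6, 0, c(1e8))), 0L)
  expect_error(sampleTractSet(0.5, 0.01, c(1e8)), "g must be")
  set.seed(4)
  L <- rep(1e8, 5)
  fs <- replicate(300, {
    tr <- sampleTractSet(6, 0.05, L)
    sum(tr$bp_end - tr$bp_start) / sum(L)
  })
  # truncation at chromosome ends biases coverage down slightly
  expect_lt(abs(mean(fs) - 0.05), 3 * sd(fs) / sqrt(300) + 0.004)
  tr <- sampleTractSet(6, 0.3, 1e8)
  expect_true(all(tr$bp_end <= 1e8))
  expect_true(all(tr$bp_end[-nrow(tr)] < tr$bp_start[-1]))  # disjoint
})

test_that("synthesized genotypes are homozygous inside tracts and HWE outside", {
  map <- gridMap(800, spacing = 30000)
  set.seed(5)
  freqs <- rep(0.5, 800)
  tract <- data.frame(chrom = 1L, bp_start = 1, bp_end = 800 * 30000)
  g <- synthesizeIndividual(map, freqs, tract, ld_rho = 0.3)
  expect_equal(sum(g == 1L), 0L)               # fully autozygous chromosome
  het <- mean(replicate(30, mean(synthesizeIndividual(
    map, freqs, tract[0, ], ld_rho = 0) == 1L)))
  expect_lt(abs(het - 0.5), 0.02)              # 2pq at p = 0.5
  set.seed(99); a <- synthesizeIndividual(map, freqs, tract, 0.3, 0.01, 0.01)
  set.seed(99); b <- synthesizeIndividual(map, freqs, tract, 0.3, 0.01, 0.01)
  expect_identical(a, b)
  expect_error(synthesizeIndividual(map, freqs,
                                    data.frame(chrom = 2L, bp_start = 1,
                                               bp_end = 100), 0),
               "outside map")
})

test_that("phenotype assignment follows the logistic disease model", {
  n <- 20000
  truth <- data.frame(sample_id = as.character(1:n),
                      dataset_id = rep(c("a", "b"), n / 2),
                      true_f = rep(0, n))
  cfg0 <- simConfig(beta_froh = 0, sigma_dataset = 0, alpha0 = 0)
  set.seed(2)
  ph <- assignPhenotypes(truth, cfg0)
  expect_lt(abs(mean(ph$phenotype) - 0.5), 0.01)
  # log-odds difference between true_f 0.01 and 0 equals 0.161
  cfg <- simConfig(beta_froh = 16.1, sigma_dataset = 0, alpha0 = 0)
  p1 <- plogis(cfg@alpha0 + cfg@beta_froh * 0.01)
  odds_ratio <- (p1 / (1 - p1)) / (0.5 / 0.5)
  expect_equal(odds_ratio, exp(0.161))
  expect_equal(round(odds_ratio, 3), 1.175)
  # saturation at extreme slope
  cfg_big <- simConfig(beta_froh = 500, sigma_dataset = 0, alpha0 = 0)
  truth$true_f <- 0.0625
  set.seed(3)
  ph <- assignPhenotypes(truth, cfg_big)
  expect_gt(mean(ph$phenotype), 0.999)
})

test_that("deletion injection silences heterozygotes and records truth", {
  cfg <- simConfig(n_datasets = 1, samples_per_dataset = 10,
                   chrom_lengths_bp = 3e7, deletion_rate = 0, seed = 8)
  x <- simulateCohort(cfg)
  calls <- genotypeCalls(x)
  out <- injectDeletions(calls, snpMap(x), cfg)
  expect_identical(out$calls, calls)
  expect_equal(nrow(out$deletions), 0L)
  # dense deletions: within each recorded region no het survives
  cfg2 <- simConfig(n_datasets = 1, samples_per_dataset = 10,
                    chrom_lengths_bp = 3e7, deletion_rate = 40,
                    deletion_len_meanlog = log(2e5), seed = 8)
  set.seed(13)
  out2 <- injectDeletions(calls, snpMap(x), cfg2,
                          sampleTable(x)$sample_id)
  expect_gt(nrow(out2$deletions), 0L)
  map <- snpMap(x)
  ids <- sampleTable(x)$sample_id
  for (i in seq_len(nrow(out2$deletions))) {
    d <- out2$deletions[i, ]
    j <- match(d$sample_id, ids)
    idx <- map$chrom == d$chrom & map$bp >= d$bp_start & map$bp <= d$bp_end
    expect_equal(sum(out2$calls[idx, j] == 1L, na.rm = TRUE), 0L)
  }
  # a sub-spacing deletion covering no SNP is still recorded as truth
  sub <- cfg2
  expect_true(all(c("sample_id", "chrom", "bp_start", "bp_end") %in%
                    names(out2$deletions)))
})

test_that("cohort simulation is seed-reproducible and hits its f target", {
  cfg <- simConfig(n_datasets = 2, samples_per_dataset = 50,
                   chrom_lengths_bp = 3e7, seed = 17,
                   f_point_mass = 0.3, f_point_value = 0.02,
                   f_exp_mean = 0.04)
  t0 <- Sys.time()
  x <- simulateCohort(cfg)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 5)
  y <- simulateCohort(cfg)
  expect_identical(genotypeCalls(x), genotypeCalls(y))
  expect_identical(sampleTable(x)$phenotype, sampleTable(y)$phenotype)
  # f-target recovery needs chromosomes much longer than the mean tract,
  # otherwise end-truncation dominates
  cfg2 <- simConfig(n_datasets = 2, samples_per_dataset = 75,
                    chrom_lengths_bp = c(1.5e8, 1.2e8, 1e8), seed = 18,
                    f_point_mass = 0.3, f_point_value = 0.02,
                    f_exp_mean = 0.04)
  tr <- S4Vectors::metadata(simulateCohort(cfg2))$truth
  f_mean_target <- 0.3 * 0.02 + 0.7 * 0.04
  expect_lt(abs(mean(tr$true_f) - f_mean_target),
            3 * sd(tr$true_f) / sqrt(nrow(tr)) + 0.005)
})

test_that("Froh-level generator matches the cohort-level calibration", {
  fl <- simulateFrohLevel(simConfig(seed = 23))
  expect_gt(nrow(fl), 20000)
  expect_true(mean(fl$froh) > 0.001 && mean(fl$froh) < 0.002)
  expect_true(sd(fl$froh) > 0.003 && sd(fl$froh) < 0.005)
  skew <- mean((fl$froh - mean(fl$froh))^3) / sd(fl$froh)^3
  expect_gt(skew, 1)                            # strongly right-skewed
  # all-outbred configuration collapses to zero autozygosity
  cfg0 <- simConfig(f_point_mass = 1, f_point_value = 0, seed = 1,
                    n_datasets = 2, samples_per_dataset = 100)
  expect_true(all(simulateFrohLevel(cfg0)$froh == 0))
})
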