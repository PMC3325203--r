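test_that("logistic fit recovers the closed-form 2x2 odds ratio", {
  y <- c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30))
  x <- c(rep(1, 40), rep(0, 40))
  fit <- fitLogistic(y, x)
  expect_equal(fit@beta, log(9), tolerance = 1e-6)   # (30*30)/(10*10)
  expect_equal(fit@z, fit@beta / fit@se)
  expect_equal(fit@ci95, fit@beta + c(-1.96, 1.96) * fit@se)
  expect_gt(fit@nagelkerkeR2, 0)
})

test_that("logistic fit matches an independent optimizer's ML solution", {
  set.seed(71)
  for (i in 1:5) {
    n <- 150
    x <- rnorm(n)
    z <- rnorm(n)
    eta <- -0.3 + 0.8 * x + 0.5 * z
    y <- rbinom(n, 1, plogis(eta))
    fit <- fitLogistic(y, x, data.frame(z = z))
    nll <- function(b) -sum(y * plogis(b[1] + b[2] * x + b[3] * z,
                                       log.p = TRUE) +
                              (1 - y) * plogis(-(b[1] + b[2] * x + b[3] * z),
                                               log.p = TRUE))
    opt <- optim(c(0, 0, 0), nll, method = "BFGS",
                 control = list(reltol = 1e-14))
    expect_equal(fit@beta, opt$par[2], tolerance = 1e-6)
  }
})

test_that("degenerate predictors are flagged, not silently reported", {
  y <- rep(c(0, 1), 20)
  fit <- fitLogistic(y, rep(1, 40))
  expect_false(fit@converged)
  expect_equal(fit@beta, 0)
  # complete separation
  fit2 <- fitLogistic(c(rep(0, 20), rep(1, 20)),
                      c(rep(0, 20), rep(1, 20)))
  expect_false(fit2@converged)
})

test_that("logistic p-values are calibrated under the null", {
  set.seed(72)
  n <- 200
  x <- rnorm(n)
  rej <- mean(replicate(500, {
    y <- rbinom(n, 1, 0.5)
    fitLogistic(y, x)@p < 0.05
  }))
  expect_true(rej >= 0.03 && rej <= 0.07)
})

test_that("odds transforms reproduce the headline fold changes", {
  expect_equal(oddsPerPercent(16.1), exp(0.161))
  expect_equal(round(100 * (oddsPerPercent(16.1) - 1)), 17)
  expect_equal(round(foldIncrease(16.1, 0.0625), 2), 2.74)
  expect_equal(round(foldIncrease(16.1, 0.015625), 2), 1.29)
  expect_equal(oddsPerPercent(0), 1)
  expect_equal(foldIncrease(0, 0.5), 1)
  # recomputation from a stored fit is exact
  y <- rbinom(100, 1, 0.5); x <- rnorm(100)
  fit <- fitLogistic(y, x)
  expect_identical(fit@or1pct, oddsPerPercent(fit@beta))
})

test_that("sign test gives exact binomial tails", {
  s <- signTest(c(rep(1, 13), rep(-1, 4)))
  expect_equal(s$k_positive, 13)
  expect_equal(s$n, 17)
  expect_equal(s$p, 3214 / 131072)
  expect_equal(round(s$p, 3), 0.025)
  expect_equal(signTest(c(rep(1, 9), rep(-1, 8)))$p, 0.5)
  expect_equal(signTest(rep(1, 17))$p, 2^-17)
  # ties excluded
  s2 <- signTest(c(rep(1, 13), rep(-1, 4), 0, 0))
  expect_equal(s2$n, 17)
  # cross-check against binom.test
  expect_equal(s$p, binom.test(13, 17, alternative = "greater")$p.value)
})

test_that("mixed model reduces to the pooled fit without dataset variance", {
  set.seed(73)
  cfg <- simConfig(n_datasets = 4, samples_per_dataset = 500,
                   sigma_dataset = 0, seed = 74)
  fl <- simulateFrohLevel(cfg)
  mixed <- fitMixedLogistic(fl$phenotype, fl$froh, dataset = fl$dataset_id)
  pooled <- fitLogistic(fl$phenotype, fl$froh)
  expect_lt(abs(mixed@beta - pooled@beta), pooled@se)
  expect_true(is.finite(mixed@nagelkerkeR2))
})

test_that("covariate builder returns calibrated PCs and QC statistics", {
  cfg <- simConfig(n_datasets = 2, samples_per_dataset = 40,
                   chrom_lengths_bp = 9e6, snp_spacing_bp = 3e4,
                   ld_rho = 0, f_point_mass = 1, f_point_value = 0,
                   het_miscall_rate = 0, deletion_rate = 0, seed = 75)
  x <- simulateCohort(cfg)
  cov <- buildCovariates(x, n_pcs = 10)
  expect_equal(nrow(cov), 80)
  expect_true(all(cov$missing_rate == 0))
  expect_lt(max(abs(cov$excess_het)), 0.25)      # near HWE expectation
  # homogeneous population: PC1 share close to the permutation null
  calls <- genotypeCalls(x)
  z <- scale(t(calls)); z[is.nan(z)] <- 0
  share1 <- function(m) { d <- svd(m, nu = 0, nv = 0)$d; d[1]^2 / sum(d^2) }
  obs <- share1(z)
  set.seed(76)
  nullshare <- share1(apply(z, 2, sample))
  expect_lt(obs, nullshare * 1.1)
  expect_error(buildCovariates(x, n_pcs = 1000), "rank")
})

test_that("sensitivity suite: no-op cutoffs, linearity and components", {
  set.seed(77)
  cfg <- simConfig(n_datasets = 5, samples_per_dataset = 400,
                   beta_froh = 30, seed = 78)
  fl <- simulateFrohLevel(cfg)
  sens <- sensitivitySuite(fl$phenotype, fl$froh, fl$dataset_id)
  base <- sens[sens$label == "base", ]
  noop <- sens[sens$label == "drop_froh_gt_0.125", ]
  if (noop$n_dropped == 0)
    expect_equal(noop$beta, base$beta)            # refit identical to base
  expect_true("quadratic" %in% sens$label)
  # purely linear generator: quadratic term rarely significant
  qp <- replicate(10, {
    fl2 <- simulateFrohLevel(simConfig(n_datasets = 5,
                                       samples_per_dataset = 400,
                                       beta_froh = 30,
                                       seed = sample.int(2^31 - 2, 1)))
    s <- sensitivitySuite(fl2$phenotype, fl2$froh, fl2$dataset_id,
                          cutoffs = numeric(0))
    s$p[s$label == "quadratic"]
  })
  expect_gte(mean(qp > 0.05), 0.8)
  # equal short/long effects: component fits agree within joint error
  comp <- data.frame(froh_short = fl$froh / 2, froh_long = fl$froh / 2)
  s2 <- sensitivitySuite(fl$phenotype, fl$froh, fl$dataset_id,
                         cutoffs = numeric(0), components = comp)
  bs <- s2[s2$label == "froh_short", ]
  bl <- s2[s2$label == "froh_long", ]
  expect_lt(abs(bs$beta - bl$beta), 2 * sqrt(bs$se^2 + bl$se^2))
})

test_that("threshold sweep is consistent with single fits and monotone", {
  cfg <- simConfig(n_datasets = 2, samples_per_dataset = 60,
                   chrom_lengths_bp = c(1e8, 8e7), seed = 79,
                   f_point_mass = 0.3, f_point_value = 0.01,
                   f_exp_mean = 0.05, beta_froh = 30)
  x <- simulateCohort(cfg)
  sw <- thresholdSweep(x, grid = c(50, 65, 90))
  expect_true(all(diff(sw$n_roh) <= 0))          # fewer ROHs as bar rises
  single <- thresholdSweep(x, grid = 65)
  expect_equal(sw$beta[sw$min_snps == 65], single$beta)
  st <- sampleTable(x)
  fr <- computeFroh(callRohsCohort(x, rohParams(min_snps = 65)),
                    sample_ids = st$sample_id)
  direct <- fitMixedLogistic(st$phenotype, fr$froh, dataset = st$dataset_id,
                             r2 = FALSE)
  expect_equal(single$beta, direct@beta)
})

test_that("heterogeneity LRT behaves as a 2-df test", {
  set.seed(80)
  fl <- simulateFrohLevel(simConfig(n_datasets = 6,
                                    samples_per_dataset = 300, seed = 81))
  h <- heterogeneityTest(fl$phenotype, fl$froh, fl$dataset_id)
  expect_equal(h$df, 2)
  expect_gte(h$chisq, 0)
  expect_true(h$p >= 0 && h$p <= 1)
})
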