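test_that("ROH calling applies the consecutive/gap/density rules", {
  # a heterozygote every 10 SNPs can never reach 65 consecutive
  map <- gridMap(300)
  calls <- rep(0L, 300); calls[seq(10, 300, by = 10)] <- 1L
  expect_equal(nrow(callRohs(calls, map)), 0L)

  # single het splits 200 homozygous SNPs into runs of 99 and 100
  map <- gridMap(200)
  calls <- rep(2L, 200); calls[100] <- 1L
  r <- callRohs(calls, map)
  expect_equal(sort(r$n_snps), c(99L, 100L))
  expect_equal(r$length_bp, r$bp_end - r$bp_start)

  # 65 homozygous SNPs spread over 20 Mb fail the 1 SNP / 200 kb density
  map <- gridMap(65, spacing = floor(20e6 / 65))
  expect_equal(nrow(callRohs(rep(0L, 65), map)), 0L)

  # a > 500 kb gap breaks one run into two of 65 SNPs each
  bp <- c(seq_len(65) * 30000, 65 * 30000 + 600000 + (seq_len(65) - 1) * 30000)
  map <- data.frame(snp_id = paste0("s", 1:130), chrom = 1L, bp = bp,
                    cm = bp * 1e-6, a1 = "A", a2 = "B")
  r <- callRohs(rep(0L, 130), map)
  expect_equal(r$n_snps, c(65L, 65L))

  # missing calls break a run by default but can be made transparent
  calls <- rep(0L, 200); calls[100] <- NA
  map <- gridMap(200)
  expect_equal(nrow(callRohs(calls, map, rohParams(min_snps = 150))), 0L)
  r2 <- callRohs(calls, map, rohParams(min_snps = 150, allowed_missing = 1))
  expect_equal(r2$n_snps, 199L)
  expect_error(callRohs(rep(0L, 10), map), "length")
  expect_error(rohParams(allowed_het = 1), "break")
})

test_that("caller agrees with the brute-force enumerator on random instances", {
  set.seed(61)
  for (rep in 1:60) {
    inst <- randomInstance(150)
    params <- rohParams(min_snps = sample(3:12, 1),
                        min_density_bp_per_snp = sample(c(1e5, 2e5), 1),
                        max_gap_bp = sample(c(3e5, 5e5), 1))
    expect_identical(canonRoh(callRohs(inst$calls, inst$map, params, "s")),
                     canonRoh(bruteRohs(inst$calls, inst$map, params, "s")))
  }
})

test_that("miscall-split ROHs are rejoined idempotently", {
  map <- gridMap(200)
  calls <- rep(0L, 200); calls[100] <- 1L
  x <- vectorCohort(calls, map)
  r <- callRohs(calls, map, rohParams(min_snps = 50), "s")
  expect_equal(nrow(r), 2L)
  j1 <- joinMiscallSplit(r, x)
  expect_equal(nrow(j1), 1L)
  expect_equal(j1$n_snps, 199L)
  expect_equal(j1$bp_start, min(r$bp_start))
  expect_equal(j1$bp_end, max(r$bp_end))
  expect_identical(joinMiscallSplit(j1, x), j1)
  # three hets between runs: too many to bridge
  calls3 <- rep(0L, 200); calls3[99:101] <- 1L
  x3 <- vectorCohort(calls3, map)
  r3 <- callRohs(calls3, map, rohParams(min_snps = 50), "s")
  expect_identical(joinMiscallSplit(r3, x3), r3)
})

test_that("Froh arithmetic and decompositions", {
  expect_equal(computeFroh(rohTable(), sample_ids = "s")$froh, 0)
  one <- rohTable("s", 1L, 1, 27700001, 900L)   # 27,700,000 bp span
  expect_equal(computeFroh(one)$froh, 0.01)
  two <- rohTable(c("s", "s"), c(1L, 2L), c(1, 1), c(2.3e6 + 1, 3.0e6 + 1),
                  c(70L, 90L))
  f <- computeFroh(two)
  expect_equal(f$froh, 5.3e6 / 2.77e9)
  expect_equal(f$froh_long, 0)
  expect_equal(f$froh_short + f$froh_long, f$froh)
  # exactly 5 Mb goes to the long class
  five <- rohTable("s", 1L, 1, 5e6 + 1, 100L)
  f5 <- computeFroh(five)
  expect_equal(f5$froh_short, 0)
  expect_equal(f5$froh_long, f5$froh)
  expect_error(computeFroh(two, denominator_bp = 0), "positive")
  # labels give a frequency decomposition that also sums exactly
  lab <- c("common", "uncommon")
  fl <- computeFroh(two, labels = lab)
  expect_equal(fl$froh_common + fl$froh_uncommon, fl$froh)
})

test_that("raising min_snps never increases froh (monotone in threshold)", {
  set.seed(62)
  cfg <- simConfig(n_datasets = 1, samples_per_dataset = 12,
                   chrom_lengths_bp = c(1e8, 8e7), seed = 63,
                   f_point_mass = 0.2, f_point_value = 0.02,
                   f_exp_mean = 0.05)
  x <- simulateCohort(cfg)
  ids <- sampleTable(x)$sample_id
  prev <- NULL
  for (ms in c(40, 65, 90, 120)) {
    fr <- computeFroh(callRohsCohort(x, rohParams(min_snps = ms)),
                      sample_ids = ids)
    if (!is.null(prev)) expect_true(all(fr$froh <= prev + 1e-12))
    prev <- fr$froh
  }
})

test_that("allelic matching separates common from uncommon ROHs", {
  # 25 samples share one haplotype over a region; 3 carry a second,
  # distinct haplotype; singleton elsewhere is uncommon by construction
  set.seed(64)
  m <- 300
  map <- gridMap(m)
  hapA <- sample(c(0L, 2L), m, TRUE)
  hapB <- 2L - hapA                              # maximally different
  n <- 29
  calls <- matrix(1L, nrow = m, ncol = n)        # het background: no ROH
  for (j in 1:25) calls[50:150, j] <- hapA[50:150]
  for (j in 26:28) calls[50:150, j] <- hapB[50:150]
  calls[200:290, 29] <- hapA[200:290]            # isolated ROH
  st <- data.frame(sample_id = sprintf("s%02d", 1:n),
                   dataset_id = "d", phenotype = 0L)
  x <- SnpCohort(map, calls, st)
  rohs <- callRohsCohort(x, rohParams(min_snps = 50))
  expect_equal(nrow(rohs), n)
  lab <- matchRohs(rohs, x)
  nm <- attr(lab, "n_matches")
  big <- rohs$sample_id %in% sprintf("s%02d", 1:25)
  small <- rohs$sample_id %in% sprintf("s%02d", 26:28)
  iso <- rohs$sample_id == "s29"
  expect_true(all(nm[big] == 24))                # 25-family: common (> 16)
  expect_true(all(lab[big] == "common"))
  expect_true(all(lab[small] == "uncommon"))     # 3-family
  expect_true(all(nm[iso] == 0) && all(lab[iso] == "uncommon"))
})

test_that("possible-deletion rule uses the strict residual threshold", {
  roh <- rohTable("s", 1L, 1e6, 3e6, 80L)        # 2,000 kb
  del <- data.frame(chrom = 1L, bp_start = 1.2e6, bp_end = 2.8e6)  # 1,600 kb
  expect_true(classifyPossibleDeletion(roh, del))
  # no overlap, length >= 500 kb: clean
  far <- data.frame(chrom = 2L, bp_start = 1, bp_end = 1e6)
  expect_false(classifyPossibleDeletion(roh, far))
  # residual exactly 500 kb: NOT flagged (strict <)
  del2 <- data.frame(chrom = 1L, bp_start = 1e6, bp_end = 2.5e6)
  expect_false(classifyPossibleDeletion(roh, del2))
  del3 <- data.frame(chrom = 1L, bp_start = 1e6, bp_end = 2.5e6 + 1)
  expect_true(classifyPossibleDeletion(roh, del3))
  # per-sample deletions only affect their carrier
  rohs <- rohTable(c("a", "b"), c(1L, 1L), c(1e6, 1e6), c(3e6, 3e6),
                   c(80L, 80L))
  dels <- data.frame(sample_id = "a", chrom = 1L, bp_start = 1e6,
                     bp_end = 2.9e6)
  expect_equal(classifyPossibleDeletion(rohs, dels), c(TRUE, FALSE))
})

test_that("generation-depth inversion matches the Haldane model", {
  expect_equal(inferGenerations(0.05), 10)
  expect_equal(inferGenerations(rep(0.08333333333, 5)), 6, tolerance = 1e-8)
  expect_error(inferGenerations(numeric(0)), "no tract lengths")
  set.seed(65)
  lens <- sampleTractLengths(20000, g = 6)
  expect_lt(abs(inferGenerations(lens) - 6), 0.2)
})
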