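#' Simulation configuration for synthetic case/control SNP cohorts
#'
#' Defines the study conditions emulated by the cohort generator: a
#' multi-dataset case/control sample genotyped on a pruned autosomal SNP
#' panel, with per-sample autozygous tracts planted under the exponential
#' (Haldane) tract-length model and a logistic disease model on the true
#' autozygous fraction.
#'
#' The per-sample target autozygous fraction is drawn from a two-component
#' mixture: with probability \code{f_point_mass} a point mass at
#' \code{f_point_value} (the outbred bulk), otherwise Exponential with mean
#' \code{f_exp_mean} (the right tail of elevated inbreeding). The defaults
#' give a marginal Froh distribution with mean ~0.0015 and SD ~0.004.
#'
#' @slot n_datasets number of collection sites (default 17)
#' @slot samples_per_dataset samples per site (default 1285, so that the
#'   default cohort size ~21,845)
#' @slot chrom_lengths_bp autosome lengths in bp
#' @slot snp_spacing_bp mean SNP spacing of the pruned panel (default 30 kb);
#'   positions sit on a regular grid with +/-20\% uniform jitter
#' @slot maf_range allele-frequency range for SNPs (default 0.05-0.5)
#' @slot ld_rho adjacent-SNP haplotype copying probability of the first-order
#'   Markov haplotype model (0-1)
#' @slot g generations to the common ancestor of planted tracts; tract
#'   lengths are Exponential with mean 1/(2g) Morgans
#' @slot f_point_mass,f_point_value,f_exp_mean mixture for the per-sample
#'   target autozygous fraction (see Details)
#' @slot beta_froh disease log-odds slope on the true autozygous fraction
#' @slot alpha0 baseline log-odds of disease
#' @slot sigma_dataset SD of dataset-level random intercepts
#' @slot het_miscall_rate probability that a truly homozygous call is read
#'   as a heterozygote
#' @slot missing_rate probability that any call is missing
#' @slot deletion_rate expected number of hemizygous deletions per sample
#' @slot deletion_len_meanlog,deletion_len_sdlog log-normal deletion length
#'   parameters (defaults give median ~10 kb)
#' @slot cm_per_mb genetic map scale (default 1 cM/Mb)
#' @slot seed RNG seed
#' @aliases SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig", representation(
  n_datasets = "integer", samples_per_dataset = "integer",
  chrom_lengths_bp = "numeric", snp_spacing_bp = "numeric",
  maf_range = "numeric", ld_rho = "numeric", g = "numeric",
  f_point_mass = "numeric", f_point_value = "numeric", f_exp_mean = "numeric",
  beta_froh = "numeric", alpha0 = "numeric", sigma_dataset = "numeric",
  het_miscall_rate = "numeric", missing_rate = "numeric",
  deletion_rate = "numeric", deletion_len_meanlog = "numeric",
  deletion_len_sdlog = "numeric", cm_per_mb = "numeric", seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  rates <- c(object@het_miscall_rate, object@missing_rate, object@ld_rho,
             object@f_point_mass)
  if (any(rates < 0 | rates > 1)) msg <- c(msg, "rates must lie in [0,1]")
  if (object@g < 1) msg <- c(msg, "g must be >= 1")
  if (any(object@chrom_lengths_bp <= 0))
    msg <- c(msg, "chromosome lengths must be positive")
  if (length(object@maf_range) != 2 || object@maf_range[1] > object@maf_range[2])
    msg <- c(msg, "maf_range must be (lo, hi)")
  if (length(msg)) msg else TRUE
})

#' @rdname SimConfig-class
#' @param ... slot overrides, e.g. \code{simConfig(n_datasets = 2,
#'   samples_per_dataset = 50, seed = 1)}
#' @return a \code{SimConfig}
#' @export
simConfig <- function(...) {
  args <- list(...)
  defaults <- list(
    n_datasets = 17L, samples_per_dataset = 1285L,
    chrom_lengths_bp = unname(autosomeLengths()),
    snp_spacing_bp = 30000, maf_range = c(0.05, 0.5), ld_rho = 0.3,
    g = 6, f_point_mass = 0.85, f_point_value = 0.0005, f_exp_mean = 0.006,
    beta_froh = 16.1, alpha0 = -0.28, sigma_dataset = 0.3,
    het_miscall_rate = 0.001, missing_rate = 0,
    deletion_rate = 100, deletion_len_meanlog = log(1e4),
    deletion_len_sdlog = 1, cm_per_mb = 1, seed = 1L
  )
  for (nm in names(args)) defaults[[nm]] <- args[[nm]]
  defaults$n_datasets <- as.integer(defaults$n_datasets)
  defaults$samples_per_dataset <- as.integer(defaults$samples_per_dataset)
  defaults$seed <- as.integer(defaults$seed)
  do.call(methods::new, c(list(Class = "SimConfig"), defaults))
}

# total genetic length of the simulated autosome, in Morgans
.totalMorgans <- function(config) {
  sum(config@chrom_lengths_bp) * 1e-8 * config@cm_per_mb
}

#' Draw autozygous tract lengths under the Haldane model
#'
#' Tract lengths are i.i.d. Exponential with mean 1/(2g) Morgans, the
#' expected length of an IBD segment inherited intact from a common
#' ancestor g generations back.
#' @param n number of lengths
#' @param g generations to the common ancestor (>= 1)
#' @return lengths in Morgans
#' @export
sampleTractLengths <- function(n, g) {
  if (g < 1) stop("g must be >= 1")
  stats::rexp(n, rate = 2 * g)
}

#' Plant a set of autozygous tracts on the genome
#'
#' Tract count is Poisson with mean \code{f_target * total_morgans * 2g}
#' (so the expected covered fraction is \code{f_target}); lengths follow
#' \code{\link{sampleTractLengths}}; placement is uniform; tracts are
#' truncated at chromosome ends and merged if overlapping.
#'
#' @param g generations to the common ancestor
#' @param f_target target autozygous fraction in [0, 1)
#' @param chrom_lengths_bp chromosome lengths
#' @param cm_per_mb genetic map scale (default 1)
#' @return data.frame with chrom, bp_start, bp_end (span convention:
#'   covered length = bp_end - bp_start)
#' @export
sampleTractSet <- function(g, f_target, chrom_lengths_bp, cm_per_mb = 1) {
  if (g < 1) stop("g must be >= 1")
  if (f_target < 0 || f_target >= 1) stop("f_target must be in [0, 1)")
  empty <- data.frame(chrom = integer(), bp_start = numeric(),
                      bp_end = numeric())
  if (f_target == 0) return(empty)
  total_m <- sum(chrom_lengths_bp) * 1e-8 * cm_per_mb
  n <- stats::rpois(1, f_target * total_m * 2 * g)
  if (n == 0) return(empty)
  len_bp <- sampleTractLengths(n, g) * 1e8 / cm_per_mb
  chrom <- sample.int(length(chrom_lengths_bp), n, replace = TRUE,
                      prob = chrom_lengths_bp)
  start <- floor(stats::runif(n, min = 1, max = chrom_lengths_bp[chrom]))
  end <- pmin(start + len_bp, chrom_lengths_bp[chrom])
  keep <- end > start
  if (!any(keep)) return(empty)
  mergeRegions(data.frame(chrom = chrom[keep], bp_start = start[keep],
                          bp_end = end[keep]))
}

# mixture draw of per-sample target autozygous fractions
sampleFTarget <- function(n, config) {
  pick <- stats::runif(n) < config@f_point_mass
  ft <- numeric(n)
  ft[pick] <- config@f_point_value
  ft[!pick] <- stats::rexp(sum(!pick), rate = 1 / config@f_exp_mean)
  pmin(ft, 0.999)
}

# one haplotype over the SNP panel: first-order Markov chain that with
# probability ld_rho copies the previous allele, else draws Bern(p_j)
.simHaplotype <- function(p, chrom, ld_rho) {
  m <- length(p)
  fresh <- as.integer(stats::runif(m) < p)
  if (ld_rho <= 0) return(fresh)
  copy <- stats::runif(m) < ld_rho
  copy[c(TRUE, chrom[-1] != chrom[-m])] <- FALSE  # chromosome starts anew
  src <- cummax(ifelse(copy, 0L, seq_len(m)))
  fresh[src]
}

#' Synthesize one individual's genotypes with planted autozygous tracts
#'
#' Two haplotypes are drawn from the Markov haplotype model; inside each
#' tract the second haplotype is overwritten by the first (every covered
#' site homozygous before noise). Each truly homozygous call then flips to
#' a heterozygote with probability \code{het_miscall_rate}, and any call
#' becomes missing with probability \code{missing_rate}.
#'
#' @param map SNP map data.frame (chrom, bp)
#' @param freqs per-SNP frequency of the counted allele
#' @param tracts data.frame of tracts (chrom, bp_start, bp_end)
#' @param ld_rho,het_miscall_rate,missing_rate model parameters
#' @return integer genotype vector in \{0,1,2,NA\}
#' @export
synthesizeIndividual <- function(map, freqs, tracts, ld_rho = 0,
                                 het_miscall_rate = 0, missing_rate = 0) {
  if (nrow(tracts) && !all(tracts$chrom %in% map$chrom))
    stop("tract outside map extent")
  h1 <- .simHaplotype(freqs, map$chrom, ld_rho)
  h2 <- .simHaplotype(freqs, map$chrom, ld_rho)
  if (nrow(tracts)) {
    for (i in seq_len(nrow(tracts))) {
      idx <- map$chrom == tracts$chrom[i] &
        map$bp >= tracts$bp_start[i] & map$bp <= tracts$bp_end[i]
      h2[idx] <- h1[idx]
    }
  }
  gcall <- h1 + h2
  hom <- gcall != 1L
  if (het_miscall_rate > 0) {
    flip <- hom & stats::runif(length(gcall)) < het_miscall_rate
    gcall[flip] <- 1L
  }
  if (missing_rate > 0)
    gcall[stats::runif(length(gcall)) < missing_rate] <- NA_integer_
  as.integer(gcall)
}

#' Assign case/control phenotypes under a logistic disease model
#'
#' \code{P(case) = plogis(alpha0 + alpha_d + beta_froh * true_f)} with
#' dataset intercepts \code{alpha_d ~ Normal(0, sigma_dataset^2)}.
#'
#' @param truth data.frame with sample_id, dataset_id, true_f
#' @param config a \linkS4class{SimConfig}
#' @param alpha_d optional named vector of dataset intercepts (drawn if NULL)
#' @return data.frame sample_id, dataset_id, phenotype (0/1), with the
#'   dataset intercepts as attribute \code{"alpha_d"}
#' @export
assignPhenotypes <- function(truth, config, alpha_d = NULL) {
  ds <- unique(truth$dataset_id)
  if (is.null(alpha_d)) {
    alpha_d <- stats::setNames(
      stats::rnorm(length(ds), 0, config@sigma_dataset), ds)
  }
  eta <- config@alpha0 + alpha_d[truth$dataset_id] +
    config@beta_froh * truth$true_f
  pheno <- stats::rbinom(nrow(truth), 1, stats::plogis(eta))
  out <- data.frame(sample_id = truth$sample_id,
                    dataset_id = truth$dataset_id,
                    phenotype = as.integer(pheno),
                    stringsAsFactors = FALSE)
  attr(out, "alpha_d") <- alpha_d
  out
}

#' Inject hemizygous deletions into a call matrix
#'
#' Deletion count per sample is Poisson(\code{deletion_rate}); lengths are
#' log-normal (median ~10 kb by default); placement uniform. Within a
#' deletion a heterozygous call becomes homozygous for the remaining allele
#' (either, with equal probability); homozygotes are unchanged. Regions are
#' returned even when they cover no SNP.
#'
#' @param calls SNPs x samples integer matrix
#' @param map SNP map data.frame
#' @param config a \linkS4class{SimConfig}
#' @param sample_ids column ids of \code{calls}
#' @return list(calls = modified matrix, deletions = data.frame(sample_id,
#'   chrom, bp_start, bp_end))
#' @export
injectDeletions <- function(calls, map, config,
                            sample_ids = colnames(calls)) {
  n <- ncol(calls)
  L <- config@chrom_lengths_bp
  # per-chromosome row offsets for O(log m) SNP lookup per deletion
  chrom_rows <- lapply(sort(unique(map$chrom)), function(ch)
    which(map$chrom == ch))
  names(chrom_rows) <- as.character(sort(unique(map$chrom)))
  dels <- vector("list", n)
  for (j in seq_len(n)) {
    k <- stats::rpois(1, config@deletion_rate)
    if (k == 0) next
    len <- stats::rlnorm(k, config@deletion_len_meanlog,
                         config@deletion_len_sdlog)
    chrom <- sample.int(length(L), k, replace = TRUE, prob = L)
    start <- floor(stats::runif(k, 1, L[chrom]))
    end <- pmin(start + len, L[chrom])
    keep <- end > start
    if (!any(keep)) next
    d <- data.frame(sample_id = sample_ids[j], chrom = chrom[keep],
                    bp_start = start[keep], bp_end = end[keep])
    for (i in seq_len(nrow(d))) {
      rows <- chrom_rows[[as.character(d$chrom[i])]]
      if (is.null(rows)) next
      bp <- map$bp[rows]
      lo <- findInterval(d$bp_start[i] - 1, bp) + 1
      hi <- findInterval(d$bp_end[i], bp)
      if (hi < lo) next
      idx <- rows[lo:hi]
      het <- idx[!is.na(calls[idx, j]) & calls[idx, j] == 1L]
      if (length(het))
        calls[het, j] <- sample(c(0L, 2L), length(het), replace = TRUE)
    }
    dels[[j]] <- d
  }
  dels <- do.call(rbind, dels[!vapply(dels, is.null, TRUE)])
  if (is.null(dels))
    dels <- data.frame(sample_id = character(), chrom = integer(),
                       bp_start = numeric(), bp_end = numeric())
  list(calls = calls, deletions = dels)
}

# SNP map on a jittered regular grid: near-uniform density as in a pruned
# panel, and no gaps approaching the ROH gap rule
.simMap <- function(config) {
  maps <- lapply(seq_along(config@chrom_lengths_bp), function(ch) {
    L <- config@chrom_lengths_bp[ch]
    s <- config@snp_spacing_bp
    k <- floor(L / s)
    if (k < 1) return(NULL)
    grid <- seq_len(k) * s - s / 2
    bp <- round(grid + stats::runif(k, -0.2 * s, 0.2 * s))
    data.frame(chrom = ch, bp = pmin(pmax(bp, 1), L))
  })
  map <- do.call(rbind, maps[!vapply(maps, is.null, TRUE)])
  map$snp_id <- sprintf("snp%d_%d", map$chrom, map$bp)
  map$cm <- map$bp * 1e-6 * config@cm_per_mb
  map$a1 <- "A"; map$a2 <- "B"
  map[, c("snp_id", "chrom", "bp", "cm", "a1", "a2")]
}

#' Simulate a full multi-dataset case/control SNP cohort
#'
#' Runs the whole generator: SNP panel, haplotypes, planted autozygous
#' tracts, heterozygote-miscall and missingness noise, hemizygous
#' deletions, and the logistic disease model. Fully reproducible from
#' \code{config@seed}.
#'
#' @param config a \linkS4class{SimConfig}
#' @return a \linkS4class{SnpCohort}; simulation truth is stored in
#'   \code{metadata(x)$truth} (per-sample table), \code{$tracts},
#'   \code{$deletions} and \code{$snp_freqs}
#' @export
simulateCohort <- function(config) {
  methods::validObject(config)
  set.seed(config@seed)
  map <- .simMap(config)
  m <- nrow(map)
  freqs <- stats::runif(m, config@maf_range[1], config@maf_range[2])
  n <- config@n_datasets * config@samples_per_dataset
  dataset_id <- rep(sprintf("dataset%02d", seq_len(config@n_datasets)),
                    each = config@samples_per_dataset)
  sample_id <- sprintf("%s_s%04d", dataset_id,
                       sequence(rep(config@samples_per_dataset,
                                    config@n_datasets)))
  f_target <- sampleFTarget(n, config)
  calls <- matrix(NA_integer_, nrow = m, ncol = n)
  tract_list <- vector("list", n)
  true_f <- numeric(n)
  total_bp <- sum(config@chrom_lengths_bp)
  for (j in seq_len(n)) {
    tr <- sampleTractSet(config@g, f_target[j], config@chrom_lengths_bp,
                         config@cm_per_mb)
    tract_list[[j]] <- if (nrow(tr)) cbind(sample_id = sample_id[j], tr)
    true_f[j] <- sum(tr$bp_end - tr$bp_start) / total_bp
    calls[, j] <- synthesizeIndividual(map, freqs, tr, config@ld_rho,
                                       config@het_miscall_rate,
                                       config@missing_rate)
  }
  colnames(calls) <- sample_id
  del <- injectDeletions(calls, map, config, sample_id)
  truth <- data.frame(sample_id = sample_id, dataset_id = dataset_id,
                      f_target = f_target, true_f = true_f,
                      stringsAsFactors = FALSE)
  pheno <- assignPhenotypes(truth, config)
  truth$alpha_d <- attr(pheno, "alpha_d")[truth$dataset_id]
  samples <- data.frame(sample_id = sample_id, dataset_id = dataset_id,
                        phenotype = pheno$phenotype,
                        stringsAsFactors = FALSE)
  x <- SnpCohort(map, del$calls, samples)
  tracts <- do.call(rbind, tract_list[!vapply(tract_list, is.null, TRUE)])
  if (is.null(tracts))
    tracts <- data.frame(sample_id = character(), chrom = integer(),
                         bp_start = numeric(), bp_end = numeric())
  S4Vectors::metadata(x)$truth <- truth
  S4Vectors::metadata(x)$tracts <- tracts
  S4Vectors::metadata(x)$deletions <- del$deletions
  S4Vectors::metadata(x)$snp_freqs <- freqs
  x
}

#' Fast Froh-level cohort simulation (no genotypes)
#'
#' Bypasses genotype synthesis: each sample's Froh is the autosomal
#' fraction covered by a Poisson number of Exponential(mean 1/(2g) Morgan)
#' tracts, calibrated by the target-fraction mixture so that the marginal
#' distribution has mean ~0.0015 and SD ~0.004 under the defaults.
#' Phenotypes follow the same logistic disease model as
#' \code{\link{assignPhenotypes}}. Intended for power and
#' parameter-recovery studies at full cohort scale.
#'
#' @param config a \linkS4class{SimConfig}
#' @param set_seed set the RNG from \code{config@seed} first (default TRUE;
#'   FALSE lets callers run replicate streams)
#' @return data.frame sample_id, dataset_id, froh, phenotype; the per-sample
#'   target fraction is attached as column \code{f_target}
#' @export
simulateFrohLevel <- function(config, set_seed = TRUE) {
  methods::validObject(config)
  if (set_seed) set.seed(config@seed)
  n <- config@n_datasets * config@samples_per_dataset
  total_m <- .totalMorgans(config)
  dataset_id <- rep(sprintf("dataset%02d", seq_len(config@n_datasets)),
                    each = config@samples_per_dataset)
  sample_id <- sprintf("%s_s%05d", dataset_id,
                       sequence(rep(config@samples_per_dataset,
                                    config@n_datasets)))
  ft <- sampleFTarget(n, config)
  k <- stats::rpois(n, ft * total_m * 2 * config@g)
  froh <- numeric(n)
  pos <- which(k > 0)
  if (length(pos)) {
    lens <- sampleTractLengths(sum(k[pos]), config@g)
    froh[pos] <- rowsum(lens, rep(pos, k[pos]))[, 1] / total_m
  }
  froh <- pmin(froh, 1)
  truth <- data.frame(sample_id = sample_id, dataset_id = dataset_id,
                      true_f = froh, stringsAsFactors = FALSE)
  pheno <- assignPhenotypes(truth, config)
  data.frame(sample_id = sample_id, dataset_id = dataset_id, froh = froh,
             phenotype = pheno$phenotype, f_target = ft,
             stringsAsFactors = FALSE)
}
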