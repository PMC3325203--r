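#' Build the burden-model covariate set
#'
#' Principal components of the column-standardized call matrix (missing
#' calls mean-imputed) to control ancestry stratification, the per-sample
#' missing-call rate, and an excess-heterozygosity statistic
#' \code{(observed het count - expected het count under per-SNP
#' frequencies) / expected}, which track genotype quality.
#'
#' @param x a \linkS4class{SnpCohort}
#' @param n_pcs number of principal components (default 20)
#' @return data.frame with columns pc1..pc<n_pcs>, missing_rate, excess_het,
#'   one row per sample
#' @export
buildCovariates <- function(x, n_pcs = 20) {
  calls <- genotypeCalls(x)
  z <- t(calls)                 # samples x snps
  miss <- rowMeans(is.na(z))
  p <- colMeans(z, na.rm = TRUE) / 2
  exp_het_site <- 2 * p * (1 - p)
  obs <- rowSums(z == 1L, na.rm = TRUE)
  expd <- (!is.na(z)) %*% exp_het_site
  excess_het <- as.numeric((obs - expd) / pmax(expd, .Machine$double.eps))
  mu <- colMeans(z, na.rm = TRUE)
  for (j in seq_len(ncol(z))) {
    nas <- is.na(z[, j])
    if (any(nas)) z[nas, j] <- mu[j]
  }
  z <- scale(z)
  z[is.nan(z)] <- 0
  z[is.na(z)] <- 0
  sv <- svd(z, nu = min(n_pcs, dim(z)), nv = 0)
  rank <- sum(sv$d > max(dim(z)) * .Machine$double.eps * sv$d[1])
  if (n_pcs > rank) stop("n_pcs exceeds the rank of the genotype matrix")
  pcs <- sv$u[, seq_len(n_pcs), drop = FALSE] %*%
    diag(sv$d[seq_len(n_pcs)], n_pcs)
  out <- as.data.frame(pcs)
  names(out) <- paste0("pc", seq_len(n_pcs))
  out$missing_rate <- miss
  out$excess_het <- excess_het
  rownames(out) <- rownames(z)
  out
}

.newBurdenFit <- function(beta, se, n, model, r2 = NA_real_,
                          converged = TRUE, note = "") {
  if (!is.finite(se) || se <= 0) {
    converged <- FALSE
    w <- list(z = NA_real_, p = NA_real_, ci = c(NA_real_, NA_real_))
  } else w <- waldStats(beta, se)
  methods::new("BurdenFit", beta = beta, se = se, z = w$z, p = w$p,
               or1pct = exp(0.01 * beta), ci95 = w$ci,
               nagelkerkeR2 = r2, n = as.integer(n), model = model,
               converged = converged, note = note)
}

#' Logistic burden regression
#'
#' Maximum-likelihood logistic regression of case/control status on a
#' predictor (typically Froh) with optional covariates, fitted by
#' iteratively reweighted least squares; Wald se/z/p and Nagelkerke pseudo
#' R-squared (full model vs covariate-only null). Quasi-separation or a
#' degenerate predictor yields a flagged (non-converged) result rather
#' than a silent one.
#'
#' @param y binary 0/1 outcome
#' @param x predictor
#' @param covariates optional data.frame/matrix of covariates
#' @return a \linkS4class{BurdenFit}
#' @export
fitLogistic <- function(y, x, covariates = NULL) {
  if (length(unique(y[!is.na(y)])) < 2)
    stop("y must contain both cases and controls")
  df <- data.frame(y = y, x = x)
  form <- y ~ x
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    cv <- as.data.frame(covariates)
    df <- cbind(df, cv)
    form <- stats::as.formula(paste("y ~ x +",
                                    paste(names(cv), collapse = " + ")))
  }
  if (stats::var(x) == 0)
    return(.newBurdenFit(0, Inf, length(y), "per_dataset",
                         note = "constant predictor"))
  note <- ""
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- summary(fit)$coefficients
  beta <- cf["x", 1]; se <- cf["x", 2]
  null_form <- if (is.null(covariates)) y ~ 1 else
    stats::as.formula(paste("y ~",
                            paste(names(as.data.frame(covariates)),
                                  collapse = " + ")))
  null <- stats::glm(null_form, data = df, family = stats::binomial())
  r2 <- nagelkerkeR2(as.numeric(stats::logLik(null)),
                     as.numeric(stats::logLik(fit)), length(y))
  conv <- fit$converged && !sep_warn && is.finite(se) && se < 1e3 * max(1, abs(beta))
  if (sep_warn) note <- "possible separation"
  if (!fit$converged) note <- "IRLS did not converge"
  .newBurdenFit(beta, se, length(y), "per_dataset", r2,
                converged = conv, note = note)
}

#' Mixed-effects logistic burden regression
#'
#' Logit-link mixed model with a dataset-level random intercept (Laplace
#' approximate maximum likelihood); the fixed-effect slope for Froh is
#' reported. This is the combined-sample burden model: datasets differ in
#' baseline risk and genotyping platform, which the random intercept
#' absorbs.
#'
#' @param y binary outcome
#' @param froh per-sample Froh
#' @param covariates optional covariate data.frame
#' @param dataset dataset identifier per sample (>= 2 datasets)
#' @param r2 also fit the no-Froh null for Nagelkerke R2 (default TRUE;
#'   skipping it halves the cost in replicate studies)
#' @return a \linkS4class{BurdenFit}
#' @export
fitMixedLogistic <- function(y, froh, covariates = NULL, dataset, r2 = TRUE) {
  if (length(unique(dataset)) < 2) stop("need >= 2 datasets")
  df <- data.frame(y = y, froh = froh, dataset = dataset)
  rhs <- "froh"
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    cv <- as.data.frame(covariates)
    df <- cbind(df, cv)
    rhs <- paste(c("froh", names(cv)), collapse = " + ")
  }
  form <- stats::as.formula(paste("y ~", rhs, "+ (1 | dataset)"))
  ctrl <- lme4::glmerControl(optimizer = "bobyqa", calc.derivs = FALSE,
                             check.scaleX = "ignore")
  fit <- tryCatch(
    suppressMessages(lme4::glmer(form, data = df,
                                 family = stats::binomial(), nAGQ = 1L,
                                 control = ctrl)),
    error = function(e) stop("mixed model failed to converge: ",
                             conditionMessage(e)))
  cf <- summary(fit)$coefficients
  beta <- cf["froh", 1]; se <- cf["froh", 2]
  r2v <- NA_real_
  if (r2) {
    null_rhs <- sub("^froh \\+ |^froh$", "", rhs)
    null_form <- stats::as.formula(
      paste("y ~", if (nzchar(null_rhs)) null_rhs else "1", "+ (1 | dataset)"))
    null <- suppressMessages(lme4::glmer(null_form, data = df,
                                         family = stats::binomial(),
                                         nAGQ = 1L, control = ctrl))
    r2v <- nagelkerkeR2(as.numeric(stats::logLik(null)),
                        as.numeric(stats::logLik(fit)), length(y))
  }
  conv <- length(fit@optinfo$conv$lme4) == 0
  .newBurdenFit(beta, se, length(y), "mixed", r2v, converged = conv,
                note = if (conv) "" else "optimizer warnings")
}

#' Odds multipliers implied by a burden slope
#'
#' \code{oddsPerPercent} gives the odds multiplier for a 0.01 increase in
#' Froh (\code{exp(0.01 beta)}); \code{foldIncrease} the multiplier at an
#' arbitrary autozygosity level \code{F} (\code{exp(beta F)}), e.g.
#' F = 0.0625 for cousin-cousin and F = 0.015625 for second-cousin
#' offspring.
#'
#' @param beta log-odds per unit Froh
#' @param F autozygosity level
#' @return fold change in odds
#' @export
oddsPerPercent <- function(beta) exp(0.01 * beta)

#' @rdname oddsPerPercent
#' @export
foldIncrease <- function(beta, F) exp(beta * F)

#' Exact binomial sign test on per-dataset odds-ratio directions
#'
#' One-sided exact binomial tail probability \code{P(X >= k)} at success
#' probability 0.5, where k is the number of datasets whose odds ratio
#' exceeds one. Ties (OR exactly 1) are excluded.
#'
#' @param betas per-dataset log-odds slopes (or anything signed)
#' @return list(k_positive, n, p)
#' @export
signTest <- function(betas) {
  betas <- betas[!is.na(betas) & betas != 0]
  n <- length(betas)
  k <- sum(betas > 0)
  p <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  list(k_positive = k, n = n, p = p)
}

#' Per-dataset logistic burden fits
#'
#' Fits \code{\link{fitLogistic}} within each dataset; the forest of these
#' fits feeds \code{\link{signTest}}.
#'
#' @param y,froh,dataset aligned vectors
#' @param covariates optional covariate data.frame (subset per dataset)
#' @return data.frame: dataset, n, beta, se, z, p, or_1pct, converged
#' @export
perDatasetFits <- function(y, froh, dataset, covariates = NULL) {
  out <- lapply(unique(dataset), function(d) {
    sel <- dataset == d
    cv <- if (is.null(covariates)) NULL else
      as.data.frame(covariates)[sel, , drop = FALSE]
    fit <- tryCatch(fitLogistic(y[sel], froh[sel], cv),
                    error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(dataset = d, n = sum(sel), beta = NA, se = NA,
                        z = NA, p = NA, or_1pct = NA, converged = FALSE))
    data.frame(dataset = d, n = sum(sel), beta = fit@beta, se = fit@se,
               z = fit@z, p = fit@p, or_1pct = fit@or1pct,
               converged = fit@converged)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Burden slope across a grid of ROH SNP thresholds
#'
#' For each \code{min_snps} value, ROHs are re-called, Froh recomputed and
#' the mixed burden model refitted, tracing how the slope depends on the
#' calling threshold.
#'
#' @param x a \linkS4class{SnpCohort} with phenotypes
#' @param grid ascending vector of min_snps values
#' @param covariates optional covariate data.frame
#' @param params base \code{\link{rohParams}} (min_snps replaced per point)
#' @param denominator_bp Froh denominator
#' @return data.frame: min_snps, n_roh, beta, se, ci_lo, ci_hi, z, p
#' @export
thresholdSweep <- function(x, grid = seq(40, 100, by = 10),
                           covariates = NULL, params = rohParams(),
                           denominator_bp = FROH_DENOMINATOR_BP) {
  if (is.unsorted(grid)) stop("grid must be ascending")
  st <- sampleTable(x)
  out <- lapply(grid, function(ms) {
    p <- params; p$min_snps <- ms
    rohs <- callRohsCohort(x, p)
    fr <- computeFroh(rohs, denominator_bp, sample_ids = st$sample_id)
    fit <- fitMixedLogistic(st$phenotype, fr$froh, covariates,
                            st$dataset_id, r2 = FALSE)
    data.frame(min_snps = ms, n_roh = nrow(rohs), beta = fit@beta,
               se = fit@se, ci_lo = fit@ci95[1], ci_hi = fit@ci95[2],
               z = fit@z, p = fit@p)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Burden sensitivity analyses
#'
#' Refits the mixed burden model after dropping samples above each Froh
#' cutoff (half-sib, cousin, half-cousin, elevated-distant and
#' above-the-mean levels), adds a quadratic Froh term (testing linearity),
#' and fits the short/long and common/uncommon Froh components separately.
#'
#' @param y,froh,dataset aligned vectors
#' @param covariates optional covariate data.frame
#' @param cutoffs Froh cutoffs for the outlier-dropping refits
#' @param components optional data.frame with any of froh_short,
#'   froh_long, froh_common, froh_uncommon
#' @return data.frame: label, n, n_dropped, beta, se, z, p, note. For the
#'   "quadratic" row the statistics refer to the Froh^2 term.
#' @export
sensitivitySuite <- function(y, froh, dataset, covariates = NULL,
                             cutoffs = c(0.125, 0.0625, 0.03125, 0.005),
                             components = NULL) {
  rows <- list()
  push <- function(label, fit, n, n_dropped = 0L, note = "") {
    rows[[length(rows) + 1]] <<- data.frame(
      label = label, n = n, n_dropped = n_dropped,
      beta = if (is.null(fit)) NA_real_ else fit@beta,
      se = if (is.null(fit)) NA_real_ else fit@se,
      z = if (is.null(fit)) NA_real_ else fit@z,
      p = if (is.null(fit)) NA_real_ else fit@p,
      note = note, stringsAsFactors = FALSE)
  }
  subcov <- function(sel) if (is.null(covariates)) NULL else
    as.data.frame(covariates)[sel, , drop = FALSE]

  base <- fitMixedLogistic(y, froh, covariates, dataset, r2 = FALSE)
  push("base", base, length(y))

  for (cut in c(cutoffs, mean(froh))) {
    lab <- if (cut == mean(froh) && !(cut %in% cutoffs))
      "drop_above_mean" else sprintf("drop_froh_gt_%g", cut)
    keep <- froh <= cut
    nd <- sum(!keep)
    if (length(unique(dataset[keep])) < 2 ||
        length(unique(y[keep])) < 2) {
      push(lab, NULL, sum(keep), nd, "skipped: < 2 datasets or one class")
      next
    }
    fit <- if (nd == 0) base else
      fitMixedLogistic(y[keep], froh[keep], subcov(keep), dataset[keep],
                       r2 = FALSE)
    push(lab, fit, sum(keep), nd, if (nd == 0) "no samples dropped" else "")
  }

  # quadratic term: froh^2 added as a second fixed effect
  cv2 <- data.frame(froh2 = froh^2)
  if (!is.null(covariates)) cv2 <- cbind(as.data.frame(covariates), cv2)
  qdf <- data.frame(y = y, froh = froh, dataset = dataset, cv2)
  qform <- stats::as.formula(paste("y ~",
                                   paste(setdiff(names(qdf),
                                                 c("y", "dataset")),
                                         collapse = " + "),
                                   "+ (1 | dataset)"))
  qfit <- suppressMessages(lme4::glmer(
    qform, data = qdf, family = stats::binomial(), nAGQ = 1L,
    control = lme4::glmerControl(optimizer = "bobyqa",
                                 calc.derivs = FALSE,
                                 check.scaleX = "ignore")))
  qcf <- summary(qfit)$coefficients
  qb <- qcf["froh2", 1]; qse <- qcf["froh2", 2]
  qw <- waldStats(qb, qse)
  rows[[length(rows) + 1]] <- data.frame(
    label = "quadratic", n = length(y), n_dropped = 0L,
    beta = qb, se = qse, z = qw$z, p = qw$p,
    note = "stats are for the Froh^2 term", stringsAsFactors = FALSE)

  if (!is.null(components)) {
    for (comp in intersect(c("froh_short", "froh_long", "froh_common",
                             "froh_uncommon"), names(components))) {
      v <- components[[comp]]
      fit <- fitMixedLogistic(y, v, covariates, dataset, r2 = FALSE)
      push(comp, fit, length(y))
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Between-dataset heterogeneity of the burden slope
#'
#' Likelihood-ratio test of a random-slope mixed model (slope variance plus
#' intercept-slope covariance) against the random-intercept model, 2 df.
#'
#' @param y,froh,dataset aligned vectors
#' @return list(chisq, df, p)
#' @export
heterogeneityTest <- function(y, froh, dataset) {
  df <- data.frame(y = y, froh = froh, dataset = dataset)
  ctrl <- lme4::glmerControl(optimizer = "bobyqa", calc.derivs = FALSE,
                             check.scaleX = "ignore")
  m0 <- suppressMessages(lme4::glmer(y ~ froh + (1 | dataset), data = df,
                                     family = stats::binomial(), nAGQ = 1L,
                                     control = ctrl))
  m1 <- suppressMessages(lme4::glmer(y ~ froh + (1 + froh | dataset),
                                     data = df,
                                     family = stats::binomial(), nAGQ = 1L,
                                     control = ctrl))
  chisq <- max(0, 2 * (as.numeric(stats::logLik(m1)) -
                         as.numeric(stats::logLik(m0))))
  list(chisq = chisq, df = 2,
       p = stats::pchisq(chisq, df = 2, lower.tail = FALSE))
}
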