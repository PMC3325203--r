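#' Tile the autosome into fixed-width bins
#'
#' Bins are anchored at bp 1 per chromosome; the final partial bin is
#' retained, so the bin count is \code{sum(ceiling(lengths / width))}.
#'
#' @param chrom_lengths_bp chromosome lengths (named or in chromosome order)
#' @param width bin width in bp (default 500 kb)
#' @return data.frame: chrom, bp_start, bp_end
#' @export
makeBins <- function(chrom_lengths_bp, width = 5e5) {
  if (width <= 0) stop("width must be positive")
  if (any(chrom_lengths_bp <= 0)) stop("chromosome lengths must be positive")
  chroms <- if (!is.null(names(chrom_lengths_bp)))
    as.integer(names(chrom_lengths_bp)) else seq_along(chrom_lengths_bp)
  out <- lapply(seq_along(chrom_lengths_bp), function(i) {
    L <- chrom_lengths_bp[i]
    k <- ceiling(L / width)
    s <- (seq_len(k) - 1) * width + 1
    data.frame(chrom = chroms[i], bp_start = s,
               bp_end = pmin(seq_len(k) * width, L))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Score samples for ROH carriage in each bin
#'
#' Entry (sample, bin) is 1 when any of the sample's ROHs overlaps the bin
#' by at least one base.
#'
#' @param rohs ROH records
#' @param bins from \code{\link{makeBins}}
#' @param sample_ids row order of the output (defaults to ids in
#'   \code{rohs})
#' @return binary samples x bins matrix
#' @export
rohBinMatrix <- function(rohs, bins, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- unique(rohs$sample_id)
  mat <- matrix(0L, nrow = length(sample_ids), ncol = nrow(bins),
                dimnames = list(sample_ids, NULL))
  if (nrow(rohs) == 0) return(mat)
  row <- match(rohs$sample_id, sample_ids)
  for (ch in unique(rohs$chrom)) {
    bsel <- which(bins$chrom == ch)
    rsel <- which(rohs$chrom == ch)
    if (!length(bsel) || !length(rsel)) next
    gr_b <- IRanges::IRanges(bins$bp_start[bsel], bins$bp_end[bsel])
    gr_r <- IRanges::IRanges(rohs$bp_start[rsel], rohs$bp_end[rsel])
    hits <- IRanges::findOverlaps(gr_r, gr_b)
    if (length(hits))
      mat[cbind(row[rsel][S4Vectors::queryHits(hits)],
                bsel[S4Vectors::subjectHits(hits)])] <- 1L
  }
  mat
}

# Wald p-value for the last column of the design in a logistic fit;
# returns c(beta, p) or NA on a degenerate fit
.fastLogit <- function(X, y) {
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(c(NA_real_, NA_real_))
  p1 <- seq_len(fit$rank)
  covmat <- tryCatch(chol2inv(fit$qr$qr[p1, p1, drop = FALSE]),
                     error = function(e) NULL)
  if (is.null(covmat)) return(c(NA_real_, NA_real_))
  k <- ncol(X)
  piv <- fit$qr$pivot[p1]
  pos <- match(k, piv)
  if (is.na(pos)) return(c(NA_real_, NA_real_))
  beta <- fit$coefficients[k]
  se <- sqrt(covmat[pos, pos])
  if (!is.finite(se) || se <= 0 || se > 100) return(c(beta, NA_real_))
  c(beta, 2 * stats::pnorm(-abs(beta / se)))
}

# shared design builder: intercept + covariates + dataset indicators
.scanDesign <- function(n, covariates, dataset) {
  X <- matrix(1, nrow = n, ncol = 1)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0)
    X <- cbind(X, as.matrix(as.data.frame(covariates)))
  if (!is.null(dataset) && length(unique(dataset)) > 1)
    X <- cbind(X, stats::model.matrix(~ factor(dataset))[, -1, drop = FALSE])
  X
}

#' Per-bin logistic ROH association scan
#'
#' One logistic regression per bin of case/control status on the bin's ROH
#' carriage indicator, plus covariates and (by default) dataset
#' indicators. Bins carried by no sample or by every sample are skipped.
#'
#' @param mat samples x bins binary matrix from \code{\link{rohBinMatrix}}
#' @param y binary outcome aligned with rows of \code{mat}
#' @param covariates optional covariate data.frame
#' @param dataset optional dataset ids (entered as fixed indicators)
#' @return data.frame: bin, beta, p, minus_log10_p, sign, roh_frequency,
#'   skipped
#' @export
perBinScan <- function(mat, y, covariates = NULL, dataset = NULL) {
  n <- nrow(mat)
  X0 <- .scanDesign(n, covariates, dataset)
  freq <- colMeans(mat)
  out <- data.frame(bin = seq_len(ncol(mat)), beta = NA_real_,
                    p = NA_real_, minus_log10_p = NA_real_,
                    sign = NA_integer_, roh_frequency = freq,
                    skipped = freq <= 0 | freq >= 1)
  X <- cbind(X0, 0)
  k <- ncol(X)
  for (b in which(!out$skipped)) {
    X[, k] <- mat[, b]
    bp <- .fastLogit(X, y)
    out$beta[b] <- bp[1]
    out$p[b] <- bp[2]
  }
  out$skipped <- out$skipped | is.na(out$p)
  out$minus_log10_p <- -log10(out$p)
  out$sign <- sign(out$beta)
  out
}

#' Order-statistic threshold from per-permutation minimum p-values
#'
#' @param minima one minimum p per permutation
#' @param rank which order statistic (the rank-th smallest)
#' @return the threshold p-value
#' @export
permThresholdFromMinima <- function(minima, rank) {
  if (rank < 1 || rank > length(minima))
    stop("rank must lie in 1..length(minima)")
  sort(minima)[rank]
}

#' Permute case/control labels within datasets
#'
#' @param y binary labels
#' @param dataset dataset ids (case:control counts preserved per dataset)
#' @return permuted copy of \code{y}
#' @export
permuteWithinDataset <- function(y, dataset) {
  out <- y
  for (d in unique(dataset)) {
    sel <- which(dataset == d)
    out[sel] <- y[sel][sample.int(length(sel))]
  }
  out
}

#' Permutation significance thresholds for the ROH mapping scan
#'
#' Case/control labels are permuted within each dataset; for each
#' permutation the full per-bin scan is rerun (the same bins skipped as in
#' the real scan) and the minimum p retained. The genome-wide threshold is
#' the \code{rank_gw}-th smallest of these minima and the suggestive
#' threshold the \code{rank_sugg}-th smallest (family-wise error ~
#' rank / n_perm).
#'
#' @param mat,y,covariates,dataset as in \code{\link{perBinScan}}
#' @param n_perm number of permutations (default 1000)
#' @param rank_gw,rank_sugg order statistics (defaults 50 and 100)
#' @param seed RNG seed (required for reproducibility)
#' @return list(genomewide_p, suggestive_p, minima)
#' @export
permutationThresholds <- function(mat, y, covariates = NULL, dataset = NULL,
                                  n_perm = 1000, rank_gw = 50,
                                  rank_sugg = 100, seed) {
  if (n_perm < max(rank_gw, rank_sugg))
    stop("n_perm must be >= the requested ranks")
  set.seed(seed)
  n <- nrow(mat)
  X0 <- .scanDesign(n, covariates, dataset)
  freq <- colMeans(mat)
  tested <- which(freq > 0 & freq < 1)
  X <- cbind(X0, 0)
  k <- ncol(X)
  ds <- if (is.null(dataset)) rep(1L, n) else dataset
  minima <- vapply(seq_len(n_perm), function(r) {
    yp <- permuteWithinDataset(y, ds)
    best <- 1
    for (b in tested) {
      X[, k] <- mat[, b]
      p <- .fastLogit(X, yp)[2]
      if (!is.na(p) && p < best) best <- p
    }
    best
  }, numeric(1))
  list(genomewide_p = permThresholdFromMinima(minima, rank_gw),
       suggestive_p = permThresholdFromMinima(minima, rank_sugg),
       minima = minima)
}

#' Full ROH mapping analysis
#'
#' Bins the autosome, scores ROH carriage, runs the per-bin scan and, when
#' \code{n_perm > 0}, the permutation thresholds.
#'
#' @param x a \linkS4class{SnpCohort} with phenotypes
#' @param rohs ROH records for the samples of \code{x}
#' @param width bin width (default 500 kb)
#' @param chrom_lengths_bp chromosome lengths (defaults to the extent of
#'   the cohort's SNP map)
#' @param covariates optional covariate data.frame
#' @param n_perm permutations for thresholds (0 to skip)
#' @param rank_gw,rank_sugg order statistics for the thresholds
#' @param seed RNG seed for the permutation engine
#' @return a \linkS4class{MappingResult}
#' @export
rohMapping <- function(x, rohs, width = 5e5, chrom_lengths_bp = NULL,
                       covariates = NULL, n_perm = 0, rank_gw = 50,
                       rank_sugg = 100, seed = 1) {
  st <- sampleTable(x)
  map <- snpMap(x)
  if (is.null(chrom_lengths_bp)) {
    chrom_lengths_bp <- vapply(split(map$bp, map$chrom), max, numeric(1))
  }
  bins <- makeBins(chrom_lengths_bp, width)
  mat <- rohBinMatrix(rohs, bins, st$sample_id)
  scan <- perBinScan(mat, st$phenotype, covariates, st$dataset_id)
  gw <- sugg <- NA_real_
  if (n_perm > 0) {
    th <- permutationThresholds(mat, st$phenotype, covariates,
                                st$dataset_id, n_perm, rank_gw, rank_sugg,
                                seed)
    gw <- th$genomewide_p
    sugg <- th$suggestive_p
  }
  methods::new("MappingResult", bins = bins, results = scan,
               genomewideP = gw, suggestiveP = sugg,
               nPerm = as.integer(n_perm))
}
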