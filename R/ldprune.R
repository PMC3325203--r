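#' LD-pruning parameters
#'
#' @param window_snps window size in SNPs (default 50)
#' @param step_snps window step (default 5)
#' @param r2_max multiple-R-squared removal threshold (default 0.90)
#' @return list of parameters
#' @export
pruneParams <- function(window_snps = 50, step_snps = 5, r2_max = 0.90) {
  stopifnot(window_snps >= 2, step_snps >= 1)
  list(window_snps = window_snps, step_snps = step_snps, r2_max = r2_max)
}

# multiple R^2 of column j of z on the other columns (standardized,
# missing already imputed); rank-deficient predictor sets handled by QR
.multipleR2 <- function(z, j, others) {
  y <- z[, j]
  if (!length(others) || stats::var(y) == 0) return(0)
  X <- cbind(1, z[, others, drop = FALSE])
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(0)
  max(0, 1 - rss / tss)
}

#' Prune SNPs in strong linkage disequilibrium
#'
#' Slides a \code{window_snps}-SNP window along each chromosome in map
#' order (step \code{step_snps}). Within a window each SNP is regressed on
#' the other currently retained SNPs of the window (ordinary least squares
#' on standardized calls, missing values mean-imputed); while any SNP has
#' multiple R-squared above \code{r2_max}, the offender at the largest map
#' position is removed, so of a redundant pair the later SNP goes. On exit
#' no retained SNP can be predicted from its retained window-mates above
#' the threshold. The result is deterministic for a fixed input.
#'
#' @param x a \linkS4class{SnpCohort}
#' @param params from \code{\link{pruneParams}}
#' @return character vector of retained snp ids
#' @export
ldPrune <- function(x, params = pruneParams()) {
  calls <- genotypeCalls(x)
  map <- snpMap(x)
  z <- t(calls)  # samples x snps
  mu <- colMeans(z, na.rm = TRUE)
  for (j in seq_len(ncol(z))) {
    nas <- is.na(z[, j])
    if (any(nas)) z[nas, j] <- mu[j]
  }
  z <- scale(z)
  z[is.nan(z)] <- 0
  keep <- rep(TRUE, nrow(map))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    m <- length(idx)
    starts <- unique(c(seq(1, max(1, m - params$window_snps + 1),
                           by = params$step_snps)))
    for (s in starts) {
      win <- idx[s:min(s + params$window_snps - 1, m)]
      repeat {
        ret <- win[keep[win]]
        if (length(ret) < 2) break
        r2 <- vapply(ret, function(j)
          .multipleR2(z, j, setdiff(ret, j)), numeric(1))
        off <- ret[r2 > params$r2_max]
        if (!length(off)) break
        keep[max(off)] <- FALSE
      }
    }
  }
  map$snp_id[keep]
}
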