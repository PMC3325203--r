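#' Approximate autosome lengths
#'
#' Physical lengths (bp) of chromosomes 1-22, rounded to the Mb. Their sum
#' (~2.87e9) is close to, but deliberately distinct from, the SNP-mappable
#' denominator used for Froh (2.77e9), which excludes unmappable sequence.
#' @return named numeric vector of 22 lengths
#' @export
autosomeLengths <- function() {
  stats::setNames(1e6 * c(247, 243, 199, 191, 181, 171, 159, 146, 140, 135,
                          134, 132, 114, 106, 100, 89, 79, 76, 64, 62, 47, 50),
                  as.character(1:22))
}

# Merge possibly-overlapping regions (1-based inclusive data.frame) into a
# disjoint set, per chromosome. Touching spans (end == next start) merge.
mergeRegions <- function(regions) {
  if (nrow(regions) == 0) return(regions[, c("chrom", "bp_start", "bp_end")])
  out <- lapply(split(regions, regions$chrom), function(r) {
    o <- order(r$bp_start)
    s <- r$bp_start[o]; e <- r$bp_end[o]
    ms <- s[1]; me <- e[1]
    ks <- ke <- numeric(0)
    for (i in seq_along(s)[-1]) {
      if (s[i] <= me) me <- max(me, e[i])
      else { ks <- c(ks, ms); ke <- c(ke, me); ms <- s[i]; me <- e[i] }
    }
    data.frame(chrom = r$chrom[1], bp_start = c(ks, ms), bp_end = c(ke, me))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$bp_start), , drop = FALSE]
}

# Total span overlap (end - start metric) of one interval with a set of
# disjoint regions on the same chromosome scale.
spanOverlap <- function(chrom, bp_start, bp_end, regions) {
  if (nrow(regions) == 0) return(0)
  r <- regions[regions$chrom == chrom, , drop = FALSE]
  if (nrow(r) == 0) return(0)
  sum(pmax(0, pmin(bp_end, r$bp_end) - pmax(bp_start, r$bp_start)))
}

# Nagelkerke pseudo R^2 from null and full log-likelihoods
nagelkerkeR2 <- function(ll_null, ll_full, n) {
  cox <- 1 - exp(2 * (ll_null - ll_full) / n)
  maxr2 <- 1 - exp(2 * ll_null / n)
  if (maxr2 <= 0) return(0)
  cox / maxr2
}

# Wald summary helper
waldStats <- function(beta, se) {
  z <- beta / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)),
       ci = beta + c(-1.96, 1.96) * se)
}
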