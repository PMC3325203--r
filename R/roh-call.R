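#' ROH calling parameters
#'
#' Defaults follow the calling rule used throughout the package: at least
#' 65 consecutive homozygous SNPs with no heterozygote calls allowed, a
#' density of at least 1 SNP per 200 kb over the run, and a split wherever
#' adjacent homozygous SNPs are more than 500 kb apart.
#'
#' @param min_snps minimum homozygous SNPs per run (default 65)
#' @param min_density_bp_per_snp maximum bp per SNP over a run (default 2e5)
#' @param max_gap_bp split gap between adjacent homozygous SNPs (default 5e5)
#' @param allowed_het must be 0: heterozygotes always break a run
#' @param allowed_missing 0 (default): missing calls break a run; any
#'   positive value makes missing calls transparent (skipped, not counted)
#' @return list of parameters
#' @export
rohParams <- function(min_snps = 65, min_density_bp_per_snp = 2e5,
                      max_gap_bp = 5e5, allowed_het = 0,
                      allowed_missing = 0) {
  if (min_snps < 2) stop("min_snps must be >= 2")
  if (allowed_het != 0)
    stop("allowed_het must be 0: heterozygote calls always break a run")
  list(min_snps = min_snps, min_density_bp_per_snp = min_density_bp_per_snp,
       max_gap_bp = max_gap_bp, allowed_het = allowed_het,
       allowed_missing = allowed_missing)
}

# core scan for one chromosome: returns matrix of (start_idx, end_idx,
# n_snps) over positions `bp` with genotype vector `calls`
.scanChrom <- function(calls, bp, params) {
  hom <- which(!is.na(calls) & calls != 1L)
  if (!length(hom)) return(NULL)
  breaking <- !is.na(calls) & calls == 1L
  if (params$allowed_missing == 0) breaking <- breaking | is.na(calls)
  nb <- cumsum(breaking)
  if (length(hom) > 1) {
    i <- hom[-length(hom)]; j <- hom[-1]
    sep <- (nb[j] - nb[i]) > 0 | (bp[j] - bp[i]) > params$max_gap_bp
    grp <- cumsum(c(TRUE, sep))
  } else grp <- 1L
  runs <- split(hom, grp)
  out <- lapply(runs, function(r) {
    n <- length(r)
    if (n < params$min_snps) return(NULL)
    len <- bp[r[n]] - bp[r[1]]
    if (len / n > params$min_density_bp_per_snp) return(NULL)
    c(r[1], r[n], n)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Call runs of homozygosity for one genotype vector
#'
#' Finds maximal runs of consecutive homozygous calls (heterozygotes and,
#' by default, missing calls break a run), splits a run wherever adjacent
#' homozygous SNPs are more than \code{max_gap_bp} apart, and keeps runs
#' with at least \code{min_snps} SNPs and a density of no more than
#' \code{min_density_bp_per_snp} bp per SNP.
#'
#' @param calls integer genotype vector in \{0,1,2,NA\}
#' @param map SNP map data.frame aligned with \code{calls}
#' @param params from \code{\link{rohParams}}
#' @param sample_id id recorded on the output rows
#' @return data.frame of ROH records (see \code{\link{rohTable}})
#' @export
callRohs <- function(calls, map, params = rohParams(), sample_id = "sample") {
  if (length(calls) != nrow(map))
    stop("genotype vector and map lengths differ")
  recs <- lapply(unique(map$chrom), function(ch) {
    idx <- which(map$chrom == ch)
    m <- .scanChrom(calls[idx], map$bp[idx], params)
    if (is.null(m)) return(NULL)
    data.frame(sample_id = sample_id, chrom = ch,
               bp_start = map$bp[idx][m[, 1]],
               bp_end = map$bp[idx][m[, 2]],
               n_snps = m[, 3], stringsAsFactors = FALSE)
  })
  recs <- recs[!vapply(recs, is.null, TRUE)]
  if (!length(recs))
    return(rohTable())
  out <- do.call(rbind, recs)
  out$length_bp <- out$bp_end - out$bp_start
  rownames(out) <- NULL
  out
}

#' Call runs of homozygosity for every sample of a cohort
#'
#' @param x a \linkS4class{SnpCohort}
#' @param params from \code{\link{rohParams}}
#' @return data.frame of ROH records for all samples
#' @export
callRohsCohort <- function(x, params = rohParams()) {
  calls <- genotypeCalls(x)
  map <- snpMap(x)
  ids <- sampleTable(x)$sample_id
  out <- lapply(seq_len(ncol(calls)), function(j)
    callRohs(calls[, j], map, params, ids[j]))
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0) return(rohTable())
  rownames(res) <- NULL
  res
}

#' Re-join ROHs split by a probable heterozygote miscall
#'
#' Two adjacent ROHs of the same sample and chromosome are merged when no
#' more than \code{max_bridge_hets} heterozygous calls and no more than
#' \code{max_bridge_bp} separate them. Used for tract-length and
#' generation-depth analyses only, never for Froh itself.
#'
#' @param rohs ROH records (one or more samples)
#' @param x the \linkS4class{SnpCohort} the calls came from
#' @param max_bridge_hets maximum heterozygous calls at a junction (default 1)
#' @param max_bridge_bp maximum bp between joined runs (default 5e5)
#' @return data.frame of ROH records after joining (idempotent)
#' @export
joinMiscallSplit <- function(rohs, x, max_bridge_hets = 1,
                             max_bridge_bp = 5e5) {
  if (nrow(rohs) == 0) return(rohs)
  calls <- genotypeCalls(x)
  map <- snpMap(x)
  ids <- sampleTable(x)$sample_id
  pieces <- split(rohs, list(rohs$sample_id, rohs$chrom), drop = TRUE)
  out <- lapply(pieces, function(r) {
    r <- r[order(r$bp_start), , drop = FALSE]
    if (nrow(r) < 2) return(r)
    j <- match(r$sample_id[1], ids)
    on_chr <- map$chrom == r$chrom[1]
    het_bp <- map$bp[on_chr][!is.na(calls[on_chr, j]) &
                               calls[on_chr, j] == 1L]
    acc <- r[1, , drop = FALSE]
    for (i in 2:nrow(r)) {
      gap <- r$bp_start[i] - acc$bp_end[nrow(acc)]
      hets <- sum(het_bp > acc$bp_end[nrow(acc)] & het_bp < r$bp_start[i])
      if (gap <= max_bridge_bp && hets <= max_bridge_hets) {
        k <- nrow(acc)
        acc$bp_end[k] <- r$bp_end[i]
        acc$n_snps[k] <- acc$n_snps[k] + r$n_snps[i]
        acc$length_bp[k] <- acc$bp_end[k] - acc$bp_start[k]
      } else acc <- rbind(acc, r[i, , drop = FALSE])
    }
    acc
  })
  res <- do.call(rbind, out)
  res <- res[order(res$sample_id, res$chrom, res$bp_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
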