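#' Quality-control thresholds
#'
#' Standard GWAS sample/SNP filters with the defaults used throughout the
#' package: sample missingness > 0.02; sample heterozygosity more than 6 SD
#' above the mean; one member of each pair with relatedness (pi-hat proxy)
#' > 0.2; SNP Hardy-Weinberg p < 1e-6; SNP missingness > 0.02;
#' case/control missingness difference > 0.02; minor-allele-frequency
#' difference to a reference panel > 0.15; MAF < 0.05.
#'
#' @param sample_missing_max,het_sd_max,pihat_max,hwe_p_min,snp_missing_max,maf_diff_max,diff_missing_max,maf_min
#'   threshold overrides
#' @return list of thresholds
#' @export
qcThresholds <- function(sample_missing_max = 0.02, het_sd_max = 6,
                         pihat_max = 0.2, hwe_p_min = 1e-6,
                         snp_missing_max = 0.02, maf_diff_max = 0.15,
                         diff_missing_max = 0.02, maf_min = 0.05) {
  list(sample_missing_max = sample_missing_max, het_sd_max = het_sd_max,
       pihat_max = pihat_max, hwe_p_min = hwe_p_min,
       snp_missing_max = snp_missing_max, maf_diff_max = maf_diff_max,
       diff_missing_max = diff_missing_max, maf_min = maf_min)
}

# standardized genotype relationship matrix (pi-hat proxy): off-diagonal
# entries estimate genome-wide IBD sharing for the relationship classes at
# the 0.2 decision boundary
.relatednessMatrix <- function(calls) {
  p <- rowMeans(calls, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  x <- calls[keep, , drop = FALSE]
  p <- p[keep]
  x <- (x - 2 * p) / sqrt(2 * p * (1 - p))
  x[is.na(x)] <- 0
  crossprod(x) / nrow(x)
}

#' Sample quality control
#'
#' Removes samples with call missingness above threshold, genome-wide
#' heterozygosity more than \code{het_sd_max} SDs above the cohort mean,
#' and one of each pair related above \code{pihat_max} (the member with
#' higher missingness is dropped).
#'
#' @param x a \linkS4class{SnpCohort}
#' @param thresholds from \code{\link{qcThresholds}}
#' @return list(kept = sample ids, report = data.frame(sample_id, reason,
#'   value))
#' @export
sampleQC <- function(x, thresholds = qcThresholds()) {
  calls <- genotypeCalls(x)
  st <- sampleTable(x)
  if (ncol(calls) < 2) stop("sample QC needs at least 2 samples")
  report <- data.frame(sample_id = character(), reason = character(),
                       value = numeric(), stringsAsFactors = FALSE)
  note <- function(ids, reason, values) {
    if (!length(ids)) return()
    report <<- rbind(report, data.frame(sample_id = ids,
                                        reason = rep(reason, length(ids)),
                                        value = values,
                                        stringsAsFactors = FALSE))
  }
  miss <- colMeans(is.na(calls))
  bad_miss <- miss > thresholds$sample_missing_max
  note(st$sample_id[bad_miss], "missingness", miss[bad_miss])
  het <- colMeans(calls == 1L, na.rm = TRUE)
  hlim <- mean(het) + thresholds$het_sd_max * stats::sd(het)
  bad_het <- !bad_miss & het > hlim
  note(st$sample_id[bad_het], "heterozygosity", het[bad_het])
  alive <- which(!(bad_miss | bad_het))
  if (length(alive) >= 2) {
    rel <- .relatednessMatrix(calls[, alive, drop = FALSE])
    pairs <- which(upper.tri(rel) & rel > thresholds$pihat_max, arr.ind = TRUE)
    if (nrow(pairs)) {
      # drop the higher-missingness member of each flagged pair, greedily
      dropped <- logical(length(alive))
      o <- order(rel[pairs], decreasing = TRUE)
      for (r in o) {
        i <- pairs[r, 1]; j <- pairs[r, 2]
        if (dropped[i] || dropped[j]) next
        victim <- if (miss[alive[i]] >= miss[alive[j]]) i else j
        dropped[victim] <- TRUE
        note(st$sample_id[alive[victim]], "relatedness", rel[i, j])
      }
      alive <- alive[!dropped]
    }
  }
  if (!length(alive)) stop("sample QC removed all samples")
  list(kept = st$sample_id[alive], report = report)
}

#' Hardy-Weinberg equilibrium chi-square test (1 df)
#'
#' @param n0,n1,n2 genotype class counts (hom-ref, het, hom-alt)
#' @return list(chisq, p)
#' @export
hweTest <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * n)
  q <- 1 - p
  e <- n * c(q^2, 2 * p * q, p^2)
  o <- cbind(n0, n1, n2)
  e <- cbind(n * q^2, n * 2 * p * q, n * p^2)
  chisq <- rowSums((o - e)^2 / pmax(e, .Machine$double.eps))
  chisq[n == 0 | p == 0 | p == 1] <- 0
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' SNP quality control
#'
#' Applies, in order: Hardy-Weinberg filter (1-df chi-square, computed in
#' controls), SNP missingness, case/control differential missingness,
#' frequency difference to an optional reference panel, and the MAF floor.
#'
#' @param x a \linkS4class{SnpCohort} (phenotypes needed for differential
#'   missingness; when all phenotypes are NA those filters are skipped)
#' @param reference_freqs optional named (by snp_id) reference allele
#'   frequencies of the counted allele
#' @param thresholds from \code{\link{qcThresholds}}
#' @return list(kept = snp ids, report = data.frame(snp_id, reason, value))
#' @export
snpQC <- function(x, reference_freqs = NULL, thresholds = qcThresholds()) {
  calls <- genotypeCalls(x)
  map <- snpMap(x)
  st <- sampleTable(x)
  report <- data.frame(snp_id = character(), reason = character(),
                       value = numeric(), stringsAsFactors = FALSE)
  flag <- function(bad, reason, value) {
    bad[is.na(bad)] <- FALSE
    if (any(bad))
      report <<- rbind(report,
                       data.frame(snp_id = map$snp_id[bad],
                                  reason = rep(reason, sum(bad)),
                                  value = value[bad],
                                  stringsAsFactors = FALSE))
    bad
  }
  ctrl <- !is.na(st$phenotype) & st$phenotype == 0
  hwe_calls <- if (any(ctrl)) calls[, ctrl, drop = FALSE] else calls
  n0 <- rowSums(hwe_calls == 0L, na.rm = TRUE)
  n1 <- rowSums(hwe_calls == 1L, na.rm = TRUE)
  n2 <- rowSums(hwe_calls == 2L, na.rm = TRUE)
  hwe <- hweTest(n0, n1, n2)
  bad <- flag(hwe$p < thresholds$hwe_p_min, "hwe", hwe$p)
  miss <- rowMeans(is.na(calls))
  bad <- bad | flag(!bad & miss > thresholds$snp_missing_max,
                    "missingness", miss)
  if (any(ctrl) && any(st$phenotype == 1, na.rm = TRUE)) {
    case <- !is.na(st$phenotype) & st$phenotype == 1
    dmiss <- abs(rowMeans(is.na(calls[, case, drop = FALSE])) -
                   rowMeans(is.na(calls[, ctrl, drop = FALSE])))
    bad <- bad | flag(!bad & dmiss > thresholds$diff_missing_max,
                      "diff_missingness", dmiss)
  }
  freq <- rowMeans(calls, na.rm = TRUE) / 2
  if (!is.null(reference_freqs)) {
    ref <- reference_freqs[map$snp_id]
    dmaf <- abs(freq - ref)
    bad <- bad | flag(!bad & dmaf > thresholds$maf_diff_max,
                      "maf_vs_reference", dmaf)
  }
  maf <- pmin(freq, 1 - freq)
  maf[is.nan(maf)] <- 0
  bad <- bad | flag(!bad & maf < thresholds$maf_min, "maf", maf)
  list(kept = map$snp_id[!bad], report = report)
}

#' Subset a SnpCohort by sample and/or SNP ids
#'
#' @param x a \linkS4class{SnpCohort}
#' @param samples,snps ids to keep (NULL keeps all)
#' @return a \linkS4class{SnpCohort}
#' @export
subsetCohort <- function(x, samples = NULL, snps = NULL) {
  ri <- if (is.null(snps)) seq_len(nrow(x)) else
    which(snpMap(x)$snp_id %in% snps)
  ci <- if (is.null(samples)) seq_len(ncol(x)) else
    which(sampleTable(x)$sample_id %in% samples)
  st <- sampleTable(x)[ci, , drop = FALSE]
  y <- SnpCohort(snpMap(x)[ri, , drop = FALSE],
                 genotypeCalls(x)[ri, ci, drop = FALSE], st)
  S4Vectors::metadata(y) <- S4Vectors::metadata(x)
  y
}
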