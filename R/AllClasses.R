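#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges colData assay
NULL

#' SnpCohort: genotype calls with SNP map and sample metadata
#'
#' The central container of the package. A \code{SnpCohort} extends
#' \linkS4class{RangedSummarizedExperiment}: the single assay \code{"calls"}
#' holds allele counts (SNPs in rows, samples in columns) coded 0/2 for the
#' two homozygotes, 1 for heterozygotes and \code{NA} for missing calls; the
#' \code{rowRanges} carry the SNP map (autosomal chromosome, 1-based physical
#' position, genetic position in centiMorgans, allele labels); \code{colData}
#' carries the sample table (\code{sample_id}, \code{dataset_id},
#' \code{phenotype} coded 0 = control / 1 = case, plus optional covariates).
#'
#' Invariants enforced by the validity method: positions strictly increasing
#' within each chromosome, chromosomes 1-22 in ascending order, unique sample
#' identifiers, and calls restricted to \{0, 1, 2, NA\}.
#'
#' @slot truth optional list of per-sample simulation truth (see
#'   \code{\link{simulateCohort}}).
#'
#' @seealso \code{\link{SnpCohort}} (constructor), \code{\link{snpMap}},
#'   \code{\link{genotypeCalls}}, \code{\link{sampleTable}}
#' @aliases SnpCohort-class
#' @exportClass SnpCohort
setClass("SnpCohort",
  contains = "RangedSummarizedExperiment"
)

.validSnpCohort <- function(object) {
  msg <- character()
  if (!("calls" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'calls' is required")
  else {
    calls <- SummarizedExperiment::assay(object, "calls")
    bad <- calls[!is.na(calls)]
    if (length(bad) && !all(bad %in% c(0L, 1L, 2L)))
      msg <- c(msg, "calls must be 0, 1, 2 or NA")
  }
  map <- SummarizedExperiment::rowRanges(object)
  chrom <- as.integer(as.character(GenomicRanges::seqnames(map)))
  if (anyNA(chrom) || !all(chrom %in% 1:22))
    msg <- c(msg, "chromosomes must be autosomes named 1-22")
  else {
    if (is.unsorted(chrom))
      msg <- c(msg, "chromosomes must be in ascending order")
    bp <- GenomicRanges::start(map)
    for (ch in unique(chrom)) {
      b <- bp[chrom == ch]
      if (any(diff(b) <= 0)) {
        msg <- c(msg, sprintf("bp not strictly increasing on chromosome %d", ch))
        break
      }
    }
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("sample_id", "dataset_id", "phenotype") %in% colnames(cd)))
    msg <- c(msg, "colData requires sample_id, dataset_id, phenotype")
  else if (anyDuplicated(cd$sample_id))
    msg <- c(msg, "sample_id must be unique")
  if (length(msg)) msg else TRUE
}
setValidity("SnpCohort", .validSnpCohort)

#' Construct a SnpCohort from a SNP map, a call matrix and a sample table
#'
#' @param map data.frame with columns \code{snp_id}, \code{chrom} (integer
#'   1-22), \code{bp} (1-based physical position), and optionally \code{cm}
#'   (genetic position, centiMorgans), \code{a1}, \code{a2} (allele labels).
#'   When \code{cm} is absent it is derived as \code{bp * 1e-6} (1 cM/Mb).
#' @param calls integer matrix, SNPs x samples, values in \{0,1,2,NA\}.
#' @param samples data.frame with columns \code{sample_id},
#'   \code{dataset_id}, \code{phenotype} (0/1) and optional covariates.
#' @return a \linkS4class{SnpCohort}
#' @examples
#' map <- data.frame(snp_id = c("rs1", "rs2"), chrom = 1L, bp = c(100L, 200L))
#' calls <- matrix(c(0L, 1L, 2L, NA), nrow = 2)
#' samples <- data.frame(sample_id = c("s1", "s2"),
#'                       dataset_id = "d1", phenotype = c(0L, 1L))
#' SnpCohort(map, calls, samples)
#' @export
SnpCohort <- function(map, calls, samples) {
  map <- normalizeSnpMap(map)
  calls <- matrix(as.integer(calls), nrow = nrow(calls),
                  dimnames = list(map$snp_id, samples$sample_id))
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(map$chrom),
    ranges = IRanges::IRanges(start = map$bp, width = 1L),
    snp_id = map$snp_id, cm = map$cm, a1 = map$a1, a2 = map$a2
  )
  names(gr) <- map$snp_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = calls),
    rowRanges = gr,
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample_id)
  )
  methods::new("SnpCohort", se)
}

#' Normalize and validate a SNP map data.frame
#'
#' Sorts by chromosome then position, checks the map invariants and fills in
#' defaults (genetic position at 1 cM/Mb, placeholder allele labels).
#' @param map data.frame; see \code{\link{SnpCohort}}.
#' @return data.frame with columns snp_id, chrom, bp, cm, a1, a2
#' @export
normalizeSnpMap <- function(map) {
  stopifnot(all(c("snp_id", "chrom", "bp") %in% names(map)))
  map$chrom <- as.integer(map$chrom)
  map$bp <- as.integer(map$bp)
  if (!all(map$chrom %in% 1:22))
    stop("chrom must be an autosome number 1-22")
  o <- order(map$chrom, map$bp)
  map <- map[o, , drop = FALSE]
  if (is.null(map$cm)) map$cm <- map$bp * 1e-6
  if (is.null(map$a1)) map$a1 <- "A"
  if (is.null(map$a2)) map$a2 <- "B"
  dup <- unlist(lapply(split(map$bp, map$chrom), function(b) any(diff(b) <= 0)))
  if (any(dup))
    stop("bp must be strictly increasing within chromosome")
  rownames(map) <- NULL
  map
}

#' @describeIn SnpCohort-accessors SNP map as a data.frame
#' @export
snpMap <- function(x) {
  gr <- SummarizedExperiment::rowRanges(x)
  data.frame(
    snp_id = gr$snp_id,
    chrom = as.integer(as.character(GenomicRanges::seqnames(gr))),
    bp = GenomicRanges::start(gr),
    cm = gr$cm, a1 = gr$a1, a2 = gr$a2,
    stringsAsFactors = FALSE
  )
}

#' Accessors for SnpCohort
#'
#' \code{genotypeCalls} returns the SNPs x samples integer call matrix,
#' \code{snpMap} the SNP map as a data.frame, and \code{sampleTable} the
#' sample table as a data.frame.
#' @param x a \linkS4class{SnpCohort}
#' @name SnpCohort-accessors
#' @export
genotypeCalls <- function(x) SummarizedExperiment::assay(x, "calls")

#' @describeIn SnpCohort-accessors sample table as a data.frame
#' @export
sampleTable <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
}

setMethod("show", "SnpCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("SnpCohort: %d SNPs x %d samples\n", nrow(object), ncol(object)))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(as.character(GenomicRanges::seqnames(
                SummarizedExperiment::rowRanges(object)))), collapse = ", ")))
  cat(sprintf("  datasets: %d; cases: %d; controls: %d\n",
              length(unique(cd$dataset_id)),
              sum(cd$phenotype == 1), sum(cd$phenotype == 0)))
  miss <- mean(is.na(SummarizedExperiment::assay(object, "calls")))
  cat(sprintf("  missing call rate: %.4f\n", miss))
})

#' BurdenFit: a fitted autozygosity burden model
#'
#' Holds the slope of case/control status on Froh from a logistic (or
#' mixed-effects logistic) regression, its Wald statistics, the odds ratio
#' per 1\% Froh, and the Nagelkerke pseudo R-squared.
#'
#' @slot beta log-odds per unit Froh
#' @slot se Wald standard error of beta
#' @slot z Wald z statistic (beta / se)
#' @slot p two-sided Wald p-value
#' @slot or1pct exp(0.01 * beta): odds multiplier per 0.01 increase in Froh
#' @slot ci95 beta +/- 1.96 se
#' @slot nagelkerkeR2 Nagelkerke pseudo R-squared
#' @slot n number of samples in the fit
#' @slot model "per_dataset" or "mixed"
#' @slot converged FALSE when the fit is degenerate (e.g. separation)
#' @slot note free-text diagnostic
#' @aliases BurdenFit-class
#' @exportClass BurdenFit
setClass("BurdenFit", representation(
  beta = "numeric", se = "numeric", z = "numeric", p = "numeric",
  or1pct = "numeric", ci95 = "numeric", nagelkerkeR2 = "numeric",
  n = "integer", model = "character", converged = "logical",
  note = "character"
))

setValidity("BurdenFit", function(object) {
  msg <- character()
  if (length(object@ci95) != 2) msg <- c(msg, "ci95 must have length 2")
  if (object@converged && is.finite(object@se) && object@se > 0 &&
      abs(object@z - object@beta / object@se) > 1e-8)
    msg <- c(msg, "z must equal beta/se")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BurdenFit", function(object) {
  cat(sprintf("BurdenFit (%s model, n = %d)\n", object@model, object@n))
  cat(sprintf("  beta = %.3f (se %.3f), z = %.3f, p = %.3g\n",
              object@beta, object@se, object@z, object@p))
  cat(sprintf("  OR per 1%% Froh = %.4f;  95%% CI(beta) = [%.3f, %.3f]\n",
              object@or1pct, object@ci95[1], object@ci95[2]))
  cat(sprintf("  Nagelkerke R2 = %.4f%s\n", object@nagelkerkeR2,
              if (!object@converged) "  [NOT CONVERGED]" else ""))
  if (nzchar(object@note)) cat("  note:", object@note, "\n")
})

#' @describeIn BurdenFit-class coefficients as a named list
#' @param object,x a BurdenFit
#' @export
burdenCoef <- function(x) {
  list(beta = x@beta, se = x@se, z = x@z, p = x@p, or_1pct = x@or1pct,
       ci95_beta = x@ci95, nagelkerke_r2 = x@nagelkerkeR2, n = x@n,
       model = x@model, converged = x@converged)
}

#' MappingResult: bin-level ROH association scan
#'
#' @slot bins data.frame of the 500 kb (by default) bin grid
#'   (chrom, bp_start, bp_end)
#' @slot results data.frame per bin: beta, p, minus_log10_p, sign,
#'   roh_frequency, skipped
#' @slot genomewideP permutation genome-wide significance threshold
#' @slot suggestiveP permutation suggestive threshold
#' @slot nPerm number of permutations behind the thresholds
#' @aliases MappingResult-class
#' @exportClass MappingResult
setClass("MappingResult", representation(
  bins = "data.frame", results = "data.frame",
  genomewideP = "numeric", suggestiveP = "numeric", nPerm = "integer"
))

setMethod("show", "MappingResult", function(object) {
  cat(sprintf("MappingResult: %d bins (%d tested)\n",
              nrow(object@bins), sum(!object@results$skipped)))
  if (is.finite(object@genomewideP))
    cat(sprintf("  thresholds (n_perm = %d): genome-wide p <= %.3g, suggestive p <= %.3g\n",
                object@nPerm, object@genomewideP, object@suggestiveP))
  hits <- sum(!object@results$skipped &
                object@results$p <= object@suggestiveP, na.rm = TRUE)
  if (is.finite(object@suggestiveP))
    cat(sprintf("  bins at or below suggestive threshold: %d\n", hits))
})
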