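#' Label ROHs as common or uncommon by allelic matching
#'
#' ROHs pooled across all samples are grouped by physical overlap
#' (single-linkage over pairs with at least \code{reciprocal_overlap}
#' reciprocal span overlap). Within a group, two ROHs "match" when their
#' homozygous-genotype identity over the group consensus region (the
#' intersection of the group's spans, falling back to the pairwise overlap
#' when the intersection is empty) is at least \code{identity_min}. An ROH
#' matching \code{uncommon_max_matches} or fewer others is labelled
#' uncommon; all others are common.
#'
#' @param rohs ROH records pooled across samples
#' @param x the \linkS4class{SnpCohort} the calls came from
#' @param identity_min minimum genotype identity for a match (default 0.95)
#' @param uncommon_max_matches an ROH with this many matches or fewer is
#'   uncommon (default 16)
#' @param reciprocal_overlap grouping threshold (default 0.5)
#' @return character vector ("common"/"uncommon") aligned with
#'   \code{rohs} rows; match counts as attribute \code{"n_matches"}
#' @export
matchRohs <- function(rohs, x, identity_min = 0.95,
                      uncommon_max_matches = 16, reciprocal_overlap = 0.5) {
  n <- nrow(rohs)
  n_matches <- integer(n)
  if (n) {
    calls <- genotypeCalls(x)
    map <- snpMap(x)
    col <- match(rohs$sample_id, sampleTable(x)$sample_id)
    gr <- GenomicRanges::GRanges(as.character(rohs$chrom),
                                 IRanges::IRanges(rohs$bp_start,
                                                  rohs$bp_end))
    hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    sel <- qh < sh
    qh <- qh[sel]; sh <- sh[sel]
    if (length(qh)) {
      ov <- pmin(rohs$bp_end[qh], rohs$bp_end[sh]) -
        pmax(rohs$bp_start[qh], rohs$bp_start[sh])
      recip <- ov / rohs$length_bp[qh] >= reciprocal_overlap &
        ov / rohs$length_bp[sh] >= reciprocal_overlap
      qh <- qh[recip]; sh <- sh[recip]
    }
    # single-linkage grouping by union-find
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (k in seq_along(qh)) {
      a <- find(qh[k]); b <- find(sh[k])
      if (a != b) parent[b] <- a
    }
    root <- vapply(seq_len(n), find, 1L)
    for (g in unique(root)) {
      members <- which(root == g)
      if (length(members) < 2) next
      cs <- max(rohs$bp_start[members])
      ce <- min(rohs$bp_end[members])
      chrom <- rohs$chrom[members[1]]
      pre <- if (ce > cs)
        which(map$chrom == chrom & map$bp >= cs & map$bp <= ce) else integer()
      for (a in seq_along(members)[-length(members)]) {
        for (b in (a + 1):length(members)) {
          i <- members[a]; j <- members[b]
          snps <- pre
          if (!length(snps)) {
            s <- max(rohs$bp_start[i], rohs$bp_start[j])
            e <- min(rohs$bp_end[i], rohs$bp_end[j])
            if (e <= s) next
            snps <- which(map$chrom == chrom & map$bp >= s & map$bp <= e)
            if (!length(snps)) next
          }
          gi <- calls[snps, col[i]]; gj <- calls[snps, col[j]]
          ident <- mean(!is.na(gi) & !is.na(gj) & gi == gj & gi != 1L)
          if (ident >= identity_min) {
            n_matches[i] <- n_matches[i] + 1L
            n_matches[j] <- n_matches[j] + 1L
          }
        }
      }
    }
  }
  labels <- ifelse(n_matches <= uncommon_max_matches, "uncommon", "common")
  attr(labels, "n_matches") <- n_matches
  labels
}

#' Flag ROHs that may be hemizygous deletions rather than autozygosity
#'
#' An ROH is a "possible deletion" when its length, after removing its
#' overlap with known deletion regions, falls strictly below
#' \code{residual_min_bp}.
#'
#' @param rohs ROH records
#' @param deletions data.frame(chrom, bp_start, bp_end) of deletion calls;
#'   an optional \code{sample_id} column restricts each deletion to its
#'   carrier
#' @param residual_min_bp residual-length threshold (default 5e5; strict <)
#' @return logical vector aligned with \code{rohs} rows
#' @export
classifyPossibleDeletion <- function(rohs, deletions,
                                     residual_min_bp = 5e5) {
  n <- nrow(rohs)
  if (n == 0) return(logical(0))
  per_sample <- "sample_id" %in% names(deletions)
  merged_all <- if (!per_sample) mergeRegions(deletions) else NULL
  flags <- logical(n)
  for (i in seq_len(n)) {
    d <- if (per_sample)
      mergeRegions(deletions[deletions$sample_id == rohs$sample_id[i], ,
                             drop = FALSE])
    else merged_all
    ov <- spanOverlap(rohs$chrom[i], rohs$bp_start[i], rohs$bp_end[i], d)
    flags[i] <- (rohs$length_bp[i] - ov) < residual_min_bp
  }
  flags
}
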