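#' The SNP-mappable autosomal distance used as the Froh denominator
#' @export
FROH_DENOMINATOR_BP <- 2.77e9

#' Compute Froh and its decompositions
#'
#' Froh is the summed ROH length divided by the SNP-mappable autosomal
#' distance (2.77e9 bp by default). ROHs shorter than 5 Mb contribute to
#' \code{froh_short}, those of 5 Mb or more to \code{froh_long}; when
#' common/uncommon labels are supplied (\code{\link{matchRohs}}) the
#' frequency decomposition is filled in as well. Both decompositions sum
#' to \code{froh} exactly.
#'
#' @param rohs ROH records (any number of samples)
#' @param denominator_bp Froh denominator (default \code{FROH_DENOMINATOR_BP})
#' @param labels optional per-ROH character vector, "common"/"uncommon",
#'   aligned with the rows of \code{rohs}
#' @param sample_ids ids to report (zero-ROH samples get froh 0); defaults
#'   to the ids present in \code{rohs}
#' @param split_bp short/long boundary (default 5e6; length >= split_bp is
#'   long)
#' @return data.frame: sample_id, froh, froh_short, froh_long, froh_common,
#'   froh_uncommon, n_roh, mean_roh_length_bp
#' @export
computeFroh <- function(rohs, denominator_bp = FROH_DENOMINATOR_BP,
                        labels = NULL, sample_ids = NULL, split_bp = 5e6) {
  if (denominator_bp <= 0) stop("denominator_bp must be positive")
  if (is.null(sample_ids)) sample_ids <- unique(rohs$sample_id)
  if (!is.null(labels) && length(labels) != nrow(rohs))
    stop("labels must align with rohs rows")
  out <- data.frame(sample_id = sample_ids,
                    froh = 0, froh_short = 0, froh_long = 0,
                    froh_common = NA_real_, froh_uncommon = NA_real_,
                    n_roh = 0L, mean_roh_length_bp = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    out$froh_common <- 0
    out$froh_uncommon <- 0
  }
  if (nrow(rohs) == 0) return(out)
  idx <- match(rohs$sample_id, sample_ids)
  if (anyNA(idx)) stop("rohs contain samples absent from sample_ids")
  tot <- rowsum(rohs$length_bp, idx)
  who <- as.integer(rownames(tot))
  out$froh[who] <- tot[, 1] / denominator_bp
  short <- rohs$length_bp < split_bp
  if (any(short)) {
    t2 <- rowsum(rohs$length_bp[short], idx[short])
    out$froh_short[as.integer(rownames(t2))] <- t2[, 1] / denominator_bp
  }
  out$froh_long <- out$froh - out$froh_short
  if (!is.null(labels)) {
    com <- labels == "common"
    if (any(com)) {
      t3 <- rowsum(rohs$length_bp[com], idx[com])
      out$froh_common[as.integer(rownames(t3))] <- t3[, 1] / denominator_bp
    }
    out$froh_uncommon <- out$froh - out$froh_common
  }
  cnt <- rowsum(rep(1L, nrow(rohs)), idx)
  out$n_roh[as.integer(rownames(cnt))] <- cnt[, 1]
  out$mean_roh_length_bp[who] <- tot[, 1] / out$n_roh[who]
  out
}

#' Recompute Froh with genomic regions excluded
#'
#' Each ROH's overlap with the (merged) excluded regions is subtracted
#' from its length before summing; used to assess how much identified hit
#' regions drive the overall burden signal.
#'
#' @param rohs ROH records
#' @param regions data.frame(chrom, bp_start, bp_end) to exclude
#' @param denominator_bp Froh denominator
#' @param sample_ids see \code{\link{computeFroh}}
#' @return data.frame as \code{\link{computeFroh}} (short/long split applied
#'   to the reduced lengths)
#' @export
frohExcluding <- function(rohs, regions,
                          denominator_bp = FROH_DENOMINATOR_BP,
                          sample_ids = NULL) {
  if (nrow(rohs) == 0 || nrow(regions) == 0)
    return(computeFroh(rohs, denominator_bp, sample_ids = sample_ids))
  merged <- mergeRegions(regions)
  reduced <- rohs
  for (i in seq_len(nrow(reduced))) {
    ov <- spanOverlap(reduced$chrom[i], reduced$bp_start[i],
                      reduced$bp_end[i], merged)
    reduced$length_bp[i] <- reduced$length_bp[i] - ov
  }
  reduced <- reduced[reduced$length_bp > 0, , drop = FALSE]
  if (is.null(sample_ids)) sample_ids <- unique(rohs$sample_id)
  computeFroh(reduced, denominator_bp, sample_ids = sample_ids)
}
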