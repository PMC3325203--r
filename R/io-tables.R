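.ROH_COLS <- c("sample_id", "chrom", "bp_start", "bp_end", "n_snps", "length_bp")

#' Create a table of ROH records
#'
#' ROH calls are held as a plain data.frame with one row per run of
#' homozygosity: \code{sample_id}, \code{chrom}, \code{bp_start},
#' \code{bp_end} (1-based, inclusive of the first/last homozygous SNP),
#' \code{n_snps} (homozygous SNPs in the run) and
#' \code{length_bp = bp_end - bp_start}.
#'
#' @param sample_id,chrom,bp_start,bp_end,n_snps vectors of equal length
#' @return data.frame of ROH records
#' @export
rohTable <- function(sample_id = character(), chrom = integer(),
                     bp_start = integer(), bp_end = integer(),
                     n_snps = integer()) {
  df <- data.frame(sample_id = as.character(sample_id),
                   chrom = as.integer(chrom),
                   bp_start = as.numeric(bp_start),
                   bp_end = as.numeric(bp_end),
                   n_snps = as.integer(n_snps),
                   stringsAsFactors = FALSE)
  df$length_bp <- df$bp_end - df$bp_start
  if (nrow(df) && any(df$length_bp <= 0))
    stop("bp_end must exceed bp_start")
  df
}

#' Read and write ROH tables
#'
#' Tab-separated with a header; \code{readRohTable(writeRohTable(x)) == x}.
#' @param rohs data.frame of ROH records (see \code{\link{rohTable}})
#' @param path file path
#' @return \code{readRohTable}: data.frame of ROH records
#' @export
writeRohTable <- function(rohs, path) {
  stopifnot(all(.ROH_COLS %in% names(rohs)))
  utils::write.table(rohs[, .ROH_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeRohTable
#' @export
readRohTable <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "numeric",
                                         "numeric", "integer", "numeric"))
  if (!identical(names(df), .ROH_COLS))
    stop("not an ROH table: ", path)
  df
}

#' Read genomic regions from a BED file
#'
#' BED intervals are 0-based half-open; they are converted at the boundary
#' to the package's 1-based inclusive convention (start + 1, end). Used for
#' deletion calls and region exclusion lists.
#'
#' @param path BED file (3+ columns)
#' @return data.frame with chrom, bp_start, bp_end, label
#' @export
readRegionsBed <- function(path) {
  info <- file.info(path)
  if (is.na(info$size)) stop("BED file not found: ", path)
  if (info$size == 0 || length(readLines(path, n = 1)) == 0)
    return(data.frame(chrom = integer(), bp_start = numeric(),
                      bp_end = numeric(), label = character(),
                      stringsAsFactors = FALSE))
  gr <- rtracklayer::import(path, format = "BED")
  if (any(GenomicRanges::width(gr) <= 0))
    stop("BED interval with end <= start in ", path)
  label <- if (!is.null(gr$name)) as.character(gr$name)
           else rep(NA_character_, length(gr))
  data.frame(chrom = as.integer(as.character(GenomicRanges::seqnames(gr))),
             bp_start = GenomicRanges::start(gr),
             bp_end = GenomicRanges::end(gr),
             label = label, stringsAsFactors = FALSE)
}

#' Write genomic regions to a BED file
#'
#' Converts the internal 1-based inclusive intervals back to BED's 0-based
#' half-open convention, so \code{readRegionsBed(writeRegionsBed(x))} is the
#' identity.
#' @param regions data.frame with chrom, bp_start, bp_end and optional label
#' @param path output path
#' @export
writeRegionsBed <- function(regions, path) {
  if (nrow(regions) && any(regions$bp_end <= regions$bp_start))
    stop("regions must have bp_end > bp_start")
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(regions$chrom),
    ranges = IRanges::IRanges(start = regions$bp_start, end = regions$bp_end))
  if (!is.null(regions$label) && !all(is.na(regions$label)))
    gr$name <- regions$label
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
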