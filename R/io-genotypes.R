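#' Read SNP genotypes into a SnpCohort
#'
#' Reads either a PLINK text PED/MAP pair or a VCF (GT field) into the
#' package's \linkS4class{SnpCohort} container. Allele pairs are mapped to
#' allele counts in \{0, 1, 2\}; unparseable or missing calls become
#' \code{NA}.
#'
#' @param path for \code{format = "ped_map"}, the file prefix (reads
#'   \code{<path>.ped} and \code{<path>.map}) or the path of the .ped file;
#'   for \code{format = "vcf"} the VCF path.
#' @param format one of \code{"ped_map"}, \code{"vcf"}.
#' @param samples optional data.frame overriding the sample table (matched
#'   by \code{sample_id}); useful for VCF input, which carries no phenotype.
#' @return a \linkS4class{SnpCohort}
#' @export
readGenotypes <- function(path, format = c("ped_map", "vcf"), samples = NULL) {
  format <- match.arg(format)
  x <- switch(format,
    ped_map = readPedMap(path),
    vcf = readVcfGenotypes(path)
  )
  if (!is.null(samples)) {
    st <- sampleTable(x)
    idx <- match(st$sample_id, samples$sample_id)
    if (anyNA(idx)) stop("samples table does not cover all genotyped samples")
    x <- SnpCohort(snpMap(x), genotypeCalls(x), samples[idx, , drop = FALSE])
  }
  x
}

#' @rdname readGenotypes
#' @export
readPedMap <- function(path) {
  ped_path <- if (grepl("\\.ped$", path)) path else paste0(path, ".ped")
  map_path <- sub("\\.ped$", ".map", ped_path)
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)

  map_raw <- utils::read.table(map_path, header = FALSE,
                               colClasses = c("character", "character",
                                              "numeric", "integer"))
  names(map_raw) <- c("chrom", "snp_id", "cm", "bp")
  m <- nrow(map_raw)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  if (n == 0) stop("PED file is empty")

  calls <- matrix(NA_integer_, nrow = m, ncol = n)
  fam <- sam <- character(n)
  phe <- integer(n)
  a1 <- a2 <- rep(NA_character_, m)
  tok_list <- strsplit(lines, "[ \t]+")
  for (i in seq_len(n)) {
    tok <- tok_list[[i]]
    if (length(tok) != 6 + 2 * m)
      stop(sprintf("malformed PED line %d: expected %d fields, found %d",
                   i, 6 + 2 * m, length(tok)))
    fam[i] <- tok[1]; sam[i] <- tok[2]
    phe[i] <- switch(tok[6], "2" = 1L, "1" = 0L, NA_integer_)
    al1 <- tok[seq(7, by = 2, length.out = m)]
    al2 <- tok[seq(8, by = 2, length.out = m)]
    ok <- al1 != "0" & al2 != "0"
    # record the (at most two) allele labels seen at each SNP
    new1 <- ok & is.na(a1)
    a1[new1] <- al1[new1]
    hit2 <- ok & !is.na(a1) & al1 != a1 & is.na(a2)
    a2[hit2] <- al1[hit2]
    hit2 <- ok & !is.na(a1) & al2 != a1 & is.na(a2)
    a2[hit2] <- al2[hit2]
    calls[, i] <- ifelse(ok, (al1 != a1) + (al2 != a1), NA_integer_)
  }
  if (anyDuplicated(sam)) stop("duplicated sample_id in PED: ",
                               paste(sam[duplicated(sam)], collapse = ", "))
  # orient counts so genotype = copies of a2, alleles sorted alphabetically
  swap <- !is.na(a1) & !is.na(a2) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
    calls[swap, ] <- 2L - calls[swap, , drop = FALSE]
  }
  a1[is.na(a1)] <- "A"; a2[is.na(a2)] <- "B"
  map <- data.frame(snp_id = map_raw$snp_id,
                    chrom = as.integer(map_raw$chrom),
                    bp = map_raw$bp, cm = map_raw$cm,
                    a1 = a1, a2 = a2, stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sam, dataset_id = fam, phenotype = phe,
                        stringsAsFactors = FALSE)
  o <- order(map$chrom, map$bp)
  SnpCohort(map[o, ], calls[o, , drop = FALSE], samples)
}

#' Write a SnpCohort as a PLINK text PED/MAP pair
#'
#' @param x a \linkS4class{SnpCohort}
#' @param path output file prefix (writes \code{<path>.ped}, \code{<path>.map})
#' @return invisibly, the two file paths
#' @export
writePedMap <- function(x, path) {
  map <- snpMap(x)
  calls <- genotypeCalls(x)
  st <- sampleTable(x)
  map_path <- paste0(path, ".map")
  ped_path <- paste0(path, ".ped")
  utils::write.table(
    data.frame(map$chrom, map$snp_id, map$cm, map$bp),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (j in seq_len(ncol(calls))) {
    g <- calls[, j]
    al1 <- ifelse(is.na(g), "0", ifelse(g >= 1, map$a2, map$a1))
    al2 <- ifelse(is.na(g), "0", ifelse(g == 2, map$a2, map$a1))
    pheno <- if (is.na(st$phenotype[j])) "0" else as.character(st$phenotype[j] + 1L)
    writeLines(paste(c(st$dataset_id[j], st$sample_id[j], "0", "0", "0",
                       pheno, as.vector(rbind(al1, al2))), collapse = " "),
               con)
  }
  invisible(c(ped_path, map_path))
}

#' @rdname readGenotypes
#' @export
readVcfGenotypes <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, colnames(v@gt)[-1]))
  gt <- gsub("|", "/", gt, fixed = TRUE)
  calls <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  calls[gt == "0/0"] <- 0L
  calls[gt %in% c("0/1", "1/0")] <- 1L
  calls[gt == "1/1"] <- 2L
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0("snp", which(is.na(ids) | ids == "."))
  map <- data.frame(snp_id = ids,
                    chrom = as.integer(fix[, "CHROM"]),
                    bp = as.integer(fix[, "POS"]),
                    a1 = fix[, "REF"], a2 = fix[, "ALT"],
                    stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = colnames(gt),
                        dataset_id = "dataset1",
                        phenotype = NA_integer_,
                        stringsAsFactors = FALSE)
  o <- order(map$chrom, map$bp)
  SnpCohort(map[o, ], calls[o, , drop = FALSE], samples)
}

#' Write a SnpCohort as a minimal VCF (GT only)
#'
#' @param x a \linkS4class{SnpCohort}
#' @param path output VCF path
#' @return invisibly, \code{path}
#' @export
writeVcfGenotypes <- function(x, path) {
  map <- snpMap(x)
  calls <- genotypeCalls(x)
  st <- sampleTable(x)
  gt <- matrix("./.", nrow = nrow(calls), ncol = ncol(calls))
  gt[calls == 0L] <- "0/0"
  gt[calls == 1L] <- "0/1"
  gt[calls == 2L] <- "1/1"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", st$sample_id), collapse = "\t")), con)
  body <- cbind(map$chrom, map$bp, map$snp_id, map$a1, map$a2,
                ".", ".", ".", "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}
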