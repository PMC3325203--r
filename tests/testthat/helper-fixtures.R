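# Independent brute-force ROH enumerator: walks each maximal qualifying run
# explicitly, SNP by SNP. Used as the oracle for callRohs.
bruteRohs <- function(calls, map, params = rohParams(), sample_id = "s") {
  out <- list()
  for (ch in unique(map$chrom)) {
    sel <- map$chrom == ch
    g <- calls[sel]
    bp <- map$bp[sel]
    m <- length(g)
    is_hom <- function(k) !is.na(g[k]) && g[k] != 1L
    i <- 1
    while (i <= m) {
      if (!is_hom(i)) { i <- i + 1; next }
      # maximal-run start: previous SNP non-hom or gap too large
      if (i > 1 && is_hom(i - 1) && bp[i] - bp[i - 1] <= params$max_gap_bp) {
        i <- i + 1; next
      }
      j <- i
      while (j < m && is_hom(j + 1) &&
             bp[j + 1] - bp[j] <= params$max_gap_bp) j <- j + 1
      ns <- j - i + 1
      len <- bp[j] - bp[i]
      if (ns >= params$min_snps && len / ns <= params$min_density_bp_per_snp)
        out[[length(out) + 1]] <- data.frame(
          sample_id = sample_id, chrom = ch, bp_start = bp[i],
          bp_end = bp[j], n_snps = ns, length_bp = len)
      i <- j + 1
    }
  }
  if (!length(out)) return(rohTable())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# canonical column types/order for exact ROH-table comparison
canonRoh <- function(d) {
  d <- d[order(d$sample_id, d$chrom, d$bp_start),
         c("sample_id", "chrom", "bp_start", "bp_end", "n_snps",
           "length_bp")]
  d$chrom <- as.integer(d$chrom)
  d$bp_start <- as.numeric(d$bp_start)
  d$bp_end <- as.numeric(d$bp_end)
  d$n_snps <- as.integer(d$n_snps)
  d$length_bp <- as.numeric(d$length_bp)
  rownames(d) <- NULL
  d
}

# uniform 30 kb map on one chromosome
gridMap <- function(n, spacing = 30000, chrom = 1L) {
  data.frame(snp_id = paste0("s", seq_len(n)), chrom = chrom,
             bp = seq_len(n) * spacing, cm = seq_len(n) * spacing * 1e-6,
             a1 = "A", a2 = "B", stringsAsFactors = FALSE)
}

# tiny all-homozygous cohort wrapper around a single genotype vector
vectorCohort <- function(calls, map, phenotype = 0L) {
  SnpCohort(map, matrix(as.integer(calls), ncol = 1),
            data.frame(sample_id = "s", dataset_id = "d1",
                       phenotype = phenotype))
}

# random genotype/map instance for oracle tests
randomInstance <- function(n_snps = 120) {
  spacing <- sample(c(20000, 30000, 150000), 1)
  bp <- cumsum(sample(c(spacing, spacing, 600000), n_snps, replace = TRUE,
                      prob = c(.6, .3, .1)))
  calls <- sample(c(0L, 1L, 2L, NA), n_snps, replace = TRUE,
                  prob = c(.42, .12, .42, .04))
  list(calls = calls,
       map = data.frame(snp_id = paste0("s", seq_len(n_snps)), chrom = 1L,
                        bp = bp, cm = bp * 1e-6, a1 = "A", a2 = "B"))
}
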