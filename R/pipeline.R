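#' Assemble a pipeline configuration
#'
#' A plain list understood by \code{\link{runPipeline}}; can be written to
#' or read from YAML/JSON. All calling thresholds default to the package
#' defaults and every stage can be toggled.
#'
#' @param seed global seed; per-stage child seeds are derived from it
#' @param outdir output directory
#' @param sim list of \code{\link{simConfig}} overrides (ignored when
#'   \code{input} is given)
#' @param input optional list(path, format) read via
#'   \code{\link{readGenotypes}} instead of simulating
#' @param stages character vector among simulate, qc, prune, roh, burden,
#'   map
#' @param qc,prune,roh lists of threshold overrides
#' @param burden list(n_pcs, sweep_grid, sensitivity)
#' @param mapping list(width, n_perm, rank_gw, rank_sugg)
#' @param figures write figure files (default FALSE)
#' @return config list
#' @export
pipelineConfig <- function(seed = 1, outdir = tempfile("rohpipe"),
                           sim = list(), input = NULL,
                           stages = c("simulate", "qc", "prune", "roh",
                                      "burden", "map"),
                           qc = list(), prune = list(), roh = list(),
                           burden = list(), mapping = list(),
                           figures = FALSE) {
  list(seed = seed, outdir = outdir, sim = sim, input = input,
       stages = stages, qc = qc, prune = prune, roh = roh,
       burden = burden, mapping = mapping, figures = figures)
}

#' Read a pipeline configuration from YAML (or JSON)
#' @param path config file
#' @return config list
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipelineConfig, cfg)
}

.logline <- function(con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                 paste0(...))
  writeLines(msg, con)
  message(msg)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order (simulate/read, sample and SNP QC,
#' LD pruning, ROH calling, Froh, burden models, ROH mapping), writing
#' per-stage TSVs, a machine-readable JSON summary of the headline numbers
#' and a log. Fully reproducible from config + seed.
#'
#' @param config from \code{\link{pipelineConfig}}
#' @return invisibly, a list with the cohort, ROH table, Froh table,
#'   burden fits, mapping result and the summary list
#' @export
runPipeline <- function(config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(config$outdir, "pipeline.log"), "w")
  on.exit(close(log_con))
  t0 <- Sys.time()
  .logline(log_con, "RohBurden ", as.character(utils::packageVersion("RohBurden")),
           " | R ", paste(R.version$major, R.version$minor, sep = "."),
           " | seed ", config$seed)
  set.seed(config$seed)
  stage_seed <- stats::setNames(
    sample.int(.Machine$integer.max - 1, 6),
    c("simulate", "qc", "prune", "roh", "burden", "map"))
  summary <- list(seed = config$seed)
  run <- function(stage) stage %in% config$stages
  res <- list()

  step <- function(name, expr) {
    t <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    .logline(log_con, sprintf("stage %-8s done in %.1f s", name,
                              as.numeric(difftime(Sys.time(), t, units = "secs"))))
    out
  }

  if (!is.null(config$input)) {
    x <- step("read", readGenotypes(config$input$path,
                                    config$input$format))
  } else if (run("simulate")) {
    x <- step("simulate", {
      sc <- do.call(simConfig,
                    c(config$sim, list(seed = unname(stage_seed["simulate"]))))
      simulateCohort(sc)
    })
  } else stop("no input and simulate stage disabled")
  res$cohort <- x
  summary$n_samples <- ncol(x)
  summary$n_snps <- nrow(x)

  if (run("qc")) {
    x <- step("qc", {
      set.seed(stage_seed["qc"])
      sq <- sampleQC(x, do.call(qcThresholds, config$qc))
      utils::write.table(sq$report, file.path(config$outdir, "sample_qc.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      x2 <- subsetCohort(x, samples = sq$kept)
      kq <- snpQC(x2, thresholds = do.call(qcThresholds, config$qc))
      utils::write.table(kq$report, file.path(config$outdir, "snp_qc.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      subsetCohort(x2, snps = kq$kept)
    })
    summary$n_samples_post_qc <- ncol(x)
    summary$n_snps_post_qc <- nrow(x)
  }

  if (run("prune")) {
    x <- step("prune", {
      kept <- ldPrune(x, do.call(pruneParams, config$prune))
      subsetCohort(x, snps = kept)
    })
    summary$n_snps_post_prune <- nrow(x)
  }
  res$cohort <- x

  roh_par <- do.call(rohParams, config$roh)
  # Froh denominator: the SNP-mappable autosome for real data; for a
  # simulated cohort, the simulated genome extent (so slopes are on the
  # same scale as the generating model)
  denom <- config$burden$denominator_bp
  if (is.null(denom)) {
    denom <- if (is.null(config$input)) {
      sc <- do.call(simConfig, config$sim)
      sum(sc@chrom_lengths_bp)
    } else FROH_DENOMINATOR_BP
  }
  summary$froh_denominator_bp <- denom
  rohs <- NULL
  froh <- NULL
  if (run("roh")) {
    rohs <- step("roh", callRohsCohort(x, roh_par))
    writeRohTable(rohs, file.path(config$outdir, "roh.tsv"))
    froh <- computeFroh(rohs, denominator_bp = denom,
                        sample_ids = sampleTable(x)$sample_id)
    utils::write.table(froh, file.path(config$outdir, "froh.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$n_roh <- nrow(rohs)
    summary$froh_mean <- mean(froh$froh)
    summary$froh_sd <- stats::sd(froh$froh)
    res$rohs <- rohs
    res$froh <- froh
  }

  if (run("burden")) {
    if (is.null(froh)) stop("burden stage requires the roh stage")
    bres <- step("burden", {
      set.seed(stage_seed["burden"])
      st <- sampleTable(x)
      n_pcs <- config$burden$n_pcs
      cov <- NULL
      if (!is.null(n_pcs) && n_pcs > 0)
        cov <- buildCovariates(x, n_pcs)
      mixed <- fitMixedLogistic(st$phenotype, froh$froh, cov,
                                st$dataset_id)
      per_ds <- perDatasetFits(st$phenotype, froh$froh, st$dataset_id, cov)
      utils::write.table(per_ds,
                         file.path(config$outdir, "burden_per_dataset.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      stest <- signTest(per_ds$beta)
      sens <- NULL
      if (isTRUE(config$burden$sensitivity))
        sens <- sensitivitySuite(st$phenotype, froh$froh, st$dataset_id,
                                 cov,
                                 components = froh[, c("froh_short",
                                                       "froh_long")])
      sweep <- NULL
      if (!is.null(config$burden$sweep_grid))
        sweep <- thresholdSweep(x, config$burden$sweep_grid, cov, roh_par,
                                denominator_bp = denom)
      list(mixed = mixed, per_dataset = per_ds, sign = stest,
           sensitivity = sens, sweep = sweep, covariates = cov)
    })
    res$burden <- bres
    summary$burden <- list(
      beta = bres$mixed@beta, se = bres$mixed@se, z = bres$mixed@z,
      p = bres$mixed@p, or_per_1pct = bres$mixed@or1pct,
      pct_increase_per_1pct = 100 * (bres$mixed@or1pct - 1),
      nagelkerke_r2 = bres$mixed@nagelkerkeR2,
      sign_test = bres$sign,
      fold_cousin = foldIncrease(bres$mixed@beta, 0.0625),
      fold_second_cousin = foldIncrease(bres$mixed@beta, 0.015625))
    if (!is.null(bres$sensitivity))
      utils::write.table(bres$sensitivity,
                         file.path(config$outdir, "burden_sensitivity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(bres$sweep)) {
      utils::write.table(bres$sweep,
                         file.path(config$outdir, "burden_sweep.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summary$sweep <- bres$sweep[, c("min_snps", "beta", "p")]
    }
  }

  if (run("map")) {
    if (is.null(rohs)) stop("map stage requires the roh stage")
    mres <- step("map", {
      mp <- config$mapping
      rohMapping(x, rohs,
                 width = mp$width %||% 5e5,
                 covariates = res$burden$covariates,
                 n_perm = mp$n_perm %||% 0,
                 rank_gw = mp$rank_gw %||% 50,
                 rank_sugg = mp$rank_sugg %||% 100,
                 seed = unname(stage_seed["map"]))
    })
    res$mapping <- mres
    utils::write.table(cbind(mres@bins, mres@results[, -1]),
                       file.path(config$outdir, "mapping.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$mapping <- list(
      n_bins = nrow(mres@bins),
      n_tested = sum(!mres@results$skipped),
      min_p = suppressWarnings(min(mres@results$p, na.rm = TRUE)),
      genomewide_p = mres@genomewideP,
      suggestive_p = mres@suggestiveP,
      n_perm = mres@nPerm)
  }

  if (isTRUE(config$figures)) {
    if (!is.null(res$burden))
      ggplot2::ggsave(file.path(config$outdir, "forest.png"),
                      plotForest(res$burden$per_dataset),
                      width = 6, height = 5, dpi = 120)
    if (!is.null(res$burden$sweep))
      ggplot2::ggsave(file.path(config$outdir, "sweep.png"),
                      plotSweep(res$burden$sweep),
                      width = 6, height = 4, dpi = 120)
    if (!is.null(res$mapping))
      ggplot2::ggsave(file.path(config$outdir, "mapping.png"),
                      plotMapping(res$mapping),
                      width = 8, height = 5, dpi = 120)
  }

  .logline(log_con, sprintf("total elapsed %.1f s",
                            as.numeric(difftime(Sys.time(), t0,
                                                units = "secs"))))
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  .logline(log_con, "pipeline complete")
  res$summary <- summary
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a human-readable report from a pipeline summary
#'
#' @param summary a summary list or the path of a summary.json
#' @return character vector of report lines (also printed)
#' @export
renderReport <- function(summary) {
  if (is.character(summary))
    summary <- jsonlite::read_json(summary, simplifyVector = TRUE)
  lines <- c("ROH autozygosity-burden report",
             strrep("=", 32))
  missing <- character()
  grab <- function(name) {
    if (is.null(summary[[name]])) { missing <<- c(missing, name); NULL }
    else summary[[name]]
  }
  if (!is.null(n <- grab("n_samples")))
    lines <- c(lines, sprintf("Samples: %d; SNPs: %s", n,
                              summary$n_snps %||% "?"))
  b <- grab("burden")
  if (!is.null(b)) {
    lines <- c(lines, "", "Burden (mixed model):",
               sprintf("  beta = %.2f (se %.2f), z = %.2f, p = %.3g",
                       b$beta, b$se, b$z, b$p),
               sprintf("  odds per 1%% Froh: %.3f (+%.0f%%)",
                       b$or_per_1pct, 100 * (b$or_per_1pct - 1)),
               sprintf("  predicted fold increase: cousin %.2f, second cousin %.2f",
                       exp(b$beta * 0.0625), exp(b$beta * 0.015625)),
               sprintf("  sign test: %d/%d datasets OR > 1, one-sided p = %.3f",
                       b$sign_test$k_positive, b$sign_test$n, b$sign_test$p))
  }
  if (!is.null(s <- summary$sweep)) {
    lines <- c(lines, "", "Threshold sweep (min_snps: beta, p):")
    lines <- c(lines, sprintf("  %3d: %7.2f  %.3g",
                              s$min_snps, s$beta, s$p))
  }
  mp <- grab("mapping")
  if (!is.null(mp)) {
    lines <- c(lines, "", "ROH mapping:",
               sprintf("  %d bins tested of %d; min p = %.3g",
                       mp$n_tested, mp$n_bins, mp$min_p),
               sprintf("  thresholds (n_perm = %d): genome-wide %.3g, suggestive %.3g",
                       mp$n_perm, mp$genomewide_p, mp$suggestive_p))
  }
  if (length(missing))
    lines <- c(lines, "", paste("missing sections:",
                                paste(missing, collapse = ", ")))
  cat(lines, sep = "\n")
  invisible(lines)
}
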