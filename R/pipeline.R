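#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (or a YAML file with the same
#' structure) with a \code{seed}, a \code{stages} character vector and an
#' optional parameter block per stage. Known stages: \code{field}
#' (simulate a field, segment, per-cell stats, puncta), \code{dissolution}
#' (simulate a population, ratio bins, dissolution call), \code{coloc}
#' (shared-foci field, per-cell IoU scores, strain summary),
#' \code{growth}, \code{competition}, \code{spectra}, \code{proteomics}.
#'
#' @param config named list or path to a YAML file.
#' @return the validated config list (condition class
#'   \code{"agglo_config_error"} on failure).
#' @export
readRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config))
      stop(configError("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop(configError("config must be a list"))
  known <- c("field", "dissolution", "coloc", "growth", "competition",
             "spectra", "proteomics")
  if (is.null(config$stages) || !length(config$stages))
    stop(configError("config must name at least one stage"))
  bad <- setdiff(config$stages, known)
  if (length(bad))
    stop(configError("unknown stage(s): ", paste(bad, collapse = ", "),
                     " (known: ", paste(known, collapse = ", "), ")"))
  config$seed <- as.integer(config$seed %||% 1L)
  config
}

configError <- function(...) {
  structure(class = c("agglo_config_error", "error", "condition"),
            list(message = paste0(...), call = NULL))
}

stageFailure <- function(stage, parent) {
  structure(class = c("agglo_stage_failure", "error", "condition"),
            list(message = sprintf("stage '%s' failed: %s", stage,
                                   conditionMessage(parent)),
                 call = NULL, stage = stage))
}

#' Run the synthetic-to-report pipeline
#'
#' Executes the configured stages in order, writing every output as a
#' plain-text file (CSV/TIFF) under \code{outDir}, and returns a manifest
#' listing inputs, parameter echoes, per-operation child seeds and an MD5
#' checksum for every output file. Identical config + seed reproduces
#' identical checksums. A stage failure aborts with the stage name after
#' writing the partial manifest.
#'
#' @param config list or YAML path, see [readRunConfig()].
#' @param outDir output directory.
#' @return the manifest (list), invisibly written as
#'   \code{manifest.yaml} in \code{outDir}.
#' @export
#' @examples
#' cfg <- list(seed = 7, stages = "dissolution",
#'             dissolution = list(mode = "agglomerate", n_cells = 500))
#' man <- runPipeline(cfg, tempfile("run"))
#' man$results$dissolution$label
runPipeline <- function(config, outDir) {
  config <- readRunConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(packageVersion("AggloAssay")),
                   seed = config$seed, stages = config$stages,
                   parameters = config[setdiff(names(config),
                                               c("seed", "stages"))],
                   files = list(), results = list())
  writeManifest <- function() {
    yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  }
  addFile <- function(path) {
    manifest$files[[basename(path)]] <<-
      list(path = path, md5 = unname(tools::md5sum(path)))
  }
  qp <- do.call(quantParams, config$quant %||% list())
  for (stage in config$stages) {
    res <- tryCatch(switch(stage,
      dissolution = {
        blk <- config$dissolution %||% list()
        sp <- simulationParams(
          dissolutionMode = blk$mode %||% "agglomerate",
          dissolutionSteepness = blk$steepness %||% 3,
          seed = config$seed)
        pop <- simulateDissolutionPopulation(sp, blk$n_cells %||% 5000)
        bins <- ratioBins(pop, blk$n_bins %||% 10, qp)
        call <- dissolutionCall(bins)
        f <- file.path(outDir, "dissolution_bins.csv")
        write.csv(bins, f, row.names = FALSE); addFile(f)
        f <- file.path(outDir, "dissolution_call.csv")
        write.csv(as.data.frame(call), f, row.names = FALSE); addFile(f)
        call
      },
      field = {
        blk <- config$field %||% list()
        sp <- simulationParams(nCells = blk$n_cells %||% 12,
                               fieldShape = blk$shape %||% c(192L, 192L),
                               seed = config$seed)
        fld <- simulateField(sp)
        for (p in writeFieldData(fld, outDir)) addFile(p)
        bg <- estimateBackground(greenChannel(fld), labelMask(fld))
        stats <- cellStats(greenChannel(fld), redChannel(fld),
                           labelMask(fld))
        foci <- detectPuncta(greenChannel(fld), labelMask(fld), bg, qp)
        f <- file.path(outDir, "cell_records.csv")
        write.csv(stats, f, row.names = FALSE); addFile(f)
        f <- file.path(outDir, "foci_calls.csv")
        write.csv(foci[setdiff(names(foci), "pixels")], f,
                  row.names = FALSE); addFile(f)
        list(n_cells = nrow(stats), n_foci = nrow(foci),
             background = bg)
      },
      coloc = {
        blk <- config$coloc %||% list()
        sp <- simulationParams(nCells = blk$n_cells %||% 24,
                               fieldShape = blk$shape %||% c(256L, 256L),
                               seed = config$seed)
        fld <- simulateColocPair(sp, blk$shared_fraction %||% 1)
        sc <- colocScoreField(fld, qp$colocTopFraction)
        f <- file.path(outDir, "coloc_scores.csv")
        write.csv(sc, f, row.names = FALSE); addFile(f)
        summ <- strainPairSummary(sc, rep(TRUE, nrow(sc)), qp)
        list(mean_score = summ$mean_score, status = summ$status)
      },
      growth = {
        blk <- config$growth %||% list()
        g <- simulateGrowth(rPerHour = blk$r_per_hour %||% (60 / 90),
                            noiseSd = blk$noise_sd %||% 0.01,
                            seed = config$seed)
        fit <- fitGrowth(g)
        f <- file.path(outDir, "growth_curve.csv")
        write.csv(g, f, row.names = FALSE); addFile(f)
        fit[c("doubling_time_min", "rate_per_hour", "auc_od_h")]
      },
      competition = {
        blk <- config$competition %||% list()
        cs <- simulateCompetition(blk$s %||% -0.0034,
                                  nCycles = blk$n_cycles %||% 4,
                                  cellsCounted = blk$cells_counted %||% 1000,
                                  seed = config$seed)
        cr <- competitionRates(cs)
        f <- file.path(outDir, "competition_counts.csv")
        write.csv(as.data.frame(cs), f, row.names = FALSE); addFile(f)
        list(s_hat = cr$s)
      },
      spectra = {
        blk <- config$spectra %||% list()
        sim <- simulateSpectra(perturbation = blk$perturbation %||% "random",
                               seed = config$seed)
        dc <- deltaCD(sim$wt, sim$mut)
        f <- file.path(outDir, "spectra.csv")
        write.csv(data.frame(wavelength = sim$wt$wavelength,
                             wt = sim$wt$ellipticity,
                             mut = sim$mut$ellipticity),
                  f, row.names = FALSE); addFile(f)
        list(delta_cd = dc$delta, true_delta = sim$true_delta)
      },
      proteomics = {
        blk <- config$proteomics %||% list()
        sim <- simulateAbundance(nProteins = blk$n_proteins %||% 300,
                                 deProteins = seq_len(blk$n_de %||% 10),
                                 fold = blk$fold %||% 2,
                                 seed = config$seed)
        ae <- imputeAbundance(quantileNormalize(filterAbundance(
          sim$experiment)))
        de <- differentialAbundance(ae)
        hits <- callHits(de)
        enr <- bootstrapEnrichment(hits, de$protein, sim$annotations,
                                   iterations = blk$iterations %||% 1e4,
                                   seed = config$seed)
        f <- file.path(outDir, "de_results.csv")
        write.csv(de, f, row.names = FALSE); addFile(f)
        f <- file.path(outDir, "enrichment.csv")
        write.csv(enr, f, row.names = FALSE); addFile(f)
        list(n_hits = length(hits), n_categories_tested = nrow(enr))
      }),
      error = function(e) {
        writeManifest()
        stop(stageFailure(stage, e))
      })
    manifest$results[[stage]] <- res
  }
  writeManifest()
  invisible(manifest)
}
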