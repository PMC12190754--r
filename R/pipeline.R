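#' Pipeline run configuration
#'
#' Collects every decision knob of the full analysis in one flat, serializable
#' list. Defaults follow the stated analysis protocol where it states a value
#' (1 ns snapshots, standardized PCA, 95th-percentile parallel analysis with
#' 100 draws, k scanned over 2..10 in the PC1/PC2 plane, |loading| >= 0.7
#' threshold, top 10% per-cluster decile, 100 x 100 landscape grid); the rest
#' are logged with the run.
#'
#' @param input a [Trajectory-class], a multi-model PDB path, or a list of
#'   either (replicas to concatenate).
#' @param energy optional per-frame energy table (data.frame or CSV path with
#'   replica_id, time_ns, dG_kJ_per_mol).
#' @param tunnel optional tunnel-presence table (data.frame or CSV path with
#'   frame, group, present).
#' @param outdir output directory.
#' @param referenceFrame 1-based frame used as superposition reference.
#' @param standardized use correlation-matrix PCA (TRUE, default) or classical
#'   covariance essential dynamics.
#' @param paDraws,paPercentile,paMethod parallel-analysis knobs.
#' @param kRange,clusterDim silhouette-scan knobs.
#' @param loadingCutoff,decileFraction loading-selection knobs.
#' @param dccmThreshold block-summary threshold.
#' @param gridN landscape grid resolution.
#' @param sasaStride compute SASA every `sasaStride` frames (0 disables; SASA
#'   is the costly descriptor).
#' @param seed master RNG seed for all stochastic stages.
#' @return A list of class `RunConfig`.
#' @export
runConfig <- function(input, energy = NULL, tunnel = NULL,
                      outdir = tempfile("essdyn_run_"),
                      referenceFrame = 1L, standardized = TRUE,
                      paDraws = 100, paPercentile = 0.95,
                      paMethod = "permutation",
                      kRange = 2:10, clusterDim = 2,
                      loadingCutoff = 0.7, decileFraction = 0.10,
                      dccmThreshold = 0.5, gridN = 100,
                      sasaStride = 0, seed = 1) {
  structure(list(input = input, energy = energy, tunnel = tunnel,
                 outdir = outdir, referenceFrame = as.integer(referenceFrame),
                 standardized = standardized, paDraws = paDraws,
                 paPercentile = paPercentile, paMethod = paMethod,
                 kRange = kRange, clusterDim = clusterDim,
                 loadingCutoff = loadingCutoff,
                 decileFraction = decileFraction,
                 dccmThreshold = dccmThreshold, gridN = gridN,
                 sasaStride = sasaStride, seed = as.integer(seed)),
            class = "RunConfig")
}

.resolve_input <- function(input) {
  as_traj <- function(x) if (is(x, "Trajectory")) x else readMultimodelPDB(x)
  if (is.list(input) && !is(input, "Trajectory"))
    concatenateReplicas(lapply(input, as_traj))
  else as_traj(input)
}

.stage <- function(name, log, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full essential-dynamics pipeline
#'
#' align -> descriptors -> PCA (+ parallel analysis) -> clustering -> loading
#' selections -> DCCM / porcupine -> landscape -> tunnel test, writing every
#' table as CSV into `config$outdir` together with the resolved configuration
#' (`config.json`) and a structured log of every decision knob (`log.txt`).
#' Deterministic under a fixed seed; each stage fails loudly with its name and
#' partial outputs are retained. A missing energy table skips the landscape
#' stage with a warning; a missing tunnel table skips the Z-test.
#'
#' @param config a [runConfig()] list.
#' @return Invisibly, a list with the run directory and all in-memory results.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$outdir, "log.txt")
  logline <- function(...) cat(format(Sys.time(), "%H:%M:%S"), "|", ...,
                               "\n", file = logfile, append = TRUE)
  cat("", file = logfile)
  cfg <- config
  cfg$input <- if (is.character(config$input)) config$input else "<in-memory>"
  cfg$energy <- if (is.character(config$energy)) config$energy
                else if (is.null(config$energy)) NULL else "<in-memory>"
  cfg$tunnel <- if (is.character(config$tunnel)) config$tunnel
                else if (is.null(config$tunnel)) NULL else "<in-memory>"
  jsonlite::write_json(unclass(cfg), file.path(config$outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  out <- list(dir = config$outdir)
  wcsv <- function(df, name) utils::write.csv(
    df, file.path(config$outdir, name), row.names = FALSE)

  traj <- .stage("input", logline, .resolve_input(config$input))
  logline("input:", nFrames(traj), "frames x", nResidues(traj), "residues")

  out$aligned <- .stage("align", logline, {
    ref <- getFrame(traj, config$referenceFrame)
    superposeTrajectory(traj, ref)
  })
  logline("align: reference frame", config$referenceFrame,
          "(0-based index", config$referenceFrame - 1L, ")")
  .stage("align", logline,
         writeMultimodelPDB(out$aligned, file.path(config$outdir, "aligned.pdb")))

  .stage("descriptors", logline, {
    out$rmsf <- rmsf(out$aligned)
    wcsv(out$rmsf, "rmsf.csv")
    out$rg <- radiusOfGyrationSeries(out$aligned)
    wcsv(out$rg, "rg.csv")
    rgs <- seriesStats(out$rg$rg, out$rg$replica_id)
    wcsv(data.frame(series = "rg", mean = rgs$mean, sd = rgs$sd,
                    min = rgs$min, max = rgs$max), "rg_stats.csv")
    if (config$sasaStride > 0) {
      ix <- seq(1, nFrames(out$aligned), by = config$sasaStride)
      sasa <- vapply(ix, function(f)
        sasaShrakeRupley(getFrame(out$aligned, f))$total, numeric(1))
      out$sasa <- cbind(frameLabels(out$aligned)[ix, ], sasa = sasa)
      wcsv(out$sasa, "sasa.csv")
    }
    logline("descriptors: rmsf, rg",
            if (config$sasaStride > 0) paste0(", sasa (stride ",
                                              config$sasaStride, ")") else "")
  })

  .stage("pca", logline, {
    cm <- buildCoordinateMatrix(out$aligned)
    out$coordMatrix <- if (config$standardized) standardizeColumns(cm) else cm
    out$pca <- essentialDynamics(out$coordMatrix)
    out$pa <- parallelAnalysis(out$coordMatrix, nDraws = config$paDraws,
                               percentile = config$paPercentile,
                               seed = config$seed, method = config$paMethod)
    if (out$pa@kRetained >= 1L)
      out$pca <- retainComponents(out$pca, out$pa@kRetained)
    logline("pca: basis =", if (config$standardized) "correlation" else
            "covariance", "; parallel analysis (", config$paMethod, ",",
            config$paDraws, "draws,", config$paPercentile,
            "pct) retained", out$pa@kRetained, "components")
    wcsv(screeData(out$pca, 10), "scree.csv")
    wcsv(pcaSummaryTable(out$pca), "pca_summary.csv")
    wcsv(cbind(frameLabels(out$pca),
               as.data.frame(out$pca@scores[, 1:min(3, ncol(out$pca@scores))])),
         "scores.csv")
    wcsv(cbind(out$pca@columnLabels,
               as.data.frame(out$pca@loadings[, 1:min(3, ncol(out$pca@loadings))])),
         "loadings.csv")
  })

  .stage("cluster", logline, {
    out$clusters <- silhouetteScan(out$pca, kRange = config$kRange,
                                   d = config$clusterDim, seed = config$seed)
    logline("cluster: k =", out$clusters@k, "mean silhouette =",
            round(out$clusters@meanSilhouette, 3),
            if (out$clusters@noStrongStructure) "(no strong structure)" else "")
    wcsv(out$clusters@silhouetteByK, "silhouette_by_k.csv")
    wcsv(cbind(frameLabels(out$pca),
               frame = seq_len(nrow(out$pca@scores)) - 1L,
               cluster = out$clusters@labels), "cluster_assignments.csv")
    cmap <- mapClustersToFrames(out$clusters, frameLabels(out$pca))
    wcsv(cmap$runs, "cluster_runs.csv")
    wcsv(cmap$replicaComposition, "cluster_replica_composition.csv")
    out$clusterMap <- cmap
  })

  .stage("loadings", logline, {
    out$thresholdSelection <- selectLoadingsThreshold(
      out$pca, cutoff = config$loadingCutoff)
    wcsv(out$thresholdSelection@variables, "loadings_threshold.csv")
    out$decileSelection <- selectLoadingsTopDecile(
      out$pca, k = out$clusters@k, fraction = config$decileFraction,
      seed = config$seed)
    wcsv(out$decileSelection@variables, "loadings_top_decile.csv")
    logline("loadings: threshold", config$loadingCutoff, "selected",
            nrow(out$thresholdSelection@variables), "; top",
            100 * config$decileFraction, "% selected",
            nrow(out$decileSelection@variables))
  })

  .stage("dccm", logline, {
    out$dccm <- dccm(out$aligned)
    writeDCCMCSV(out$dccm, file.path(config$outdir, "dccm.csv"))
    out$dccmBlocks <- dccmBlocks(out$dccm, threshold = config$dccmThreshold)
    wcsv(out$dccmBlocks, "dccm_blocks.csv")
    logline("dccm:", nrow(out$dccmBlocks), "coordinated block pairs at |C| >=",
            config$dccmThreshold)
  })

  .stage("porcupine", logline, {
    ref <- getFrame(out$aligned, config$referenceFrame)
    out$porcupine <- porcupineField(out$pca, 1L, ref)
    exportArrows(out$porcupine, file.path(config$outdir, "porcupine_pc1.bild"),
                 "bild")
    exportArrows(out$porcupine, file.path(config$outdir, "porcupine_pc1.csv"),
                 "csv")
    logline("porcupine: PC1 field, scale", round(out$porcupine@scale, 4))
  })

  if (is.null(config$energy)) {
    warning("no energy table supplied; landscape stage skipped")
    logline("landscape: skipped (no energy table)")
  } else .stage("landscape", logline, {
    out$energy <- attachEnergy(frameLabels(out$aligned), config$energy)
    out$landscape <- buildLandscape(out$pca, out$energy, gridN = config$gridN)
    grid <- expand.grid(pc1 = out$landscape@gridPC1,
                        pc2 = out$landscape@gridPC2)
    grid$dG <- as.numeric(out$landscape@dGGrid)
    wcsv(grid, "landscape_grid.csv")
    out$energyStats <- landscapeStats(out$energy, out$clusters)
    wcsv(out$energyStats, "energy_stats.csv")
    wcsv(landscapeMinima(out$landscape), "landscape_minima.csv")
    logline("landscape:", config$gridN, "x", config$gridN, "grid,",
            nrow(landscapeMinima(out$landscape)), "local minima")
  })

  if (is.null(config$tunnel)) {
    logline("ztest: skipped (no tunnel table)")
  } else .stage("ztest", logline, {
    out$ztest <- tunnelPresenceTest(config$tunnel)
    z <- out$ztest
    wcsv(data.frame(successes1 = z@successes1, n1 = z@n1,
                    successes2 = z@successes2, n2 = z@n2,
                    p1 = z@p1, p2 = z@p2, pooled = z@pooled, se = z@se,
                    z = z@z, p_two_sided = z@pTwoSided), "ztest.csv")
    logline("ztest: z =", round(z@z, 3), "p =", signif(z@pTwoSided, 3))
  })

  invisible(out)
}

#' Assemble a human-readable report of a pipeline run
#'
#' Collects the summary tables (PCA spectrum, clusters, energy statistics,
#' Z-test) from a run directory into one plain-text report. Incomplete runs
#' yield a partial report with the gaps flagged; regeneration is idempotent.
#'
#' @param runDir directory written by [runPipeline()].
#' @param path output file (default `report.txt` inside `runDir`).
#' @return Invisibly, the report path.
#' @export
pipelineReport <- function(runDir, path = file.path(runDir, "report.txt")) {
  stopifnot(dir.exists(runDir))
  rd <- function(name) {
    f <- file.path(runDir, name)
    if (file.exists(f)) utils::read.csv(f) else NULL
  }
  con <- textConnection("report_lines", "w", local = TRUE)
  put <- function(...) writeLines(paste0(...), con)
  section <- function(title, df, note) {
    put("== ", title, " ==")
    if (is.null(df)) put("  [missing: ", note, "]")
    else {
      txt <- utils::capture.output(print(df, row.names = FALSE))
      writeLines(paste0("  ", txt), con)
    }
    put("")
  }
  put("Essential-dynamics pipeline report")
  put("run directory: ", runDir)
  put("")
  section("Principal components summary", rd("pca_summary.csv"),
          "pca stage did not complete")
  section("Scree table", rd("scree.csv"), "pca stage did not complete")
  section("Silhouette by k", rd("silhouette_by_k.csv"),
          "cluster stage did not complete")
  section("Cluster timestamp runs", rd("cluster_runs.csv"),
          "cluster stage did not complete")
  section("Free-energy descriptive statistics", rd("energy_stats.csv"),
          "no energy table / landscape stage did not complete")
  section("Two-proportion Z-test", rd("ztest.csv"),
          "no tunnel table / ztest stage did not complete")
  close(con)
  writeLines(report_lines, path)
  invisible(path)
}
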