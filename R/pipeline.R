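#' Pipeline configuration
#'
#' Validated parameter set for the end-to-end modelling chain. Defaults are
#' the procedure's published operating point: 0.4 mm isotropic resampling,
#' 200 HU lower threshold, 1700 HU upper threshold in post-operative mode,
#' +/- 0.15 mm QC tolerance and 0.001 mm best-fit convergence. Unknown
#' fields are rejected.
#'
#' @param input DICOM series directory, .nii file, or a
#'   \linkS4class{VoxelVolume}.
#' @param outputDir run directory for models and the manifest.
#' @param postop logical; enables the minimum filter and the upper
#'   threshold.
#' @param resampleSpacing target isotropic spacing (mm).
#' @param lanczosLobes Lanczos lobe count (2, 3 or 4).
#' @param minFilterWindow odd window of the per-slice minimum filter.
#' @param lowerHU,upperHU segmentation thresholds (HU); the upper one is
#'   applied only in post-operative mode.
#' @param connectivity 6 or 26.
#' @param seeds optional n x 3 world-mm seed matrix; largest component if
#'   NULL.
#' @param plan optional \linkS4class{ResectionPlan} or plan-JSON path.
#' @param plane optional \linkS4class{SymmetryPlane}.
#' @param grooveDepth,grooveWidth resection-mark groove size (mm).
#' @param templateVoxel boolean grid step (mm).
#' @param qcTolerance deviation-map tolerance (mm).
#' @param icpTol best-fit convergence tolerance (mm).
#' @param measuredMesh optional measured-mesh STL path for QC.
#' @param seed RNG seed for all stochastic steps.
#' @param logLevel "quiet" or "info".
#' @return A validated config (list with class "osteoplanConfig").
#' @export
pipelineConfig <- function(input = NULL, outputDir = tempfile("osteoplan_run"),
                           postop = FALSE,
                           resampleSpacing = c(0.4, 0.4, 0.4),
                           lanczosLobes = 3, minFilterWindow = 3,
                           lowerHU = 200, upperHU = 1700, connectivity = 26,
                           seeds = NULL, plan = NULL, plane = NULL,
                           grooveDepth = 0.6, grooveWidth = 0.8,
                           templateVoxel = 0.2, qcTolerance = 0.15,
                           icpTol = 0.001, measuredMesh = NULL, seed = 1,
                           logLevel = c("info", "quiet")) {
  logLevel <- match.arg(logLevel)
  if (length(resampleSpacing) == 1)
    resampleSpacing <- rep(resampleSpacing, 3)
  stopifnot(all(resampleSpacing > 0), lanczosLobes %in% c(2, 3, 4),
            minFilterWindow >= 3, minFilterWindow %% 2 == 1,
            lowerHU < upperHU, connectivity %in% c(6, 26),
            qcTolerance > 0, icpTol > 0)
  if (is.character(plan)) plan <- readResectionPlan(plan)
  cfg <- list(input = input, outputDir = outputDir, postop = postop,
              resampleSpacing = resampleSpacing, lanczosLobes = lanczosLobes,
              minFilterWindow = minFilterWindow, lowerHU = lowerHU,
              upperHU = upperHU, connectivity = connectivity, seeds = seeds,
              plan = plan, plane = plane, grooveDepth = grooveDepth,
              grooveWidth = grooveWidth, templateVoxel = templateVoxel,
              qcTolerance = qcTolerance, icpTol = icpTol,
              measuredMesh = measuredMesh, seed = seed, logLevel = logLevel)
  class(cfg) <- "osteoplanConfig"
  cfg
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Fields map one-to-one onto \code{\link{pipelineConfig}} arguments;
#' unknown keys are rejected.
#'
#' @param path a .yaml/.yml or .json file.
#' @return A validated config.
#' @export
readPipelineConfig <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the yaml package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  bad <- setdiff(names(lst), names(formals(pipelineConfig)))
  if (length(bad))
    stop(sprintf("unknown configuration keys: %s", paste(bad, collapse = ", ")))
  do.call(pipelineConfig, lst)
}

.logmsg <- function(cfg, fmt, ...) {
  if (identical(cfg$logLevel, "info"))
    message(sprintf(paste0("[osteoplan] ", fmt), ...))
}

#' Run the end-to-end modelling pipeline
#'
#' Read -> (post-operative: minimum filter) -> Lanczos isotropic resampling
#' -> threshold segmentation (+ upper threshold in post-operative mode) ->
#' resection-plan clipping and region growing -> isosurface extraction ->
#' model set A-D -> metrics -> optional QC against a measured mesh. All
#' models are written as binary STL under the run directory together with a
#' manifest (parameters, metrics, md5 checksums); the run is deterministic
#' given config and seed. On a stage failure, outputs written so far are
#' retained under \code{failed/} and the error names the stage.
#'
#' @param config a config from \code{\link{pipelineConfig}}.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "osteoplanConfig"))
  cfg <- config
  outDir <- cfg$outputDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      failed <- file.path(outDir, "failed")
      dir.create(failed, showWarnings = FALSE)
      written <- list.files(outDir, full.names = TRUE)
      written <- written[!dir.exists(written)]
      file.rename(written, file.path(failed, basename(written)))
      stop(sprintf("pipeline stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  vol <- stage("read", {
    inp <- cfg$input
    if (is(inp, "VoxelVolume")) inp
    else if (is.character(inp) && dir.exists(inp)) readDicomSeries(inp)
    else if (is.character(inp) && file.exists(inp) &&
             grepl("\\.nii(\\.gz)?$", inp)) readNiftiVolume(inp)
    else stop(sprintf("input '%s' not found", as.character(inp)))
  })
  withSeed(cfg$seed, {
    if (cfg$postop) {
      .logmsg(cfg, "minimum filter (window %d)", cfg$minFilterWindow)
      vol <- stage("minimum_filter", minimumFilter(vol, cfg$minFilterWindow))
    }
    .logmsg(cfg, "Lanczos resampling to %s mm",
            paste(cfg$resampleSpacing, collapse = " x "))
    vol <- stage("resample", resampleLanczos(vol, cfg$resampleSpacing,
                                             cfg$lanczosLobes))
    upper <- if (cfg$postop) cfg$upperHU else NULL
    .logmsg(cfg, "segmentation and model set (lower %g HU%s)", cfg$lowerHU,
            if (is.null(upper)) "" else sprintf(", upper %g HU", upper))
    ms <- stage("model_set",
                makeModelSet(vol, lowerHU = cfg$lowerHU, upperHU = upper,
                             plan = cfg$plan, plane = cfg$plane,
                             seeds = cfg$seeds,
                             connectivity = cfg$connectivity,
                             grooveDepth = cfg$grooveDepth,
                             grooveWidth = cfg$grooveWidth,
                             templateVoxel = cfg$templateVoxel))
    files <- list()
    for (nm in c("A", "B", "C", "D")) {
      mm <- slot(ms, paste0("model", nm))
      if (is.null(mm)) next
      f <- file.path(outDir, sprintf("model_%s.stl", nm))
      writeSTL(mm, f)
      files[[nm]] <- f
    }
    qc <- NULL
    if (!is.null(cfg$measuredMesh)) {
      .logmsg(cfg, "QC against measured mesh")
      qc <- stage("qc", {
        measured <- readSTL(cfg$measuredMesh)
        tf <- bestFitAlign(measured, ms@modelA, tol = cfg$icpTol,
                           seed = cfg$seed)
        rep <- deviationMap(measured, ms@modelA, tf,
                            tolerance = cfg$qcTolerance, seed = cfg$seed)
        chk <- toleranceCheck(rep, cfg$qcTolerance)
        writePLY(ms@modelA, file.path(outDir, "deviation_map.ply"),
                 scalar = .vertexDeviation(ms@modelA, rep),
                 clip = 3 * cfg$qcTolerance)
        list(stats = rep@stats, fractionWithin = rep@fractionWithin,
             pass = chk$pass, maxAbs = chk$maxAbs,
             tolerance = cfg$qcTolerance)
      })
    }
    manifest <- list(
      software = list(package = "osteoplan",
                      version = as.character(packageVersion("osteoplan"))),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      parameters = .configAsList(cfg),
      stages = c("read", if (cfg$postop) "minimum_filter", "resample",
                 "model_set", if (!is.null(qc)) "qc"),
      models = ms@manifest$metrics,
      grooves = ms@manifest$grooves,
      vResect = ms@manifest$vResect,
      qc = if (is.null(qc)) "skipped" else qc,
      checksums = as.list(tools::md5sum(unlist(files))),
      printOrientation = list(
        note = "orient the lateral mandible surface along the printer Z axis",
        rotation = diag(3)))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    invisible(manifest)
  })
}

.configAsList <- function(cfg) {
  out <- cfg
  out$input <- if (is.character(cfg$input)) cfg$input else "<VoxelVolume>"
  out$plan <- if (is.null(cfg$plan)) NULL else "ResectionPlan"
  out$plane <- if (is.null(cfg$plane)) NULL
               else list(point = cfg$plane@point, normal = cfg$plane@normal)
  out$seeds <- if (is.null(cfg$seeds)) NULL else unclass(cfg$seeds)
  class(out) <- NULL
  out
}

# nearest-sample deviation per vertex, for the coloured PLY export
.vertexDeviation <- function(mesh, report) {
  V <- vertices(mesh)
  S <- report@samples
  idx <- vapply(seq_len(nrow(V)), function(i) {
    which.min((S[, 1] - V[i, 1])^2 + (S[, 2] - V[i, 2])^2 +
                (S[, 3] - V[i, 3])^2)
  }, 0L)
  report@distances[idx]
}

#' Construct a print-cost model
#'
#' @param filamentDensity g/cm^3 (PLA 1.24).
#' @param pricePerKg filament price per kg.
#' @param infill infill fraction in (0, 1].
#' @param machineRate machine cost per hour.
#' @param printSpeed deposition-rate proxy in cm^3/h.
#' @param layerThickness layer height in mm (0.15, the finest the reference
#'   printer offers).
#' @return A \linkS4class{CostModel}.
#' @export
costModel <- function(filamentDensity = 1.24, pricePerKg = 25, infill = 0.2,
                      machineRate = 2, printSpeed = 12,
                      layerThickness = 0.15) {
  new("CostModel", filamentDensity = filamentDensity,
      pricePerKg = pricePerKg, infill = infill, machineRate = machineRate,
      printSpeed = printSpeed, layerThickness = layerThickness)
}

#' Estimate fused-filament print cost of a model
#'
#' Material mass is interior volume times infill plus a solid 0.8 mm shell
#' allowance over the surface, times filament density; machine time is
#' deposited volume over the speed proxy. Costs are linear in the model's
#' rates, which are external price assumptions.
#'
#' @param mesh a watertight \linkS4class{TriMesh} with positive volume.
#' @param model a \linkS4class{CostModel}.
#' @return list(material_g, material_cost, machine_h, machine_cost,
#'   total_cost).
#' @export
estimatePrintCost <- function(mesh, model = costModel()) {
  stopifnot(is(mesh, "TriMesh"), is(model, "CostModel"))
  mt <- meshMetrics(mesh)
  if (!mt@watertight)
    stop("open mesh: print-cost estimation requires a watertight model")
  if (mt@volume <= 0) stop("degenerate mesh with non-positive volume")
  volCm3 <- mt@volume / 1000
  shellCm3 <- mt@area * 0.8 / 1000
  materialG <- (volCm3 * model@infill + shellCm3) * model@filamentDensity
  machineH <- volCm3 * model@infill / model@printSpeed
  materialCost <- materialG / 1000 * model@pricePerKg
  machineCost <- machineH * model@machineRate
  list(material_g = materialG, material_cost = materialCost,
       machine_h = machineH, machine_cost = machineCost,
       total_cost = materialCost + machineCost)
}
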