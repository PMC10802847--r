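# Workflow orchestration: generate a phantom dataset on disk, then run
# preprocess -> detect -> reconstruct -> map -> evaluate over its test
# split, with structured logging and provenance records.

#' Pipeline configuration
#'
#' Assembles the configuration consumed by [runPhantom()] and
#' [runPipeline()]. Values can also be loaded from a YAML file with
#' [loadPipelineConfig()]; explicitly supplied values override file values.
#'
#' @param out_dir dataset/output directory.
#' @param n_cases number of phantom cases to generate.
#' @param phantom named list of overrides for [phantomSpec()] (per-case
#'   seeds and fracture draws are handled by [runPhantom()]).
#' @param hu_band HU segmentation band.
#' @param detector named list of overrides for [detectorConfig()].
#' @param split length-3 train/val/test fractions.
#' @param iou_min IoU threshold for a compliant detection.
#' @param ap_method average-precision interpolation (`"all"` or `"11point"`).
#' @param camera snapshot viewing axis.
#' @param seed global seed; every stochastic stage derives its stream from
#'   it.
#' @return a list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(out_dir = "fracture3d-run", n_cases = 10L,
                           phantom = list(), hu_band = c(1150, 1250),
                           detector = list(kind = "rule"),
                           split = c(0.6, 0.1, 0.3), iou_min = 0.5,
                           ap_method = "all", camera = "x", seed = 1L) {
  if (abs(sum(split) - 1) > 1e-6) .stopf("split fractions must sum to 1")
  structure(list(out_dir = out_dir, n_cases = as.integer(n_cases),
                 phantom = phantom, hu_band = hu_band, detector = detector,
                 split = split, iou_min = iou_min, ap_method = ap_method,
                 camera = camera, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' @param path YAML file with any subset of the [pipelineConfig()] fields.
#' @param ... overrides applied on top of the file values.
#' @rdname pipelineConfig
#' @export
loadPipelineConfig <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(pipelineConfig)))
  do.call(pipelineConfig, utils::modifyList(vals[keep], list(...)))
}

.log_stage <- function(stage, ...) {
  .msgf("[%s] %s", stage, sprintf(...))
}

.write_provenance <- function(config, path) {
  jsonlite::write_json(
    list(config_hash = .hash_obj(unclass(config)), seed = config$seed,
         package = "fracture3d",
         version = as.character(utils::packageVersion("fracture3d"))),
    path, auto_unbox = TRUE, pretty = TRUE)
}

# draw one phantom case specification from the pipeline config: fracture
# wedge angle/width and axial extent vary per case, seeded from the global
# seed so the dataset is reproducible case by case
.draw_case_spec <- function(config, case_seed) {
  defaults <- list(seed = case_seed)
  spec_args <- utils::modifyList(defaults, config$phantom)
  if (is.null(spec_args$fractures)) {
    shape <- spec_args$shape %||% formals(phantomSpec)$shape
    shape <- eval(shape)
    ns <- shape[3L]
    spec_args$fractures <- .with_seed(case_seed, {
      centre <- sample(seq(2L, ns - 7L), 1L)
      list(list(slices = c(centre, centre + sample(2:4, 1L)),
                type = "gap",
                angle = stats::runif(1, 0, 360),
                width = stats::runif(1, 45, 90)))
    })
  }
  do.call(phantomSpec, spec_args)
}

#' Generate a phantom dataset on disk
#'
#' Creates `n_cases` seeded phantom cases under `out_dir/cases/`, each with
#' a DICOM series and its ground-truth box TSV, plus a split manifest
#' (train/val/test by the configured fractions) and a provenance record
#' (config hash, seed, package version). Rerunning with the same
#' configuration reproduces the dataset byte for byte.
#'
#' @param config a [pipelineConfig()].
#' @param force overwrite an existing dataset.
#' @return invisibly, the manifest as a list.
#' @export
runPhantom <- function(config, force = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  if (file.exists(manifest_path) && !force) {
    .stopf("output '%s' already holds a dataset (use force = TRUE)",
           config$out_dir)
  }
  case_names <- sprintf("case_%03d", seq_len(config$n_cases))
  for (i in seq_len(config$n_cases)) {
    case_dir <- file.path(config$out_dir, "cases", case_names[i])
    dir.create(file.path(case_dir, "dicom"), recursive = TRUE,
               showWarnings = FALSE)
    spec <- .draw_case_spec(config, config$seed * 1000L + i)
    ph <- generatePhantom(spec)
    writeDicomSeries(ph$volume, file.path(case_dir, "dicom"))
    writeBoxes(ph$truth, file.path(case_dir, "truth.tsv"))
    .log_stage("phantom", "%s: %d slices, %d ground-truth box(es)",
               case_names[i], nSlices(ph$volume), nBoxes(ph$truth))
  }
  split <- splitDataset(case_names, config$split, seed = config$seed)
  manifest <- list(cases = case_names, split = split)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = FALSE,
                       pretty = TRUE)
  .write_provenance(config, file.path(config$out_dir, "provenance.json"))
  .log_stage("phantom", "%d case(s): %d train / %d val / %d test",
             config$n_cases, length(split$train), length(split$val),
             length(split$test))
  invisible(manifest)
}

#' Run the detection/reconstruction pipeline over the test split
#'
#' For every test case in the dataset manifest: read the DICOM series,
#' threshold to the cortical band, extract and cap the bone surface, run
#' the configured detector, lift its boxes to 3-D, write the overlay scene
#' (glTF + PNG snapshot) and the per-case detections; finally aggregate all
#' test cases into one metrics report (confusion counts, PR curve, average
#' precision, IoU mean/sd) written as JSON. A failing case is logged and
#' skipped; the run aborts only if every case fails.
#'
#' @param config the [pipelineConfig()] used to generate the dataset.
#' @param net optional `YoloNetwork` (required when the detector kind is
#'   `"yolov4"`; built untrained from the config if omitted).
#' @return invisibly, the metrics report list.
#' @export
runPipeline <- function(config, net = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  if (!file.exists(manifest_path)) .stopf("no dataset at '%s'", config$out_dir)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  det_cfg <- do.call(detectorConfig, config$detector)
  if (det_cfg$kind == "yolov4" && is.null(net)) {
    net <- buildYolo(det_cfg, seed = config$seed)
  }
  out_dir <- file.path(config$out_dir, "results")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  all_gt <- list(); all_pred <- list()
  ok_cases <- 0L
  for (ci in seq_along(manifest$split$test)) {
    case <- manifest$split$test[ci]
    res <- tryCatch({
      case_dir <- file.path(config$out_dir, "cases", case)
      vol <- readDicomSeries(file.path(case_dir, "dicom"))
      truth <- readBoxes(file.path(case_dir, "truth.tsv"))
      .log_stage("preprocess", "%s: %d slices read", case, nSlices(vol))
      mask <- thresholdBone(vol, config$hu_band[1L], config$hu_band[2L])
      mesh <- capMesh(extractSurface(mask), mask)
      .log_stage("reconstruct", "%s: %d faces (watertight: %s)", case,
                 nrow(meshFaces(mesh)), isWatertight(mesh))
      pred <- if (det_cfg$kind == "rule") detectRule(vol, det_cfg)
              else detectYolo(net, vol, det_cfg)
      .log_stage("detect", "%s: %d detection(s)", case, nBoxes(pred))
      writeBoxes(pred, file.path(out_dir, paste0(case, "_detections.tsv")))
      mask3d <- stackMask(boxToCuboid(pred, vol))
      mask3d <- voxelizeMask(mask3d, dim(voxels(vol)))
      overlayScene(mesh, mask3d, file.path(out_dir, paste0(case, "_scene")),
                   camera = config$camera)
      .log_stage("map", "%s: %d component(s) in the red mask", case,
                 length(unique(cuboids(mask3d)$component)))
      # offset slice indices so slices stay unique across aggregated cases
      offset <- (ci - 1L) * 100000L
      gt_b <- boxes(truth); gt_b$slice_index <- gt_b$slice_index + offset
      pr_b <- boxes(pred); pr_b$slice_index <- pr_b$slice_index + offset
      list(gt = gt_b, pred = pr_b)
    }, error = function(e) {
      .log_stage("error", "%s failed: %s", case, conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      ok_cases <- ok_cases + 1L
      all_gt[[length(all_gt) + 1L]] <- res$gt
      all_pred[[length(all_pred) + 1L]] <- res$pred
    }
  }
  if (!ok_cases) .stopf("all %d test case(s) failed", length(manifest$split$test))

  gt <- new("BoxSet", boxes = do.call(rbind, all_gt))
  pred <- if (length(all_pred)) new("BoxSet", boxes = do.call(rbind, all_pred))
          else boxSet()
  report <- metricsReport(gt, pred, iou_min = config$iou_min,
                          ap_method = config$ap_method)
  writeMetricsReport(report, file.path(out_dir, "metrics.json"))
  pr <- prCurve(gt, pred, config$iou_min, config$ap_method)
  try(plotPrCurve(pr, file.path(out_dir, "pr_curve.png")), silent = TRUE)
  .write_provenance(config, file.path(out_dir, "run_provenance.json"))
  .log_stage("evaluate", "%d case(s): AP = %.3f, tp/fp/fn = %d/%d/%d",
             ok_cases, report$average_precision, report$counts$tp,
             report$counts$fp, report$counts$fn)
  invisible(report)
}
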