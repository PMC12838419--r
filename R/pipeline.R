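#' Pipeline configuration
#'
#' One validated object holding every stage's inputs and parameters. The
#' printed clinical constants live here as defaults: 103 px/mm calibration,
#' the +/-3 degree twist window, the 0.35 mm overlap radius, the 0.5 mm
#' blooming correction, the 1 mm wall and the 0.05 mm vertex-distance
#' exclusion. Unknown keys are rejected to catch typos early.
#'
#' @param inputs named list of input paths: `frames` (TIFF file/dir),
#'   `centerline` (text), `landmarks` (JSON), and either `ccta_mesh`
#'   (STL/PLY/OBJ) or `ccta_cloud` (PLY); optional `calcifications`
#'   (vector of mesh paths), `om_mesh` (reference model for validation).
#' @param calibration an [oct_calibration] or list of its arguments.
#' @param twist a [twist_config] or argument list.
#' @param fusion a [fusion_config] or argument list.
#' @param validation a [validation_config] or argument list.
#' @param bloom_offset_mm calcification blooming correction (mm).
#' @param cloud_density CCTA mesh sampling density (points per mm^2).
#' @param voxel_mm surface-reconstruction grid spacing (mm).
#' @param embed_voxel_mm grid spacing for the whole-model calcification
#'   union; coarser than `voxel_mm` because the union re-extracts the full
#'   solid.
#' @param regions optional list of region predicates (see [region_sphere])
#'   dropped from the fused cloud, replaying interactive residual cleanup.
#' @param seed integer seed for the stochastic steps (cloud sampling).
#' @param out_dir output directory.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs = list(), calibration = oct_calibration(),
                            twist = twist_config(), fusion = fusion_config(),
                            validation = validation_config(),
                            bloom_offset_mm = 0.5, cloud_density = 10,
                            voxel_mm = 0.15, embed_voxel_mm = 0.25,
                            regions = list(), seed = 1L,
                            out_dir = ".") {
  as_cfg <- function(x, ctor, cls) {
    if (inherits(x, cls)) x else do.call(ctor, as.list(x))
  }
  calibration <- as_cfg(calibration, oct_calibration, "oct_calibration")
  twist <- as_cfg(twist, twist_config, "twist_config")
  fusion <- as_cfg(fusion, fusion_config, "fusion_config")
  validation <- as_cfg(validation, validation_config, "validation_config")
  known <- c("frames", "centerline", "landmarks", "ccta_mesh", "ccta_cloud",
             "calcifications", "om_mesh")
  bad <- setdiff(names(inputs), known)
  if (length(bad)) {
    stop("pipeline_config: unknown input keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (bloom_offset_mm < 0 || cloud_density <= 0 || voxel_mm <= 0 ||
      embed_voxel_mm <= 0) {
    stop("pipeline_config: thresholds must be positive", call. = FALSE)
  }
  structure(list(inputs = inputs, calibration = calibration, twist = twist,
                 fusion = fusion, validation = validation,
                 bloom_offset_mm = bloom_offset_mm,
                 cloud_density = cloud_density, voxel_mm = voxel_mm,
                 embed_voxel_mm = embed_voxel_mm,
                 regions = regions, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file holds the same keys as [pipeline_config]; nested blocks
#' (`calibration`, `twist`, `fusion`, `validation`) are argument lists.
#' Unknown top-level keys are rejected.
#'
#' @param path `.yaml`/`.yml` or `.json` config file.
#' @param overrides named list applied over the file contents (CLI flags).
#' @return a [pipeline_config].
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  ext <- tolower(tools::file_ext(path))
  obj <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("read_pipeline_config: unsupported config format '.", ext, "'",
         call. = FALSE)
  }
  for (nm in names(overrides)) obj[[nm]] <- overrides[[nm]]
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(obj), known)
  if (length(bad)) {
    stop("read_pipeline_config: unknown keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, obj)
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full fusion pipeline
#'
#' Executes the stage chain oct-process -> twist-correct -> register ->
#' fuse -> reconstruct -> wall/calcifications -> validate from a validated
#' configuration. Stage failures carry the stage name; intermediates are
#' written to `out_dir` when `keep_intermediates` is set.
#'
#' @param config a [pipeline_config].
#' @param keep_intermediates write per-stage artifacts (contour archive,
#'   registered stack cloud, fused cloud, lumen mesh).
#' @return list with `lumen_mesh`, `wall_solid`, `series`, `stack`,
#'   `fused_cloud`, `profile`, `stenosis`, `report` (a
#'   validation report when a reference model was given, else `NULL`),
#'   and `paths` of written artifacts.
#' @export
run_pipeline <- function(config, keep_intermediates = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t_all <- proc.time()[3L]
  set.seed(config$seed)
  inp <- config$inputs
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  run_stage <- function(stage, expr) {
    t0 <- proc.time()[3L]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    stage_log(stage, "done in %.1f s", proc.time()[3L] - t0)
    res
  }

  series <- run_stage("oct-process",
                      process_pullback_path(inp$frames, config$calibration,
                                            skip_empty = TRUE))
  series <- run_stage("twist-correct", correct_twist(series, config$twist))
  if (keep_intermediates) {
    paths$contours <- file.path(config$out_dir, "contours.json")
    write_contour_archive(series, paths$contours)
  }

  stack <- run_stage("register", {
    cl <- read_centerline(inp$centerline)
    lm <- read_landmarks(inp$landmarks)
    register_pullback(series, cl, lm)
  })

  fused <- run_stage("fuse", {
    ccta <- if (!is.null(inp$ccta_cloud)) {
      read_point_cloud(inp$ccta_cloud)
    } else {
      mesh_to_point_cloud(read_mesh(inp$ccta_mesh),
                          density = config$cloud_density)
    }
    filt <- remove_overlapping_points(ccta, labeled_point_cloud(
      do.call(rbind, lapply(stack$contours3d, `[[`, "points")), "OCT"),
      config$fusion)
    if (length(config$regions)) {
      filt <- select_points_region(filt, config$regions, keep = FALSE)
    }
    fuse_point_clouds(filt, stack)
  })
  if (keep_intermediates) {
    paths$fused_cloud <- file.path(config$out_dir, "fused_cloud.ply")
    write_point_cloud(fused, paths$fused_cloud)
  }

  lumen <- run_stage("reconstruct",
                     reconstruct_surface(fused, voxel_mm = config$voxel_mm,
                                         cl = stack$centerline))
  paths$lumen_mesh <- file.path(config$out_dir, "lumen.stl")
  write_mesh(lumen, paths$lumen_mesh)

  wall <- run_stage("wall", {
    w <- add_wall(lumen, config$fusion)
    if (!is.null(inp$calcifications) && length(inp$calcifications)) {
      calcs <- lapply(inp$calcifications, function(pth)
        calcification_model(read_mesh(pth),
                            bloom_offset_mm = config$bloom_offset_mm))
      w <- embed_calcifications(w, calcs, voxel_mm = config$embed_voxel_mm,
                                lumen_mesh = lumen,
                                wall_thickness_mm =
                                  config$fusion$wall_thickness_mm)
    }
    w
  })
  paths$model <- file.path(config$out_dir, "model.stl")
  write_mesh(wall, paths$model)

  val <- run_stage("validate", {
    profile <- lumen_area_profile(lumen, stack$centerline)
    stenosis <- tryCatch(stenosis_from_profile(profile),
                         error = function(e) NULL)
    report <- NULL
    if (!is.null(inp$om_mesh)) {
      om <- read_mesh(inp$om_mesh)
      report <- validate_models(om, lumen, stack$centerline,
                                config$validation)
    }
    list(profile = profile, stenosis = stenosis, report = report)
  })
  paths$report <- file.path(config$out_dir, "report.csv")
  rep_df <- data.frame(
    pct_AS = if (!is.null(val$stenosis)) val$stenosis$pct_AS else NA_real_,
    MLA_mm2 = if (!is.null(val$stenosis)) val$stenosis$MLA else NA_real_,
    RVA_mm2 = if (!is.null(val$stenosis)) val$stenosis$RVA else NA_real_,
    n_frames = length(series$contours),
    n_fused_points = nrow(fused$points))
  utils::write.csv(rep_df, paths$report, row.names = FALSE)
  write_provenance(config, paths, proc.time()[3L] - t_all)

  list(lumen_mesh = lumen, wall_solid = wall, series = series, stack = stack,
       fused_cloud = fused, profile = val$profile, stenosis = val$stenosis,
       report = val$report, paths = paths)
}

# provenance: config hash, package version, timing
write_provenance <- function(config, paths, elapsed_s) {
  cfg_file <- file.path(config$out_dir, "config_used.json")
  ser <- rapply(unclass(config), function(x)
    if (is.function(x)) "<function>" else x, how = "replace")
  jsonlite::write_json(ser, cfg_file, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  log <- list(config_md5 = unname(tools::md5sum(cfg_file)),
              package_version =
                as.character(utils::packageVersion("corofuse")),
              elapsed_s = round(elapsed_s, 2L),
              artifacts = paths)
  jsonlite::write_json(log, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(log)
}
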