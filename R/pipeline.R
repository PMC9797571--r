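# End-to-end pipeline: phantom (or volume ingest) -> optional resample and
# axis alignment -> per-axis segmentation -> 2-of-3 crack vote -> consensus
# labels -> fill-in -> connected components and morphometry -> slab/sector
# partition -> projection maps, with JSON provenance and a stage log.

#' Default pipeline configuration
#'
#' @param seed Master seed; every random stage derives from it.
#' @return Nested configuration list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    phantom = list(grid = 96L, pitch_um = 65,
                   n_planes = 2L, n_isolated = 4L,
                   target_fraction = 0.02, noise_sd = 1200),
    input = NULL, # path to an existing volume instead of a phantom
    resample = list(target_pitch_um = NULL),
    align = FALSE,
    segmentation = list(backend = "oracle", tile_size = NULL,
                        model_weights = NULL),
    consensus = list(dilation_radius = 1L),
    components = list(connectivity = 26L, min_size = 27L, k_largest = 3L),
    projections = list(scale = "sqrt")
  )
}

stage_log <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cat(msg, "\n", sep = "")
  writeLines(msg, con)
}

#' Run the full crack-analysis pipeline
#'
#' Executes phantom generation (or volume ingest), optional block-mean
#' resampling and principal-axis alignment, slice segmentation along x, y
#' and z, the two-of-three crack vote, non-crack consensus, slice fill-in,
#' connected-component isolation with size filtering, morphometry,
#' slab/sector partitioning and projection maps. All artifacts, a JSON
#' provenance record and a stage log are written to `out_dir`.
#'
#' @param config Configuration list (see [default_pipeline_config()]) or a
#'   path to a YAML file with the same structure.
#' @param out_dir Output run directory (created; must not exist unless
#'   `overwrite`).
#' @param overwrite Allow writing into an existing directory.
#' @return Invisibly, a list with the main in-memory results (`labels`,
#'   `filled`, `components`, `regions`, `run_dir`).
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir,
                         overwrite = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  base <- default_pipeline_config()
  config <- utils::modifyList(base, config)
  if (dir.exists(out_dir) && !overwrite)
    stop("run_pipeline: output directory exists: ", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(logcon))
  census <- function(lab) paste(sprintf("%s=%d", names(label_codes()),
    tabulate(as.integer(lab) + 1L, 4L)), collapse = " ")

  stage <- "phantom"
  result <- tryCatch({
    truth <- NULL
    if (!is.null(config$input)) {
      grey <- read_volume(config$input)
      stage_log(logcon, "[ingest] read %s", config$input)
    } else {
      pc <- config$phantom
      spec <- phantom_spec(
        grid_shape = rep(as.integer(pc$grid), 3L),
        voxel_pitch_um = pc$pitch_um,
        crack_network = crack_network_spec(
          n_primary_planes = pc$n_planes,
          n_isolated_cracks = pc$n_isolated,
          target_volume_fraction = if (pc$n_planes > 0) pc$target_fraction
                                   else NULL),
        noise_sd = pc$noise_sd,
        rng_seed = config$seed)
      ph <- generate_phantom(spec)
      grey <- ph$grey
      truth <- ph$truth
      write_volume(truth$labels, file.path(out_dir, "truth_labels.nrrd"))
      stage_log(logcon, "[phantom] %s voxels, network fraction %.4f",
                paste(dim(grey), collapse = "x"),
                truth$connected_network_voxel_fraction)
    }

    stage <- "resample"
    if (!is.null(config$resample$target_pitch_um)) {
      grey <- resample(grey, config$resample$target_pitch_um)
      stage_log(logcon, "[resample] -> pitch %g um, %s", voxel_pitch(grey),
                paste(dim(grey), collapse = "x"))
    }

    stage <- "align"
    if (isTRUE(config$align)) {
      mask0 <- array(as_plain_array(grey) >
                       stats::quantile(as.vector(grey), 0.7), dim(grey))
      al <- align_axes(grey, mask0)
      grey <- al$volume
      stage_log(logcon, "[align] rotation angle %.2f deg",
                acos(pmin(pmax((sum(diag(al$rotation)) - 1) / 2, -1), 1)) *
                  180 / pi)
    }
    write_volume(grey, file.path(out_dir, "grey.nrrd"))

    stage <- "segment"
    backend <- if (identical(config$segmentation$backend, "oracle"))
      rule_based_oracle()
    else cnn_backend(config$segmentation$model_weights)
    labs <- lapply(c("x", "y", "z"), function(a)
      segment_axis(grey, backend, a,
                   tile_size = config$segmentation$tile_size))
    names(labs) <- c("x", "y", "z")
    for (a in names(labs))
      stage_log(logcon, "[segment %s] %s", a, census(labs[[a]]))

    stage <- "consensus"
    crack <- vote_crack(labs$x, labs$y, labs$z)
    final <- resolve_noncrack(labs$x, labs$y, labs$z, crack)
    filled <- fill_in(final, crack, config$consensus$dilation_radius)
    write_volume(final, file.path(out_dir, "labels.nrrd"))
    write_volume(filled, file.path(out_dir, "labels_filled.nrrd"))
    stage_log(logcon, "[consensus] %s", census(final))

    stage <- "components"
    comps <- connected_components(crack, config$components$connectivity,
                                  voxel_pitch(grey))
    comps <- filter_by_size(comps, config$components$min_size)
    tmask <- tooth_mask(final)
    tab <- component_table(comps, tmask)
    write_component_table(tab, file.path(out_dir, "components.csv"))
    stage_log(logcon, "[components] %d kept (min size %d)",
              nrow(tab), config$components$min_size)

    stage <- "partition"
    regions <- slab_sector_regions(tmask)
    write.csv(regions$table, file.path(out_dir, "regions.csv"),
              row.names = FALSE)
    stage_log(logcon, "[partition] 12 regions, fallback slabs: %s",
              paste(which(regions$fallback), collapse = " ") )

    stage <- "projections"
    for (a in c("z", "y", "x")) {
      write_png_map(projected_density(crack, a, config$projections$scale),
                    file.path(out_dir, sprintf("crack_density_%s.png", a)))
    }
    write_png_map(depth_shaded_projection(crack, "y"),
                  file.path(out_dir, "crack_depth_y.png"))

    prov <- list(config = config,
                 package_version = as.character(utils::packageVersion("toothcrack")),
                 r_version = R.version.string,
                 timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(labels = final, filled = filled, components = comps,
         regions = regions, truth = truth, run_dir = out_dir)
  }, error = function(e) {
    stage_log(logcon, "[%s] ERROR: %s", stage, conditionMessage(e))
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
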