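#' Pipeline configuration
#'
#' Collects and validates every knob of the end-to-end synthetic run. All
#' randomness flows from the single `seed`; stage seeds are derived from
#' it with [derive_seed()].
#'
#' @param out_dir output directory for tables and the run manifest.
#' @param n_plates,n_compounds_per_plate,n_moa,n_conc,controls_per_role
#'   screen geometry (defaults: 2 plates x 20 compounds x 5 concentrations
#'   with 12 + 12 controls and 4 MOA classes).
#' @param coculture_id co-culture combination label.
#' @param n_features feature-space dimension of the simulated profiles.
#' @param effect_size per-MOA feature-shift norm (see [effect_model()]).
#' @param conc_curve concentration multiplier curve.
#' @param cell_noise_sd,plate_sd noise scales of the effect model.
#' @param cells_per_well list with `mean`, `cv`, `positive_survival`.
#' @param image_route also render `n_image_wells` wells as images and run
#'   the image stages (FOV split/merge, illumination correction,
#'   percentile normalization, crops, handcrafted features), writing the
#'   resulting cell table alongside the simulated one.
#' @param n_image_wells wells to render when `image_route` is on.
#' @param image_size,overlap_px,box_size,masked,percentile image-stage
#'   parameters (box 50 unmasked / 90 masked are the conventional sizes).
#' @param mad_scale,alpha,n_perm,metric,leave_compound_out profiling and
#'   enrichment parameters.
#' @param seed master seed.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("moascreen_run_"),
                            n_plates = 2, n_compounds_per_plate = 4,
                            n_moa = 2, n_conc = 5, controls_per_role = 12,
                            coculture_id = "KB",
                            n_features = 8, effect_size = 0,
                            conc_curve = c(0.1, 0.3, 0.6, 0.85, 1),
                            cell_noise_sd = 1, plate_sd = 0.25,
                            cells_per_well = list(mean = 50, cv = 0.1,
                                                  positive_survival = 0.05),
                            image_route = FALSE, n_image_wells = 4,
                            image_size = c(195, 195), overlap_px = 5,
                            box_size = 50, masked = FALSE, percentile = 99,
                            mad_scale = FALSE, alpha = 0.05, n_perm = 1000,
                            metric = "pearson", leave_compound_out = FALSE,
                            seed = 1) {
  cfg <- as.list(environment())
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("alpha must lie in (0, 1), got ", cfg$alpha)
  if (!.is_count(cfg$n_perm) || cfg$n_perm < 1)
    stop("n_perm must be a positive integer")
  if (!.is_count(cfg$box_size) || cfg$box_size < 1)
    stop("box_size must be a positive integer")
  if (cfg$percentile <= 0 || cfg$percentile > 100)
    stop("percentile must lie in (0, 100]")
  if (!cfg$metric %in% c("pearson", "spearman"))
    stop("metric must be 'pearson' or 'spearman'")
  stopifnot(.is_count(cfg$n_plates), .is_count(cfg$n_moa),
            .is_count(cfg$n_conc), length(cfg$conc_curve) == cfg$n_conc,
            .is_count(cfg$seed) || is.numeric(cfg$seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full synthetic profiling pipeline
#'
#' Generates a screen layout and MOA-structured cell features, optionally
#' exercises the image stages on rendered wells, aggregates to well
#' profiles, normalizes per plate against DMSO, computes per-plate Z'
#' quality, scans every treated well for MOA enrichment, and writes all
#' result tables plus a reproducibility manifest to `config$out_dir`.
#' Running the same config twice produces byte-identical tables.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a `pipeline_run` list: the tables (`layout`,
#'   `cells`, `profiles`, `normalized`, `plate_quality`, `enrichment`,
#'   `moa_summary`), the output `paths`, and the `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  layout <- generate_screen_layout(
    n_plates = config$n_plates,
    n_compounds_per_plate = config$n_compounds_per_plate,
    n_moa = config$n_moa, n_conc = config$n_conc,
    controls_per_role = config$controls_per_role,
    coculture_id = config$coculture_id,
    seed = derive_seed(config$seed, "layout")
  )
  eff <- effect_model(
    moa_labels = sort(unique(stats::na.omit(layout$moa_label))),
    n_features = config$n_features, effect_size = config$effect_size,
    conc_curve = config$conc_curve, cell_noise_sd = config$cell_noise_sd,
    plate_sd = config$plate_sd, seed = derive_seed(config$seed, "effects")
  )
  cells <- simulate_feature_table(layout, eff,
                                  cells_per_well = config$cells_per_well,
                                  seed = derive_seed(config$seed, "cells"))

  image_cells <- NULL
  if (config$image_route)
    image_cells <- .run_image_route(layout, config)

  profiles <- aggregate_well(cells, layout)
  normalized <- robust_normalize(profiles, mad_scale = config$mad_scale)
  qc <- plate_quality(profiles)
  scan <- moa_enrichment_scan(
    normalized, alpha = config$alpha, n_perm = config$n_perm,
    leave_compound_out = config$leave_compound_out, metric = config$metric,
    seed = derive_seed(config$seed, "enrichment")
  )
  moa_summary <- percent_enriched(scan)

  paths <- c(
    layout = file.path(config$out_dir, "layout.csv"),
    cells = file.path(config$out_dir, "cell_features.csv"),
    profiles = file.path(config$out_dir, "well_profiles.csv"),
    normalized = file.path(config$out_dir, "normalized_profiles.csv"),
    plate_quality = file.path(config$out_dir, "plate_quality.csv"),
    enrichment = file.path(config$out_dir, "enrichment_results.csv"),
    moa_summary = file.path(config$out_dir, "moa_summary.csv"),
    manifest = file.path(config$out_dir, "manifest.json")
  )
  write_layout(layout, paths[["layout"]])
  write_cell_features(cells, paths[["cells"]])
  write_profiles(profiles, paths[["profiles"]])
  write_profiles(normalized, paths[["normalized"]])
  .write_table(qc, paths[["plate_quality"]])
  .write_table(scan$results, paths[["enrichment"]])
  .write_table(as.data.frame(moa_summary), paths[["moa_summary"]])
  if (!is.null(image_cells)) {
    paths[["image_cells"]] <- file.path(config$out_dir,
                                        "image_cell_features.csv")
    write_cell_features(image_cells, paths[["image_cells"]])
  }

  cfg_plain <- unclass(config)
  cfg_json <- jsonlite::toJSON(cfg_plain, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "moascreen",
    version = as.character(utils::packageVersion("moascreen")),
    config = cfg_plain,
    config_hash = .hexdigest(as.character(cfg_json)),
    master_seed = config$seed,
    stage_seeds = list(
      layout = derive_seed(config$seed, "layout"),
      effects = derive_seed(config$seed, "effects"),
      cells = derive_seed(config$seed, "cells"),
      enrichment = derive_seed(config$seed, "enrichment")
    )
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(structure(
    list(layout = layout, cells = cells, image_cells = image_cells,
         profiles = profiles, normalized = normalized, plate_quality = qc,
         enrichment = scan, moa_summary = moa_summary, paths = paths,
         manifest = manifest),
    class = "pipeline_run"
  ))
}

# Render a few wells and push them through the image stages: render ->
# split into FOVs -> merge back -> illumination correction (profile
# estimated across the rendered wells) -> percentile normalization ->
# handcrafted single-cell features keyed by well. Demonstrates that the
# image path feeds the same profiling interface as the simulator.
.run_image_route <- function(layout, config) {
  wells <- layout[layout$role != "positive_control", ]
  wells <- wells[seq_len(min(config$n_image_wells, nrow(wells))), ]
  rendered <- lapply(seq_len(nrow(wells)), function(i) {
    wseed <- derive_seed(config$seed,
                         paste0("image/", wells$plate_id[i], ":",
                                wells$well_id[i]))
    scene <- random_scene(
      n_cancer = 10, n_fibroblast = 6, image_size = config$image_size,
      seed = wseed
    )
    rw <- render_well_image(scene, image_size = config$image_size,
                            illumination = list(type = "radial",
                                                strength = 0.25),
                            seed = wseed)
    tiles <- split_into_fovs(rw$image, config$overlap_px)
    merged <- merge_fovs(tiles, config$overlap_px)
    list(image = merged, mask = rw$mask)
  })
  prof <- estimate_illumination(lapply(rendered, `[[`, "image"))
  tabs <- lapply(seq_len(nrow(wells)), function(i) {
    img <- apply_illumination(rendered[[i]]$image, prof)
    for (ch in 1:3)
      img[ch, , ] <- percentile_normalize(img[ch, , ], q = config$percentile)
    well_cell_features(img, rendered[[i]]$mask,
                       wells$plate_id[i], wells$well_id[i])
  })
  do.call(rbind, tabs)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("moascreen pipeline run\n")
  cat("  wells: ", nrow(x$profiles), ", cells: ", nrow(x$cells), "\n", sep = "")
  cat("  plates passing Z' > 0.5: ", sum(x$plate_quality$pass), "/",
      nrow(x$plate_quality), "\n", sep = "")
  print(x$enrichment)
  cat("  outputs: ", dirname(x$paths[["manifest"]]), "\n", sep = "")
  invisible(x)
}
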