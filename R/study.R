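## Study-level orchestration: whole-study simulation at coordinate level,
## per-animal aggregation, the analysis configuration, and the end-to-end
## rendered pipeline.

#' Analysis configuration
#'
#' Collects every tunable constant of the pipeline. Defaults reproduce the
#' analysis constants the pipeline is built around: 40 um vicinity radius,
#' detection stringency of nine background standard deviations, minimum
#' plaque areas of 20 px (detection) and 30 px (size analysis), a 300 um^2
#' large-plaque threshold and 1,000 null-simulation iterations per image.
#'
#' @param pixel_size_um calibration (default 0.43 um/px).
#' @param vicinity_radius_um vicinity radius (default 40).
#' @param detection_multiplier noise multiplier of the threshold (default 9).
#' @param min_area_px_detection minimum area for detection (default 20 px).
#' @param min_area_px_size minimum area for the size analysis (default 30 px).
#' @param large_threshold_um2 large-plaque threshold (default 300 um^2).
#' @param n_iterations null-simulation iterations per image (default 1000).
#' @param seed master RNG seed.
#' @param channel_map named list mapping channel names to TIFF page indices.
#' @param border_margin_px border-exclusion margin for detection (default 0).
#' @param smoothing_sigma_px smoothing SD for the size analysis (default 1).
#' @return Object of class `analysis_config` (validated list).
#' @export
analysis_config <- function(pixel_size_um = 0.43, vicinity_radius_um = 40,
                            detection_multiplier = 9,
                            min_area_px_detection = 20L,
                            min_area_px_size = 30L,
                            large_threshold_um2 = 300,
                            n_iterations = 1000L, seed = 1L,
                            channel_map = list(MX = 1L, AB = 2L, TR = 3L),
                            border_margin_px = 0L,
                            smoothing_sigma_px = 1) {
  cfg <- list(pixel_size_um = as.numeric(pixel_size_um),
              vicinity_radius_um = as.numeric(vicinity_radius_um),
              detection_multiplier = as.numeric(detection_multiplier),
              min_area_px_detection = as.integer(min_area_px_detection),
              min_area_px_size = as.integer(min_area_px_size),
              large_threshold_um2 = as.numeric(large_threshold_um2),
              n_iterations = as.integer(n_iterations),
              seed = as.integer(seed),
              channel_map = lapply(channel_map, as.integer),
              border_margin_px = as.integer(border_margin_px),
              smoothing_sigma_px = as.numeric(smoothing_sigma_px))
  for (nm in c("pixel_size_um", "vicinity_radius_um", "detection_multiplier",
               "min_area_px_detection", "min_area_px_size",
               "large_threshold_um2", "n_iterations"))
    stop_if_not_scalar_number(cfg[[nm]], nm, positive = TRUE)
  if (length(cfg$channel_map) < 2 || is.null(names(cfg$channel_map)))
    stop("channel_map must name at least two channels")
  structure(cfg, class = "analysis_config")
}

#' Write / read an analysis configuration (lossless round trip)
#' @param config an `analysis_config`.
#' @param path JSON file path.
#' @return `write_analysis_config` returns `path` invisibly;
#'   `read_analysis_config` returns the `analysis_config`.
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_analysis_config
#' @export
read_analysis_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$channel_map <- as.list(raw$channel_map)
  do.call(analysis_config, raw)
}

#' Calibrate the clustered fraction for a target vicinity proportion
#'
#' Given the chance vicinity fraction `c` of a layout (the probability a
#' uniformly placed plaque lands within the vicinity radius of some
#' pre-existing plaque), the clustered-mechanism fraction `p` that yields an
#' expected observed vicinity proportion `t` is `p = (t - c) / (1 - c)`.
#'
#' @param target desired expected vicinity proportion (e.g. 0.22).
#' @param chance chance vicinity fraction of the layout.
#' @return The clustered fraction `p_cluster` in `[0, 1]`.
#' @export
calibrate_p_cluster <- function(target, chance) {
  stopifnot(target >= 0, target <= 1, chance >= 0, chance < 1)
  p <- (target - chance) / (1 - chance)
  if (p < 0)
    stop("target vicinity proportion is below the chance level of this layout")
  p
}

#' Simulate a whole study at coordinate level
#'
#' Generates `n_animals x images_per_animal` ground-truth scenes, takes each
#' image's observed vicinity proportion from the exact coordinates (the
#' perfect-detection limit), runs the random-placement null per image, and
#' performs the per-animal matched-pairs comparison. Per-image RNG streams
#' are derived from the master seed and the image id, so results do not
#' depend on processing order.
#'
#' @param n_animals,images_per_animal study size (default 20 x 10).
#' @param scene a [scene_config()] template shared by all images.
#' @param n_iterations null-simulation iterations per image (default 1000).
#' @param seed master seed.
#' @param group_labels optional per-animal group labels (length `n_animals`).
#' @return list with `images` (per-image data.frame), `grouping`,
#'   `nullsim` (list of `nullsim_result`), `comparison`
#'   (see [paired_comparison()]), `table` (per-animal study table).
#' @export
simulate_study <- function(n_animals = 20L, images_per_animal = 10L,
                           scene = scene_config(), n_iterations = 1000L,
                           seed = 1L, group_labels = NULL) {
  stopifnot(inherits(scene, "scene_config"))
  if (is.null(group_labels)) group_labels <- rep("all", n_animals)
  stopifnot(length(group_labels) == n_animals)
  rows <- vector("list", n_animals * images_per_animal)
  sims <- vector("list", n_animals * images_per_animal)
  k <- 0L
  field <- c(scene$field_width_um, scene$field_height_um)
  for (a in seq_len(n_animals)) {
    for (i in seq_len(images_per_animal)) {
      k <- k + 1L
      image_id <- sprintf("a%02d_img%02d", a, i)
      sc <- generate_scene(scene,
                           seed = derive_stream_seed(seed,
                                                     paste0(image_id, ":scene")))
      sim <- simulate_random_placement(
        sc$pre[, c("x_um", "y_um")], n_new = nrow(sc$new), field = field,
        radius_um = scene$cluster_radius_um, n_iterations = n_iterations,
        seed = seed, image_id = image_id,
        observed_vicinity_prop = sc$truth_vicinity_fraction)
      sims[[k]] <- sim
      rows[[k]] <- data.frame(
        image_id = image_id, animal_id = sprintf("a%02d", a),
        group_label = group_labels[a],
        n_pre = nrow(sc$pre), n_new = nrow(sc$new),
        n_new_in_vicinity = sum(sc$new$in_vicinity),
        observed_vicinity_prop = sc$truth_vicinity_fraction,
        chance_mean = sim$chance_mean)
    }
  }
  images <- do.call(rbind, rows)
  grouping <- unique(images[, c("image_id", "animal_id", "group_label")])
  comparison <- paired_comparison(sims, grouping)
  per_animal <- comparison$per_animal
  per_animal$group_label <-
    grouping$group_label[match(per_animal$animal_id, grouping$animal_id)]
  list(images = images, grouping = grouping, nullsim = sims,
       comparison = comparison, table = per_animal)
}

#' Build the per-animal study table from classified images
#'
#' Aggregates per-image classification results and null simulations to one
#' row per animal, the statistical unit of the group comparisons.
#'
#' @param image_results named list (by image id) of [classify_image()]
#'   outputs, each optionally carrying a `nullsim` element
#'   (`nullsim_result`).
#' @param grouping data.frame `image_id`, `animal_id`, `group_label`.
#' @return data.frame, one row per animal: counts (`n_plaques`, `n_new`,
#'   `n_new_in_vicinity`, `n_flower_petals`, `n_multicore`, `n_large`,
#'   `n_large_multicore`, `n_merged`) and proportions
#'   (`observed_vicinity_prop`, `chance_mean`; new-plaque-count-weighted
#'   over the animal's images).
#' @export
build_study_table <- function(image_results, grouping) {
  stopifnot(all(names(image_results) %in% grouping$image_id))
  per_image <- do.call(rbind, lapply(names(image_results), function(id) {
    res <- image_results[[id]]
    rec <- res$records
    petals <- unique(res$flowers$petal_id)
    obs <- if (sum(rec$is_new) > 0)
      sum(rec$is_new & rec$in_vicinity) / sum(rec$is_new) else NA_real_
    data.frame(
      image_id = id,
      n_plaques = nrow(rec), n_new = sum(rec$is_new),
      n_new_in_vicinity = sum(rec$is_new & rec$in_vicinity),
      n_flower_petals = length(petals),
      n_multicore = sum(rec$is_multicore),
      n_large = sum(rec$is_large),
      n_large_multicore = sum(rec$is_large & rec$is_multicore),
      n_merged = sum(rec$is_multicore & rec$core_fate == "merged"),
      observed_vicinity_prop = obs,
      chance_mean = if (!is.null(res$nullsim)) res$nullsim$chance_mean
                    else NA_real_)
  }))
  per_image <- merge(per_image, grouping, by = "image_id")
  agg <- do.call(rbind, lapply(split(per_image, per_image$animal_id),
    function(d) {
      w <- d$n_new
      data.frame(
        animal_id = d$animal_id[1], group_label = d$group_label[1],
        n_images = nrow(d),
        n_plaques = sum(d$n_plaques), n_new = sum(d$n_new),
        n_new_in_vicinity = sum(d$n_new_in_vicinity),
        n_flower_petals = sum(d$n_flower_petals),
        n_multicore = sum(d$n_multicore), n_large = sum(d$n_large),
        n_large_multicore = sum(d$n_large_multicore),
        n_merged = sum(d$n_merged),
        observed_vicinity_prop = if (sum(w) > 0)
          stats::weighted.mean(d$observed_vicinity_prop, w, na.rm = TRUE)
          else NA_real_,
        chance_mean = if (sum(w) > 0)
          stats::weighted.mean(d$chance_mean, w, na.rm = TRUE)
          else NA_real_)
    }))
  rownames(agg) <- NULL
  agg
}

#' Run the full rendered pipeline
#'
#' End-to-end run over synthetic scenes: generate -> render -> detect ->
#' classify -> null-simulate -> aggregate -> report. Writes the detections,
#' records, flower, per-image null-simulation and per-animal study tables
#' as CSV, the proportion summary and test results as JSON, plus a run
#' manifest carrying the configuration and seed.
#'
#' @param out_dir output directory (created).
#' @param design data.frame `image_id`, `animal_id`, `group_label`, one row
#'   per image.
#' @param scene a [scene_config()] template for the synthetic scenes.
#' @param config an [analysis_config()].
#' @param channels channels to render/analyse (default MX, AB, TR).
#' @param verbose print per-stage progress.
#' @return Invisibly, a list with `table`, `summary`, `comparison`,
#'   `regression`, `records` (all images), `paths`.
#' @export
run_pipeline <- function(out_dir, design, scene = scene_config(),
                         config = analysis_config(),
                         channels = c("MX", "AB", "TR"), verbose = FALSE) {
  stopifnot(all(c("image_id", "animal_id", "group_label") %in% names(design)))
  stopifnot(inherits(config, "analysis_config"))
  if (!all(channels %in% names(config$channel_map)))
    stop("channel_map is missing channel(s): ",
         paste(setdiff(channels, names(config$channel_map)), collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  image_results <- list()
  det_rows <- rec_rows <- flower_rows <- sim_rows <- list()
  field <- c(scene$field_width_um, scene$field_height_um)

  for (r in seq_len(nrow(design))) {
    id <- design$image_id[r]
    say("[%s] synth + render", id)
    sc <- generate_scene(scene, seed = derive_stream_seed(config$seed,
                                                          paste0(id, ":scene")))
    ren <- render_scene(sc, channels = channels)

    say("[%s] detect", id)
    dets <- lapply(channels, function(ch) {
      img <- ren$img[, , ch]
      bg <- estimate_background(img)
      detect_plaques(img, bg, config$pixel_size_um,
                     min_area_px = config$min_area_px_detection,
                     multiplier = config$detection_multiplier,
                     border_margin_px = config$border_margin_px)
    })
    names(dets) <- channels

    say("[%s] classify", id)
    cls <- classify_image(dets$AB, dets$MX, tr_det = dets$TR,
                          radius_um = config$vicinity_radius_um,
                          large_threshold_um2 = config$large_threshold_um2)
    rec <- cls$records
    n_new <- sum(rec$is_new)
    obs <- if (n_new > 0) sum(rec$is_new & rec$in_vicinity) / n_new
           else NA_real_

    say("[%s] null simulation", id)
    sim <- simulate_random_placement(
      cls$pre_centers, n_new = n_new, field = field,
      radius_um = config$vicinity_radius_um,
      n_iterations = config$n_iterations, seed = config$seed,
      image_id = id, observed_vicinity_prop = obs)
    cls$nullsim <- sim
    image_results[[id]] <- cls

    for (ch in channels) {
      d <- dets[[ch]]$regions
      if (nrow(d) > 0)
        det_rows[[paste(id, ch)]] <- cbind(image_id = id, channel = ch, d)
    }
    rec_out <- as.data.frame(rec)
    rec_rows[[id]] <- cbind(image_id = id, rec_out)
    if (nrow(cls$flowers) > 0)
      flower_rows[[id]] <- cbind(image_id = id, cls$flowers)
    sim_rows[[id]] <- data.frame(image_id = id, n_new = sim$n_new,
                                 observed_vicinity_prop = obs,
                                 chance_mean = sim$chance_mean,
                                 n_iterations = sim$n_iterations,
                                 seed = sim$seed)
  }

  grouping <- design[, c("image_id", "animal_id", "group_label")]
  table <- build_study_table(image_results, grouping)
  summary_tab <- summarize_proportions(table)
  sims <- lapply(image_results, `[[`, "nullsim")
  comparison <- tryCatch(paired_comparison(sims, grouping),
                         error = function(e) list(error = conditionMessage(e)))
  all_rec <- do.call(rbind, rec_rows)
  regression <- tryCatch(core_size_regression(all_rec),
                         error = function(e) list(error = conditionMessage(e)))

  paths <- list(
    detections = file.path(out_dir, "detections.csv"),
    records = file.path(out_dir, "records.csv"),
    flowers = file.path(out_dir, "flowers.csv"),
    nullsim = file.path(out_dir, "nullsim.csv"),
    table = file.path(out_dir, "study_table.csv"),
    summary = file.path(out_dir, "summary_proportions.csv"),
    tests = file.path(out_dir, "tests.json"),
    manifest = file.path(out_dir, "manifest.json"))
  utils::write.csv(do.call(rbind, det_rows), paths$detections,
                   row.names = FALSE)
  utils::write.csv(all_rec, paths$records, row.names = FALSE)
  utils::write.csv(if (length(flower_rows)) do.call(rbind, flower_rows)
                   else data.frame(), paths$flowers, row.names = FALSE)
  utils::write.csv(do.call(rbind, sim_rows), paths$nullsim, row.names = FALSE)
  utils::write.csv(table, paths$table, row.names = FALSE)
  utils::write.csv(summary_tab, paths$summary, row.names = FALSE)
  reg_out <- if (!is.null(regression$error)) regression else
    regression[c("slope", "intercept", "r_squared", "p_value", "n")]
  jsonlite::write_json(list(
    paired_comparison = comparison[setdiff(names(comparison), "per_animal")],
    regression = reg_out),
    paths$tests, auto_unbox = TRUE, digits = NA, pretty = TRUE,
    force = TRUE)
  jsonlite::write_json(list(
    package_version = as.character(utils::packageVersion("plaqcluster")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = config$seed, config = unclass(config),
    scene = unclass(scene), n_images = nrow(design)),
    paths$manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(table = table, summary = summary_tab,
                 comparison = comparison, regression = regression,
                 records = all_rec, paths = paths))
}
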