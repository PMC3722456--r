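#' Configuration for a synthetic plaque scene
#'
#' Defines the geometry, plaque population and rendering parameters of one
#' simulated cortical field. Defaults emulate the post-mortem imaging setup
#' the analysis is designed for: a 688 x 512 um field at 0.43 um/px, a few
#' dozen plaques with lognormally distributed dense-core radii, diffuse
#' antibody halos around pre-existing cores, and a tunable fraction of new
#' plaques deposited within `cluster_radius_um` of a pre-existing plaque.
#'
#' @param field_width_um,field_height_um field size in micrometres.
#' @param pixel_size_um pixel calibration in micrometres per pixel.
#' @param n_pre number of pre-existing (dense-core labelled) plaques.
#' @param n_new number of newly deposited (antibody-only) plaques.
#' @param p_cluster probability in `[0, 1]` that a new plaque is deposited by
#'   the clustered mechanism (uniform on a disc of radius `cluster_radius_um`
#'   around a uniformly chosen pre-existing centre) rather than uniformly over
#'   the field.
#' @param cluster_radius_um vicinity radius in micrometres (default 40).
#' @param core_radius_meanlog,core_radius_sdlog lognormal parameters of the
#'   dense-core radius in micrometres (default median 3 um).
#' @param core_radius_min_um lower truncation of the core radius. Cores below
#'   roughly 2 um are not resolvable as separate structures at the default
#'   calibration, so draws below this floor are redrawn.
#' @param halo_radius_factor multiplier (> 1) converting a core radius into
#'   the radius of its diffuse antibody halo.
#' @param multicore_p probability that a pre-existing plaque carries one or
#'   more extra dense cores inside its halo ("multicore" plaque).
#' @param extra_cores_mean mean of the (1 + Poisson) count of extra cores
#'   planted in a multicore halo; total cores are always >= 2.
#' @param multicore_halo_growth relative halo enlargement per extra core
#'   (default 0.3): plaques assembled from several precursors present larger
#'   antibody halos, giving the positive core-count-versus-size association
#'   the classification stage quantifies.
#' @param separate_p probability that the cores of a multicore plaque remain
#'   separate (rather than merged) in the dense-core counterstain channel.
#' @param background_mean,background_sd mean and SD of the additive Gaussian
#'   background noise, in arbitrary intensity units.
#' @param amplitude peak intensity of a rendered blob above background.
#' @param min_separation_um optional minimum centre-to-centre distance
#'   between plaques (rejection sampling; default 0 = unconstrained).
#'   Unconstrained placement is the study condition the spatial statistics
#'   assume; a positive value produces scenes of resolvable, non-overlapping
#'   plaques for detector benchmarking. Must be smaller than
#'   `cluster_radius_um` for clustered deposition to remain feasible.
#' @param seed integer RNG seed; identical `(config, seed)` pairs produce
#'   identical scenes and identical rendered pixels.
#'
#' @return An object of class `scene_config` (a validated list).
#' @seealso [generate_scene()], [render_scene()]
#' @export
scene_config <- function(field_width_um = 688,
                         field_height_um = 512,
                         pixel_size_um = 0.43,
                         n_pre = 12,
                         n_new = 10,
                         p_cluster = 0.1,
                         cluster_radius_um = 40,
                         core_radius_meanlog = log(3),
                         core_radius_sdlog = 0.3,
                         core_radius_min_um = 2.2,
                         halo_radius_factor = 4,
                         multicore_p = 0.15,
                         extra_cores_mean = 0.3,
                         multicore_halo_growth = 0.3,
                         separate_p = 0.75,
                         background_mean = 100,
                         background_sd = 5,
                         amplitude = 150,
                         min_separation_um = 0,
                         seed = 1L) {
  cfg <- list(
    field_width_um = field_width_um, field_height_um = field_height_um,
    pixel_size_um = pixel_size_um,
    n_pre = as.integer(n_pre), n_new = as.integer(n_new),
    p_cluster = p_cluster, cluster_radius_um = cluster_radius_um,
    core_radius_meanlog = core_radius_meanlog,
    core_radius_sdlog = core_radius_sdlog,
    core_radius_min_um = core_radius_min_um,
    halo_radius_factor = halo_radius_factor,
    multicore_p = multicore_p, extra_cores_mean = extra_cores_mean,
    multicore_halo_growth = multicore_halo_growth,
    separate_p = separate_p,
    background_mean = background_mean, background_sd = background_sd,
    amplitude = amplitude, min_separation_um = min_separation_um,
    seed = as.integer(seed)
  )
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  for (nm in c("field_width_um", "field_height_um", "pixel_size_um",
               "cluster_radius_um", "core_radius_min_um", "background_sd"))
    stop_if_not_scalar_number(cfg[[nm]], nm, positive = TRUE)
  for (nm in c("p_cluster", "multicore_p", "separate_p")) {
    stop_if_not_scalar_number(cfg[[nm]], nm)
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop(sprintf("'%s' must lie in [0, 1]", nm), call. = FALSE)
  }
  if (cfg$n_pre < 0 || cfg$n_new < 0)
    stop("plaque counts must be non-negative", call. = FALSE)
  if (cfg$halo_radius_factor <= 1)
    stop("'halo_radius_factor' must be > 1", call. = FALSE)
  if (cfg$min_separation_um < 0)
    stop("'min_separation_um' must be >= 0", call. = FALSE)
  if (cfg$min_separation_um >= cfg$cluster_radius_um && cfg$p_cluster > 0)
    stop("'min_separation_um' must be below 'cluster_radius_um'",
         call. = FALSE)
  invisible(cfg)
}

rlnorm_trunc <- function(n, meanlog, sdlog, lower, max_tries = 1000L) {
  out <- stats::rlnorm(n, meanlog, sdlog)
  tries <- 0L
  while (any(bad <- out < lower)) {
    tries <- tries + 1L
    if (tries > max_tries) stop("core radius truncation failed to converge")
    out[bad] <- stats::rlnorm(sum(bad), meanlog, sdlog)
  }
  out
}

#' Generate a ground-truth plaque scene
#'
#' Places `n_pre` pre-existing plaques uniformly over the field, then deposits
#' `n_new` new plaques: each is clustered with probability `p_cluster`
#' (uniform on the disc of radius `cluster_radius_um` around a uniformly
#' chosen pre-existing centre, redrawn while it falls outside the field),
#' otherwise uniform over the field. Multicore halos are planted on
#' pre-existing plaques with probability `multicore_p`; extra cores are placed
#' inside the halo, kept clearly separate from the main core.
#'
#' @param config a [scene_config()].
#' @param seed optional seed overriding `config$seed`.
#' @param max_attempts bound on rejection-sampling redraws per clustered
#'   plaque; exceeding it signals a geometrically infeasible configuration.
#'
#' @return An object of class `plaque_scene` with elements:
#' \describe{
#'   \item{config}{the configuration used (seed resolved).}
#'   \item{pre}{data.frame of pre-existing plaques: `id`, `x_um`, `y_um`
#'     (main core centre), `core_radius_um`, `halo_radius_um`, `n_cores`,
#'     `fate` (`"separate"`/`"merged"`/`NA` for single-core).}
#'   \item{cores}{data.frame of all dense cores: `pre_id`, `core`,
#'     `x_um`, `y_um`, `radius_um`.}
#'   \item{new}{data.frame of new plaques: `id`, `x_um`, `y_um`, `radius_um`,
#'     `mechanism` (`"uniform"`/`"clustered"`), `parent_id` (`NA` for
#'     uniform), `nearest_pre_um`, `in_vicinity`.}
#'   \item{truth_vicinity_fraction}{fraction of new plaques whose nearest
#'     pre-existing centre is closer than `cluster_radius_um`; `NA` when
#'     `n_new` = 0 (flagged by `no_new`).}
#' }
#' @export
generate_scene <- function(config, seed = NULL, max_attempts = 1000L) {
  stopifnot(inherits(config, "scene_config"))
  validate_scene_config(config)
  seed <- as.integer(seed %||% config$seed)
  config$seed <- seed
  W <- config$field_width_um; H <- config$field_height_um
  R <- config$cluster_radius_um
  if (config$n_new > 0 && config$p_cluster > 0 && config$n_pre == 0)
    stop("p_cluster > 0 requires at least one pre-existing plaque")

  withr::with_seed(seed, {
    ## pre-existing plaques: uniform main-core centres (optionally kept at
    ## least min_separation_um apart by rejection)
    sep <- config$min_separation_um
    if (sep == 0) {
      px <- stats::runif(config$n_pre, 0, W)
      py <- stats::runif(config$n_pre, 0, H)
    } else {
      px <- py <- numeric(config$n_pre)
      for (j in seq_len(config$n_pre)) {
        ok <- FALSE
        for (att in seq_len(max_attempts)) {
          x <- stats::runif(1, 0, W); y <- stats::runif(1, 0, H)
          if (j == 1 || all((px[seq_len(j - 1)] - x)^2 +
                              (py[seq_len(j - 1)] - y)^2 >= sep^2)) {
            px[j] <- x; py[j] <- y; ok <- TRUE; break
          }
        }
        if (!ok) stop("min_separation_um is infeasible for this field")
      }
    }
    pre <- data.frame(
      id = seq_len(config$n_pre),
      x_um = px, y_um = py,
      core_radius_um = rlnorm_trunc(config$n_pre, config$core_radius_meanlog,
                                    config$core_radius_sdlog,
                                    config$core_radius_min_um)
    )
    pre$halo_radius_um <- pre$core_radius_um * config$halo_radius_factor
    pre$n_cores <- rep(1L, nrow(pre))
    pre$fate <- rep(NA_character_, nrow(pre))

    cores <- data.frame(pre_id = pre$id, core = rep(1L, nrow(pre)),
                        x_um = pre$x_um, y_um = pre$y_um,
                        radius_um = pre$core_radius_um)

    ## multicore halos: extra cores planted inside the halo, clearly separate
    ## from the main core and well inside the antibody boundary
    if (config$n_pre > 0 && config$multicore_p > 0) {
      is_multi <- stats::runif(config$n_pre) < config$multicore_p
      for (i in which(is_multi)) {
        n_extra <- 1L + stats::rpois(1L, config$extra_cores_mean)
        halo0 <- pre$halo_radius_um[i]
        pre$halo_radius_um[i] <-
          halo0 * (1 + config$multicore_halo_growth * n_extra)
        placed <- place_extra_cores(pre[i, ], n_extra, config)
        if (nrow(placed) == 0) pre$halo_radius_um[i] <- halo0
        if (nrow(placed) > 0) {
          placed$pre_id <- pre$id[i]
          placed$core <- seq_len(nrow(placed)) + 1L
          cores <- rbind(cores, placed[, names(cores)])
          pre$n_cores[i] <- 1L + nrow(placed)
          pre$fate[i] <- if (stats::runif(1) < config$separate_p)
            "separate" else "merged"
        }
      }
      cores <- cores[order(cores$pre_id, cores$core), , drop = FALSE]
      rownames(cores) <- NULL
    }

    ## new plaques
    n_new <- config$n_new
    new <- data.frame(
      id = integer(0), x_um = numeric(0), y_um = numeric(0),
      radius_um = numeric(0), mechanism = character(0),
      parent_id = integer(0)
    )
    if (n_new > 0) {
      clustered <- stats::runif(n_new) < config$p_cluster
      xs <- ys <- numeric(n_new)
      parent <- rep(NA_integer_, n_new)
      clear_of_others <- function(x, y, j) {
        if (sep == 0) return(TRUE)
        if (any((pre$x_um - x)^2 + (pre$y_um - y)^2 < sep^2)) return(FALSE)
        if (j > 1) {
          prev <- seq_len(j - 1)
          if (any((xs[prev] - x)^2 + (ys[prev] - y)^2 < sep^2)) return(FALSE)
        }
        TRUE
      }
      for (j in seq_len(n_new)) {
        if (clustered[j]) {
          ok <- FALSE
          for (att in seq_len(max_attempts)) {
            p <- sample.int(config$n_pre, 1L)
            r <- R * sqrt(stats::runif(1))
            th <- stats::runif(1, 0, 2 * pi)
            x <- pre$x_um[p] + r * cos(th); y <- pre$y_um[p] + r * sin(th)
            if (x >= 0 && x <= W && y >= 0 && y <= H &&
                r >= sep && clear_of_others(x, y, j)) {
              xs[j] <- x; ys[j] <- y; parent[j] <- pre$id[p]; ok <- TRUE
              break
            }
          }
          if (!ok)
            stop("clustered placement rejected ", max_attempts,
                 " times: cluster_radius_um is infeasible for this field")
        } else {
          ok <- FALSE
          for (att in seq_len(max_attempts)) {
            x <- stats::runif(1, 0, W); y <- stats::runif(1, 0, H)
            if (clear_of_others(x, y, j)) {
              xs[j] <- x; ys[j] <- y; ok <- TRUE; break
            }
          }
          if (!ok) stop("min_separation_um is infeasible for this field")
        }
      }
      new <- data.frame(
        id = seq_len(n_new), x_um = xs, y_um = ys,
        radius_um = rlnorm_trunc(n_new, config$core_radius_meanlog,
                                 config$core_radius_sdlog,
                                 config$core_radius_min_um),
        mechanism = ifelse(clustered, "clustered", "uniform"),
        parent_id = parent
      )
    }

    if (nrow(new) > 0 && nrow(pre) > 0) {
      new$nearest_pre_um <- nearest_dist(new[, c("x_um", "y_um")],
                                         pre[, c("x_um", "y_um")])
      new$in_vicinity <- new$nearest_pre_um < R
    } else if (nrow(new) > 0) {
      new$nearest_pre_um <- NA_real_
      new$in_vicinity <- FALSE
    }

    tvf <- if (nrow(new) > 0) mean(new$in_vicinity) else NA_real_

    structure(list(config = config, pre = pre, cores = cores, new = new,
                   truth_vicinity_fraction = tvf,
                   no_new = nrow(new) == 0L),
              class = "plaque_scene")
  })
}

## Extra cores must (a) stay well inside the suprathreshold antibody halo so
## their centroids are contained in the rendered AB mask, and (b) keep enough
## separation from the main core and each other to remain distinct 8-connected
## components after thresholding. Infeasible placements are dropped (the
## plaque then stays single-core in the ground truth).
place_extra_cores <- function(pre_row, n_extra, config, max_attempts = 200L) {
  halo <- pre_row$halo_radius_um
  out <- data.frame(x_um = numeric(0), y_um = numeric(0),
                    radius_um = numeric(0))
  sep_factor <- 0.95  # conservative suprathreshold radius / core radius bound
  margin <- 2 * config$pixel_size_um
  for (k in seq_len(n_extra)) {
    r_extra <- min(rlnorm_trunc(1, config$core_radius_meanlog - log(1.8),
                                config$core_radius_sdlog,
                                config$core_radius_min_um),
                   0.6 * pre_row$core_radius_um)
    r_extra <- max(r_extra, config$core_radius_min_um * 0.9)
    hi <- 0.55 * halo - 0
    lo <- sep_factor * (pre_row$core_radius_um + r_extra) + margin
    if (lo >= hi) next
    for (att in seq_len(max_attempts)) {
      d <- stats::runif(1, lo, hi)
      th <- stats::runif(1, 0, 2 * pi)
      x <- pre_row$x_um + d * cos(th); y <- pre_row$y_um + d * sin(th)
      inside <- x >= 0 && x <= config$field_width_um &&
        y >= 0 && y <= config$field_height_um
      clear <- if (nrow(out) == 0) TRUE else
        all(sqrt((out$x_um - x)^2 + (out$y_um - y)^2) >
              sep_factor * (out$radius_um + r_extra) + margin)
      if (inside && clear) {
        out <- rbind(out, data.frame(x_um = x, y_um = y, radius_um = r_extra))
        break
      }
    }
  }
  out
}

#' @export
print.plaque_scene <- function(x, ...) {
  cat(sprintf("plaque_scene: %d pre-existing (%d multicore), %d new (%d clustered)\n",
              nrow(x$pre), sum(x$pre$n_cores >= 2), nrow(x$new),
              sum(x$new$mechanism == "clustered")))
  cat(sprintf("  field %.0f x %.0f um @ %.2f um/px; truth vicinity fraction %s\n",
              x$config$field_width_um, x$config$field_height_um,
              x$config$pixel_size_um,
              ifelse(x$no_new, "undefined (no new plaques)",
                     sprintf("%.3f", x$truth_vicinity_fraction))))
  invisible(x)
}
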