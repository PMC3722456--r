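## Rendering of ground-truth scenes into noisy multichannel images.
##
## Channel conventions (matching the staining design the analysis targets):
##   MX  - in vivo dense-core label: a blob at every core of every
##         pre-existing plaque, and nothing else.
##   AB  - pan-amyloid antibody: halo-sized blobs at pre-existing plaques,
##         core-sized blobs at new plaques.
##   TR  - post-mortem dense-core counterstain: one blob per core when the
##         plaque's cores remained separate, a single covering blob when they
##         merged; also marks single cores and new plaques (dense by default).

## Adds a truncated isotropic Gaussian blob (zero beyond 3 sigma) in place.
## Pixel (row r, col c), 1-based, has centre ((c-0.5)*psz, (r-0.5)*psz) um.
add_blob <- function(mat, cx_um, cy_um, sigma_um, amplitude, pixel_size_um) {
  psz <- pixel_size_um
  nr <- nrow(mat); nc <- ncol(mat)
  ext <- 3 * sigma_um
  c0 <- max(1L, floor((cx_um - ext) / psz) + 1L)
  c1 <- min(nc, ceiling((cx_um + ext) / psz))
  r0 <- max(1L, floor((cy_um - ext) / psz) + 1L)
  r1 <- min(nr, ceiling((cy_um + ext) / psz))
  if (c0 > c1 || r0 > r1) return(mat)
  dx <- ((c0:c1) - 0.5) * psz - cx_um
  dy <- ((r0:r1) - 0.5) * psz - cy_um
  d2 <- outer(dy^2, dx^2, `+`)
  g <- amplitude * exp(-d2 / (2 * sigma_um^2))
  g[d2 > ext^2] <- 0
  mat[r0:r1, c0:c1] <- mat[r0:r1, c0:c1] + g
  mat
}

#' Render a synthetic scene as a noisy multichannel image
#'
#' Rasterises a [generate_scene()] ground truth into 2 or 3 intensity
#' channels. Blobs are isotropic Gaussians with `sigma = radius / 2`,
#' truncated at 3 sigma; additive Gaussian background noise
#' (`background_mean`, `background_sd`) is applied to every channel and
#' intensities are clipped at 0.
#'
#' @param scene a `plaque_scene`.
#' @param channels character vector among `c("MX", "AB", "TR")`.
#' @param noise_seed seed for the noise draw; defaults to a fixed offset of
#'   the scene seed so that identical `(config, seed)` renders bit-identically.
#' @return An object of class `scene_render`: list with `img` (array
#'   `[rows, cols, channels]`), `channels`, `pixel_size_um`, `scene`.
#' @export
render_scene <- function(scene, channels = c("MX", "AB", "TR"),
                         noise_seed = NULL) {
  stopifnot(inherits(scene, "plaque_scene"))
  channels <- match.arg(channels, c("MX", "AB", "TR"), several.ok = TRUE)
  cfg <- scene$config
  psz <- cfg$pixel_size_um
  nc <- floor(cfg$field_width_um / psz)
  nr <- floor(cfg$field_height_um / psz)
  if (nc < 1 || nr < 1) stop("field smaller than one pixel")
  noise_seed <- as.integer(noise_seed %||% (cfg$seed + 104729L) %% (2^31 - 1))

  blank <- matrix(0, nr, nc)
  out <- array(0, dim = c(nr, nc, length(channels)),
               dimnames = list(NULL, NULL, channels))

  for (ch in channels) {
    m <- blank
    if (ch == "MX") {
      for (i in seq_len(nrow(scene$cores)))
        m <- add_blob(m, scene$cores$x_um[i], scene$cores$y_um[i],
                      scene$cores$radius_um[i] / 2, cfg$amplitude, psz)
    } else if (ch == "AB") {
      for (i in seq_len(nrow(scene$pre)))
        m <- add_blob(m, scene$pre$x_um[i], scene$pre$y_um[i],
                      scene$pre$halo_radius_um[i] / 2, cfg$amplitude, psz)
      for (i in seq_len(nrow(scene$new)))
        m <- add_blob(m, scene$new$x_um[i], scene$new$y_um[i],
                      scene$new$radius_um[i] / 2, cfg$amplitude, psz)
    } else if (ch == "TR") {
      for (i in seq_len(nrow(scene$pre))) {
        p <- scene$pre[i, ]
        cs <- scene$cores[scene$cores$pre_id == p$id, , drop = FALSE]
        if (p$n_cores >= 2 && identical(p$fate, "merged")) {
          # one covering dense structure: centre of mass of the cores, sigma
          # wide enough that the suprathreshold region spans all core centres
          cx <- mean(cs$x_um); cy <- mean(cs$y_um)
          spread <- max(sqrt((cs$x_um - cx)^2 + (cs$y_um - cy)^2) +
                          cs$radius_um)
          m <- add_blob(m, cx, cy, max(max(cs$radius_um) / 2, spread / 1.2),
                        cfg$amplitude, psz)
        } else {
          for (k in seq_len(nrow(cs)))
            m <- add_blob(m, cs$x_um[k], cs$y_um[k], cs$radius_um[k] / 2,
                          cfg$amplitude, psz)
        }
      }
      for (i in seq_len(nrow(scene$new)))
        m <- add_blob(m, scene$new$x_um[i], scene$new$y_um[i],
                      scene$new$radius_um[i] / 2, cfg$amplitude, psz)
    }
    out[, , ch] <- m
  }

  withr::with_seed(noise_seed, {
    noise <- array(stats::rnorm(length(out), cfg$background_mean,
                                cfg$background_sd), dim = dim(out))
  })
  out <- out + noise
  out[out < 0] <- 0

  structure(list(img = out, channels = channels, pixel_size_um = psz,
                 scene = scene),
            class = "scene_render")
}

#' Write a rendered scene to disk
#'
#' Writes a multi-page 32-bit float TIFF (one page per channel, intensities
#' divided by `scale` to fit the TIFF float convention), a sidecar
#' ground-truth CSV and a JSON echo of the scene configuration.
#'
#' @param render a `scene_render`.
#' @param dir output directory (created if missing).
#' @param name basename for the three files.
#' @param scale intensity divisor applied before writing (default 1000).
#' @return Invisibly, the paths written.
#' @export
write_scene <- function(render, dir, name = "scene", scale = 1000) {
  stopifnot(inherits(render, "scene_render"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tif <- file.path(dir, paste0(name, ".tif"))
  pages <- lapply(seq_along(render$channels),
                  function(k) render$img[, , k] / scale)
  tiff::writeTIFF(pages, tif, bits.per.sample = 32L, reduce = FALSE)

  truth <- scene_truth_table(render$scene)
  csv <- file.path(dir, paste0(name, "_truth.csv"))
  utils::write.csv(truth, csv, row.names = FALSE)

  cfg <- file.path(dir, paste0(name, "_config.json"))
  meta <- c(unclass(render$scene$config),
            list(channels = render$channels, intensity_scale = scale))
  jsonlite::write_json(meta, cfg, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(tif = tif, truth = csv, config = cfg))
}

#' Read a scene written by [write_scene()]
#' @param dir directory containing the files.
#' @param name basename used at write time.
#' @return list with `img` array (intensities rescaled), `channels`,
#'   `pixel_size_um`, `truth` data.frame, `config` list.
#' @export
read_scene <- function(dir, name = "scene") {
  cfg <- jsonlite::read_json(file.path(dir, paste0(name, "_config.json")),
                             simplifyVector = TRUE)
  pages <- tiff::readTIFF(file.path(dir, paste0(name, ".tif")), all = TRUE)
  img <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)),
               dimnames = list(NULL, NULL, cfg$channels))
  for (k in seq_along(pages)) img[, , k] <- pages[[k]] * cfg$intensity_scale
  truth <- utils::read.csv(file.path(dir, paste0(name, "_truth.csv")))
  list(img = img, channels = cfg$channels,
       pixel_size_um = cfg$pixel_size_um, truth = truth, config = cfg)
}

#' Flatten a scene's ground truth into one table
#' @param scene a `plaque_scene`.
#' @return data.frame: `plaque_id`, `kind` (`"pre"`/`"new"`), `x_um`, `y_um`,
#'   `radius_um`, `n_cores`, `mechanism`, `parent_id`, `fate`.
#' @export
scene_truth_table <- function(scene) {
  pre <- data.frame(plaque_id = paste0("pre_", scene$pre$id), kind = "pre",
                    x_um = scene$pre$x_um, y_um = scene$pre$y_um,
                    radius_um = scene$pre$core_radius_um,
                    n_cores = scene$pre$n_cores,
                    mechanism = NA_character_, parent_id = NA_character_,
                    fate = scene$pre$fate)
  if (nrow(scene$new) > 0) {
    new <- data.frame(plaque_id = paste0("new_", scene$new$id), kind = "new",
                      x_um = scene$new$x_um, y_um = scene$new$y_um,
                      radius_um = scene$new$radius_um, n_cores = 0L,
                      mechanism = scene$new$mechanism,
                      parent_id = ifelse(is.na(scene$new$parent_id),
                                         NA_character_,
                                         paste0("pre_", scene$new$parent_id)),
                      fate = NA_character_)
    rbind(pre, new)
  } else pre
}
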