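## Detection: background-noise-scaled thresholding and connected components.

#' Estimate the background noise of an image channel
#'
#' Computes the mean and standard deviation of pixel intensities over a
#' plaque-free region. If no region is given, a deterministic fallback picks
#' the 5th-percentile-mean tile of an 8 x 8 tiling of the image, replacing
#' the manual choice of a plaque-free region.
#'
#' @param channel numeric matrix (rows = y, cols = x).
#' @param region optional region spec, a list/vector with `x`, `y`, `w`, `h`
#'   in 0-based pixel coordinates (origin top-left, x = column).
#' @param min_pixels minimum region size (default 100).
#' @return Object of class `background_model`: list with `mean`, `sd`,
#'   `region` (the region actually used, 0-based `x`, `y`, `w`, `h`).
#' @export
estimate_background <- function(channel, region = NULL, min_pixels = 100L) {
  stopifnot(is.matrix(channel), is.numeric(channel))
  if (is.null(region)) {
    region <- background_fallback_region(channel)
  }
  region <- as.list(region)
  x <- region$x; y <- region$y; w <- region$w; h <- region$h
  if (any(vapply(list(x, y, w, h), is.null, TRUE)))
    stop("region must provide x, y, w, h")
  if (x < 0 || y < 0 || x + w > ncol(channel) || y + h > nrow(channel))
    stop("background region lies outside the image")
  if (w * h < min_pixels)
    stop(sprintf("background region has %d pixels; need >= %d", w * h,
                 min_pixels))
  px <- channel[(y + 1):(y + h), (x + 1):(x + w)]
  structure(list(mean = mean(px), sd = stats::sd(as.vector(px)),
                 region = list(x = x, y = y, w = w, h = h)),
            class = "background_model")
}

## Deterministic plaque-free-region surrogate: tile the image 8 x 8 and take
## the tile whose mean intensity sits at the 5th percentile of tile means
## (4th-dimmest of 64) - dim enough to avoid plaques, not the single minimum
## (which can undershoot the noise floor).
background_fallback_region <- function(channel, n_tiles = 8L, q = 0.05) {
  nr <- nrow(channel); nc <- ncol(channel)
  ys <- floor(seq(0, nr, length.out = n_tiles + 1))
  xs <- floor(seq(0, nc, length.out = n_tiles + 1))
  means <- matrix(NA_real_, n_tiles, n_tiles)
  for (i in seq_len(n_tiles)) for (j in seq_len(n_tiles)) {
    means[i, j] <- mean(channel[(ys[i] + 1):ys[i + 1], (xs[j] + 1):xs[j + 1]])
  }
  ord <- order(means)
  pick <- ord[max(1L, ceiling(q * length(ord)))]
  i <- (pick - 1L) %% n_tiles + 1L
  j <- (pick - 1L) %/% n_tiles + 1L
  list(x = xs[j], y = ys[i], w = xs[j + 1] - xs[j], h = ys[i + 1] - ys[i])
}

## 8-connected labelling: EBImage::bwlabel is 4-connected, so components that
## touch only diagonally are merged afterwards with a union-find pass over
## the two diagonal shift directions.
label_components_8 <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]      # down-right neighbours
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]     # up-right neighbours
  keep1 <- a1 > 0 & b1 > 0 & a1 != b1
  keep2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  if (nrow(pairs) > 0) {
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(n), find, integer(1))
    remap <- match(root, sort(unique(root)))
    nz <- lab > 0
    lab[nz] <- remap[lab[nz]]
  }
  lab
}

## Region table from a label matrix. Centroids are unweighted mask centroids
## reported both in 0-based pixel coordinates (pixel centre at index + 0.5)
## and in micrometres.
region_table <- function(lab, channel, pixel_size_um) {
  n <- max(lab)
  if (n == 0L) {
    return(data.frame(id = integer(0), x_px = numeric(0), y_px = numeric(0),
                      x_um = numeric(0), y_um = numeric(0),
                      area_px = integer(0), area_um2 = numeric(0),
                      mean_intensity = numeric(0), min_rowmajor = numeric(0)))
  }
  idx <- which(lab > 0)
  lv <- lab[idx]
  rows0 <- (idx - 1L) %% nrow(lab)        # 0-based row (y)
  cols0 <- (idx - 1L) %/% nrow(lab)       # 0-based col (x)
  area <- tabulate(lv, n)
  sx <- rowsum(as.numeric(cols0), lv)[, 1]
  sy <- rowsum(as.numeric(rows0), lv)[, 1]
  si <- rowsum(as.numeric(channel[idx]), lv)[, 1]
  rowmajor <- as.numeric(rows0) * ncol(lab) + as.numeric(cols0)
  minrm <- vapply(split(rowmajor, factor(lv, levels = seq_len(n))),
                  min, numeric(1))
  data.frame(
    id = seq_len(n),
    x_px = sx / area + 0.5, y_px = sy / area + 0.5,
    x_um = (sx / area + 0.5) * pixel_size_um,
    y_um = (sy / area + 0.5) * pixel_size_um,
    area_px = area, area_um2 = area * pixel_size_um^2,
    mean_intensity = si / area,
    min_rowmajor = as.numeric(minrm)
  )
}

#' Detect plaque regions in one channel
#'
#' Thresholds the channel at `background$mean + multiplier * background$sd`
#' (detection stringency of nine background standard deviations by default),
#' labels 8-connected components of the suprathreshold mask and keeps those
#' with at least `min_area_px` pixels (putative plaques of >= 20 px by
#' default). Regions are sorted by descending area with a deterministic
#' tie-break on the row-major position of each mask's first pixel.
#'
#' @param channel numeric matrix.
#' @param background a `background_model` from [estimate_background()];
#'   `sd` must be > 0, otherwise the threshold is undefined and an error is
#'   raised.
#' @param pixel_size_um calibration, micrometres per pixel.
#' @param min_area_px minimum component area in pixels (default 20).
#' @param multiplier noise multiplier of the threshold (default 9).
#' @param border_margin_px optional exclusion band: components whose centroid
#'   lies within this many pixels of an image edge are discarded
#'   (deterministic surrogate for manual removal of section-edge artefacts;
#'   default 0 = keep all).
#' @return Object of class `plaque_regions`: list with `regions` (data.frame
#'   `id`, `x_px`, `y_px`, `x_um`, `y_um`, `area_px`, `area_um2`,
#'   `mean_intensity`), `labels` (integer matrix relabelled to match `id`),
#'   `pixel_size_um`, `threshold`, `background`.
#' @export
detect_plaques <- function(channel, background, pixel_size_um,
                           min_area_px = 20L, multiplier = 9,
                           border_margin_px = 0L) {
  stopifnot(inherits(background, "background_model"))
  stop_if_not_scalar_number(pixel_size_um, "pixel_size_um", positive = TRUE)
  if (!is.finite(background$sd) || background$sd <= 0)
    stop("background sd is 0: the noise-scaled threshold is undefined")
  thr <- background$mean + multiplier * background$sd
  mask <- channel > thr
  lab <- label_components_8(mask)
  reg <- region_table(lab, channel, pixel_size_um)
  reg <- reg[reg$area_px >= min_area_px, , drop = FALSE]
  if (border_margin_px > 0 && nrow(reg) > 0) {
    m <- border_margin_px
    keep <- reg$x_px >= m & reg$y_px >= m &
      reg$x_px <= ncol(channel) - m & reg$y_px <= nrow(channel) - m
    reg <- reg[keep, , drop = FALSE]
  }
  ## sort: descending area, ties broken by row-major position of the mask's
  ## first (minimum) pixel
  if (nrow(reg) > 0) {
    ord <- order(-reg$area_px, reg$min_rowmajor)
    reg <- reg[ord, , drop = FALSE]
    new_id <- seq_len(nrow(reg))
    remap <- integer(max(lab))
    remap[reg$id] <- new_id
    nz <- lab > 0
    lab[nz] <- ifelse(remap[lab[nz]] == 0L, 0L, remap[lab[nz]])
    reg$id <- new_id
    rownames(reg) <- NULL
  } else {
    lab[] <- 0L
  }
  reg$min_rowmajor <- NULL
  structure(list(regions = reg, labels = lab, pixel_size_um = pixel_size_um,
                 threshold = thr, background = background),
            class = "plaque_regions")
}

#' Detect antibody plaques for size-distribution analysis
#'
#' The size-distribution variant of detection: Gaussian smoothing, background
#' subtraction (subtract the background mean, clip at 0), the same
#' noise-scaled threshold, and a stricter minimum area of 30 px
#' (>= 5.5 um^2 at 0.43 um/px).
#'
#' @inheritParams detect_plaques
#' @param sigma_px smoothing kernel SD in pixels (default 1).
#' @param min_area_px minimum area, default 30.
#' @return A `plaque_regions` object (areas measured on the smoothed,
#'   background-subtracted image).
#' @export
detect_for_size_distribution <- function(channel, background, pixel_size_um,
                                         sigma_px = 1, min_area_px = 30L,
                                         multiplier = 9) {
  stopifnot(inherits(background, "background_model"))
  if (!is.finite(background$sd) || background$sd <= 0)
    stop("background sd is 0: the noise-scaled threshold is undefined")
  sm <- EBImage::gblur(channel, sigma = sigma_px)
  sm <- matrix(as.numeric(sm), nrow(channel), ncol(channel))
  sm <- sm - background$mean
  sm[sm < 0] <- 0
  bg0 <- structure(list(mean = 0, sd = background$sd,
                        region = background$region),
                   class = "background_model")
  detect_plaques(sm, bg0, pixel_size_um, min_area_px = min_area_px,
                 multiplier = multiplier)
}

#' @export
print.plaque_regions <- function(x, ...) {
  cat(sprintf("plaque_regions: %d regions, threshold %.2f, %.2f um/px\n",
              nrow(x$regions), x$threshold, x$pixel_size_um))
  invisible(x)
}
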