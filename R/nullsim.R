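## Random-placement Monte Carlo null for the vicinity proportion.

#' Random-placement null simulation for one image
#'
#' For each of `n_iterations` iterations, places `n_new` points uniformly at
#' random over the image field, measures each point's distance to the centre
#' of the closest pre-existing plaque, and records the proportion of points
#' closer than `radius_um` ("new in vicinity" occurring by chance). The mean
#' over iterations is the chance level the observed proportion is compared
#' against.
#'
#' @param pre_centers matrix or data.frame of pre-existing plaque centres in
#'   micrometres (columns `x_um`, `y_um`, or two unnamed columns).
#' @param n_new number of new plaques counted in the original image (>= 1
#'   for a meaningful simulation; 0 returns a structured "no new plaques"
#'   result).
#' @param field field size `c(width_um, height_um)` (default the 688 x 512 um
#'   imaging field).
#' @param radius_um vicinity radius, strict `<` (default 40).
#' @param n_iterations Monte Carlo iterations (default 1000).
#' @param seed RNG seed; if `image_id` is given the per-image stream seed is
#'   derived with [derive_stream_seed()], making results independent of the
#'   order in which images are processed.
#' @param image_id optional image identifier.
#' @param observed_vicinity_prop observed proportion from the classification
#'   stage (carried through into the result for pairing).
#' @return Object of class `nullsim_result`: list with `image_id`, `n_new`,
#'   `observed_vicinity_prop`, `iteration_props` (length `n_iterations`),
#'   `chance_mean`, `n_iterations`, `seed`, `no_new` flag.
#' @export
simulate_random_placement <- function(pre_centers, n_new,
                                      field = c(688, 512), radius_um = 40,
                                      n_iterations = 1000L, seed = 1L,
                                      image_id = NULL,
                                      observed_vicinity_prop = NA_real_) {
  pc <- as.matrix(as.data.frame(pre_centers))
  if (!is.null(colnames(pc)) && all(c("x_um", "y_um") %in% colnames(pc)))
    pc <- pc[, c("x_um", "y_um"), drop = FALSE]
  storage.mode(pc) <- "double"
  stopifnot(length(field) == 2, all(field > 0))
  n_new <- as.integer(n_new)
  n_iterations <- as.integer(n_iterations)
  use_seed <- if (!is.null(image_id)) derive_stream_seed(seed, image_id)
              else as.integer(seed)
  if (n_new == 0L) {
    return(structure(list(image_id = image_id, n_new = 0L,
                          observed_vicinity_prop = observed_vicinity_prop,
                          iteration_props = numeric(0), chance_mean = NA_real_,
                          n_iterations = n_iterations, seed = use_seed,
                          no_new = TRUE),
                     class = "nullsim_result"))
  }
  if (nrow(pc) == 0L)
    stop("at least one pre-existing centre is required")
  r2 <- radius_um^2
  withr::with_seed(use_seed, {
    total <- n_iterations * n_new
    ## chunked so very long runs (e.g. 1e5 iterations) stay memory-bounded
    chunk <- max(1L, min(n_iterations, ceiling(2e6 / n_new)))
    props <- numeric(n_iterations)
    done <- 0L
    while (done < n_iterations) {
      nit <- min(chunk, n_iterations - done)
      m <- nit * n_new
      x <- stats::runif(m, 0, field[1])
      y <- stats::runif(m, 0, field[2])
      d2 <- rep(Inf, m)
      for (k in seq_len(nrow(pc)))
        d2 <- pmin(d2, (x - pc[k, 1])^2 + (y - pc[k, 2])^2)
      hit <- d2 < r2
      props[(done + 1L):(done + nit)] <-
        rowsum(as.numeric(hit), rep(seq_len(nit), each = n_new))[, 1] / n_new
      done <- done + nit
    }
  })
  structure(list(image_id = image_id, n_new = n_new,
                 observed_vicinity_prop = observed_vicinity_prop,
                 iteration_props = props, chance_mean = mean(props),
                 n_iterations = n_iterations, seed = use_seed,
                 no_new = FALSE),
            class = "nullsim_result")
}

#' @export
print.nullsim_result <- function(x, ...) {
  cat(sprintf(
    "nullsim_result%s: n_new = %d, observed = %s, chance mean = %s (%d iterations)\n",
    if (is.null(x$image_id)) "" else paste0(" [", x$image_id, "]"),
    x$n_new,
    ifelse(is.na(x$observed_vicinity_prop), "NA",
           sprintf("%.3f", x$observed_vicinity_prop)),
    ifelse(is.na(x$chance_mean), "NA", sprintf("%.4f", x$chance_mean)),
    x$n_iterations))
  invisible(x)
}

#' Exact chance vicinity fraction for a fixed layout
#'
#' Numerically integrates, on a fine pixel grid, the area of the union of
#' vicinity discs around the given centres clipped to the field, divided by
#' the field area. Serves as the deterministic oracle the Monte Carlo chance
#' mean converges to.
#'
#' @inheritParams simulate_random_placement
#' @param grid_um grid spacing in micrometres (default 0.25).
#' @return A single number in `[0, 1]`.
#' @export
chance_vicinity_fraction <- function(pre_centers, field = c(688, 512),
                                     radius_um = 40, grid_um = 0.25) {
  pc <- as.matrix(as.data.frame(pre_centers))
  if (!is.null(colnames(pc)) && all(c("x_um", "y_um") %in% colnames(pc)))
    pc <- pc[, c("x_um", "y_um"), drop = FALSE]
  xs <- seq(grid_um / 2, field[1], by = grid_um)
  ys <- seq(grid_um / 2, field[2], by = grid_um)
  r2 <- radius_um^2
  inside <- 0
  for (yv in ys) {
    d2 <- rep(Inf, length(xs))
    for (k in seq_len(nrow(pc)))
      d2 <- pmin(d2, (xs - pc[k, 1])^2 + (yv - pc[k, 2])^2)
    inside <- inside + sum(d2 < r2)
  }
  inside / (length(xs) * length(ys))
}

#' Matched-pairs comparison of observed versus chance vicinity proportions
#'
#' Aggregates per-image results to one observed and one chance proportion
#' per animal (new-plaque-count-weighted means by default, so each deposited
#' plaque counts equally within an animal), then runs a two-sided Wilcoxon
#' matched-pairs signed-rank test on the per-animal pairs. Zero differences
#' are dropped (Wilcoxon convention) and counted; the exact distribution is
#' used for up to 25 informative pairs when there are no ties, the normal
#' approximation with continuity correction otherwise.
#'
#' @param results list of `nullsim_result` objects (images with
#'   `n_new = 0` are excluded from aggregation).
#' @param grouping data.frame mapping `image_id` to `animal_id`.
#' @param weighted logical; `FALSE` gives the unweighted per-image mean.
#' @return list with `per_animal` (data.frame `animal_id`, `n_images`,
#'   `n_new`, `observed`, `chance`), `statistic` (Wilcoxon V), `p_value`,
#'   `n_pairs`, `n_zero_dropped`, `zero_differences` flag, `method`.
#' @export
paired_comparison <- function(results, grouping, weighted = TRUE) {
  stopifnot(is.list(results),
            all(c("image_id", "animal_id") %in% names(grouping)))
  rows <- lapply(results, function(r) {
    stopifnot(inherits(r, "nullsim_result"))
    if (r$no_new) return(NULL)
    data.frame(image_id = as.character(r$image_id), n_new = r$n_new,
               observed = r$observed_vicinity_prop, chance = r$chance_mean)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0)
    stop("no images with new plaques to compare")
  tab <- merge(tab, grouping[, c("image_id", "animal_id")], by = "image_id")
  if (anyNA(tab$animal_id) || nrow(tab) == 0)
    stop("grouping does not cover the supplied images")
  w <- if (weighted) tab$n_new else rep(1, nrow(tab))
  agg <- do.call(rbind, lapply(split(seq_len(nrow(tab)), tab$animal_id),
    function(ix) data.frame(
      animal_id = tab$animal_id[ix[1]],
      n_images = length(ix),
      n_new = sum(tab$n_new[ix]),
      observed = stats::weighted.mean(tab$observed[ix], w[ix]),
      chance = stats::weighted.mean(tab$chance[ix], w[ix]))))
  rownames(agg) <- NULL
  if (nrow(agg) < 2) stop("at least 2 animals are required")
  if (nrow(agg) < 6)
    warning("fewer than 6 animals: the signed-rank test has little power")
  d <- agg$observed - agg$chance
  nz <- d[d != 0]
  n_zero <- sum(d == 0)
  if (length(nz) == 0) {
    return(list(per_animal = agg, statistic = NA_real_, p_value = 1,
                n_pairs = 0L, n_zero_dropped = n_zero,
                zero_differences = TRUE,
                method = "Wilcoxon matched-pairs signed-rank (degenerate)"))
  }
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(
    stats::wilcox.test(nz, alternative = "two.sided", mu = 0,
                       exact = exact, correct = TRUE))
  list(per_animal = agg, statistic = unname(wt$statistic),
       p_value = wt$p.value, n_pairs = length(nz), n_zero_dropped = n_zero,
       zero_differences = FALSE,
       method = paste0("Wilcoxon matched-pairs signed-rank, ",
                       if (exact) "exact" else "normal approximation"))
}
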