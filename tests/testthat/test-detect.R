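test_that("background estimation recovers the moments of the region", {
  # constant field
  m <- matrix(7.5, 60, 60)
  bg <- estimate_background(m, list(x = 0, y = 0, w = 60, h = 60))
  expect_equal(bg$mean, 7.5)
  expect_equal(bg$sd, 0)
  # i.i.d. Gaussian noise, 1e4-pixel region: sampling theory bounds
  set.seed(10)
  g <- matrix(rnorm(1e4, 100, 5), 100, 100)
  bg <- estimate_background(g, list(x = 0, y = 0, w = 100, h = 100))
  expect_lt(abs(bg$mean - 100), 3 * 5 / sqrt(1e4))
  expect_lt(abs(bg$sd - 5) / 5, 0.10)
  # undersized region
  expect_error(estimate_background(g, list(x = 0, y = 0, w = 7, h = 7)),
               "pixels")
  # region outside the image
  expect_error(estimate_background(g, list(x = 50, y = 50, w = 60, h = 60)),
               "outside")
})

test_that("the automatic fallback region avoids plaques", {
  set.seed(4)
  img <- matrix(rnorm(400 * 400, 50, 2), 400, 400)
  img[disc_mask(400, 400, 100, 100, 60)] <- 500  # one huge bright plaque
  bg <- estimate_background(img)
  expect_lt(abs(bg$mean - 50), 1)
  expect_lt(abs(bg$sd - 2), 0.5)
})

test_that("zero background SD is an explicit error, not a silent fallback", {
  m <- matrix(5, 50, 50)
  bg <- estimate_background(m, list(x = 0, y = 0, w = 50, h = 50))
  expect_error(detect_plaques(m, bg, 0.43), "undefined")
  expect_error(detect_for_size_distribution(m, bg, 0.43), "undefined")
})

test_that("one rendered high-SNR blob yields one region at the planted
           centre", {
  cfg <- scene_config(n_pre = 0, n_new = 1, p_cluster = 0,
                      background_sd = 1, amplitude = 100)  # peak 100 x sd
  sc <- generate_scene(cfg, seed = 8)
  sc$new$x_um <- 300; sc$new$y_um <- 250; sc$new$radius_um <- 3
  ren <- render_scene(sc, channels = "AB")
  bg <- estimate_background(ren$img[, , "AB"])
  det <- detect_plaques(ren$img[, , "AB"], bg, cfg$pixel_size_um)
  expect_equal(nrow(det$regions), 1)
  expect_lt(abs(det$regions$x_um - 300), cfg$pixel_size_um)
  expect_lt(abs(det$regions$y_um - 250), cfg$pixel_size_um)
})

test_that("area filters cut exactly at the minimum pixel count", {
  # constructed noise-free masks around the 20 px detection boundary
  for (n_px in c(19, 20, 29, 30)) {
    img <- matrix(0, 50, 50)
    cols <- ((seq_len(n_px) - 1) %% 5) + 20
    rows <- ((seq_len(n_px) - 1) %/% 5) + 20
    img[cbind(rows, cols)] <- 100
    bg <- structure(list(mean = 0, sd = 1,
                         region = list(x = 0, y = 0, w = 50, h = 50)),
                    class = "background_model")
    det20 <- detect_plaques(img, bg, 0.5, min_area_px = 20L)
    det30 <- detect_plaques(img, bg, 0.5, min_area_px = 30L)
    expect_equal(nrow(det20$regions), as.integer(n_px >= 20))
    expect_equal(nrow(det30$regions), as.integer(n_px >= 30))
    if (n_px == 30) {
      expect_equal(det30$regions$area_um2, 30 * 0.5^2)
    }
  }
})

test_that("pure-noise images produce no detections (9 sigma stringency)", {
  # per-pixel exceedance P(Z > 9) ~ 1.1e-19: expect zero false positives
  n_regions <- 0L
  for (s in 1:20) {
    set.seed(s)
    img <- matrix(rnorm(512 * 512, 100, 5), 512, 512)
    bg <- estimate_background(img, list(x = 0, y = 0, w = 512, h = 512))
    det <- detect_plaques(img, bg, 0.43, min_area_px = 1L)
    n_regions <- n_regions + nrow(det$regions)
  }
  expect_equal(n_regions, 0L)
})

test_that("raising the threshold multiplier never adds regions", {
  sc <- generate_scene(small_scene_config())
  ren <- render_scene(sc, channels = "AB")
  img <- ren$img[, , "AB"]
  bg <- estimate_background(img)
  counts <- vapply(c(3, 6, 9, 15, 25),
                   function(m) nrow(detect_plaques(img, bg, 0.43,
                                                   multiplier = m)$regions),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("labelling equals a brute-force flood-fill oracle and is
           8-connected", {
  set.seed(77)
  for (rep in 1:10) {
    mask <- matrix(runif(30 * 30) < 0.25, 30, 30)
    img <- mask * 100
    bg <- structure(list(mean = 0, sd = 1,
                         region = list(x = 0, y = 0, w = 30, h = 30)),
                    class = "background_model")
    det <- detect_plaques(img, bg, 1, min_area_px = 1L)
    oracle <- flood_components(mask)
    expect_equal(nrow(det$regions), max(oracle))
    # identical partition: labels must be a relabelling of the oracle
    both <- table(det$labels[mask], oracle[mask])
    expect_true(all(rowSums(both > 0) == 1))
    expect_true(all(colSums(both > 0) == 1))
  }
  # explicit diagonal case
  diag_mask <- matrix(0, 4, 4); diag_mask[1, 1] <- 1; diag_mask[2, 2] <- 1
  bg <- structure(list(mean = 0, sd = 1,
                       region = list(x = 0, y = 0, w = 4, h = 4)),
                  class = "background_model")
  det <- detect_plaques(diag_mask * 50, bg, 1, min_area_px = 1L)
  expect_equal(nrow(det$regions), 1)
  expect_equal(det$regions$area_px, 2)
})

test_that("regions are sorted by area with a deterministic tie-break", {
  img <- matrix(0, 40, 40)
  img[disc_mask(40, 40, 10, 10, 5)] <- 100   # big blob
  img[30:31, 30:32] <- 100                   # 6 px
  img[5:6, 30:32] <- 100                     # 6 px, earlier row-major pos
  bg <- structure(list(mean = 0, sd = 1,
                       region = list(x = 0, y = 0, w = 40, h = 40)),
                  class = "background_model")
  det <- detect_plaques(img, bg, 1, min_area_px = 1L)
  expect_equal(nrow(det$regions), 3)
  expect_true(all(diff(det$regions$area_px) <= 0))
  # among the two 6 px ties the one starting at row 5 comes first
  expect_lt(det$regions$y_px[2], det$regions$y_px[3])
})

test_that("detections agree in micrometre space across calibrations", {
  base <- scene_config(n_pre = 4, n_new = 3, p_cluster = 0, multicore_p = 0,
                       seed = 31, amplitude = 200)
  areas <- lapply(c(0.43, 0.5), function(psz) {
    cfg <- base; cfg$pixel_size_um <- psz
    sc <- generate_scene(cfg)
    ren <- render_scene(sc, channels = "AB")
    img <- ren$img[, , "AB"]
    bg <- estimate_background(img)
    det <- detect_plaques(img, bg, psz)
    det$regions[order(det$regions$x_um), c("x_um", "area_um2")]
  })
  expect_equal(nrow(areas[[1]]), nrow(areas[[2]]))
  expect_lt(max(abs(areas[[1]]$x_um - areas[[2]]$x_um)), 0.5)
  # areas agree within one pixel-area's worth of boundary per region
  perim_allow <- 4 * sqrt(areas[[1]]$area_um2) * 0.5
  expect_true(all(abs(areas[[1]]$area_um2 - areas[[2]]$area_um2) <
                    perim_allow))
})

test_that("size-distribution detection recovers a planted lognormal", {
  cfg <- scene_config(n_pre = 0, n_new = 40, p_cluster = 0,
                      amplitude = 300, seed = 62)
  sc <- generate_scene(cfg)
  ren <- render_scene(sc, channels = "AB")
  img <- ren$img[, , "AB"]
  bg <- estimate_background(img)
  det <- detect_for_size_distribution(img, bg, cfg$pixel_size_um)
  expect_gt(nrow(det$regions), 30)
  # suprathreshold disc area from the Gaussian blob profile:
  # pi * (r/2)^2 * 2 * log(smoothed peak / (9 sd)); compare distributions
  got <- sort(det$regions$area_um2)
  r <- sort(sc$new$radius_um)[seq_along(got) + (length(sc$new$radius_um) -
                                                  length(got))]
  expect_gt(cor(got, pi * (r / 2)^2), 0.9)
})
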