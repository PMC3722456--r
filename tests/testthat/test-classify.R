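# Classification operates on detections; most cases here use constructed
# noise-free masks where the expected assignment is unambiguous.

make_det <- function(img, pixel_size_um = 1, min_area_px = 1L) {
  bg <- structure(list(mean = 0, sd = 1,
                       region = list(x = 0, y = 0, w = ncol(img),
                                     h = nrow(img))),
                  class = "background_model")
  detect_plaques(img, bg, pixel_size_um, min_area_px = min_area_px)
}

test_that("cores are assigned by centroid containment; outsiders are
           orphans", {
  ab <- matrix(0, 60, 60)
  ab[disc_mask(60, 60, 20, 20, 10)] <- 100  # plaque A
  ab[disc_mask(60, 60, 45, 45, 8)] <- 100   # plaque B (new: no core)
  mx <- matrix(0, 60, 60)
  mx[disc_mask(60, 60, 20, 20, 3)] <- 100   # core inside A
  mx[disc_mask(60, 60, 5, 55, 2)] <- 100    # orphan core
  ab_det <- make_det(ab); mx_det <- make_det(mx)
  expect_warning(rec <- pair_channels(ab_det, mx_det), "orphan")
  expect_equal(sort(rec$n_cores), c(0L, 1L))
  expect_length(attr(rec, "orphans"), 1)
  rec <- classify_new(rec)
  expect_equal(rec$is_new, rec$n_cores == 0L)
})

test_that("mixed pixel grids are rejected", {
  a <- make_det(matrix(0, 30, 30))
  b <- make_det(matrix(0, 40, 40))
  expect_error(pair_channels(a, b), "pixel grid")
  c2 <- make_det(matrix(0, 30, 30), pixel_size_um = 0.5)
  expect_error(pair_channels(a, c2), "pixel grid")
})

test_that("a planted multicore halo reports its core count", {
  ab <- matrix(0, 80, 80)
  ab[disc_mask(80, 80, 40, 40, 25)] <- 100
  mx <- matrix(0, 80, 80)
  for (ctr in list(c(34, 34), c(46, 46), c(34, 48)))
    mx[disc_mask(80, 80, ctr[1], ctr[2], 3)] <- 100
  rec <- pair_channels(make_det(ab), make_det(mx))
  expect_equal(rec$n_cores, 3L)
  rec <- classify_multicore(classify_new(rec))
  expect_true(rec$is_multicore)
  expect_false(rec$is_new)
})

test_that("vicinity uses Euclidean distance with a strict 40 um cutoff", {
  rec <- data.frame(plaque_id = 1:3,
                    x_um = c(0, 0, 100), y_um = c(0, 0, 100),
                    area_px = 10, area_um2 = 10,
                    n_cores = c(0L, 0L, 1L))
  rec <- classify_new(rec)
  # hand-computed: sqrt(30^2 + 10^2) = sqrt(1000) = 31.62 < 40
  out <- vicinity_classify(rec, data.frame(x_um = 30, y_um = 10),
                           radius_um = 40)
  expect_equal(out$nearest_pre_um[1], sqrt(1000))
  expect_true(out$in_vicinity[1])
  # boundary: distance exactly 40 is NOT in vicinity (strict <)
  out <- vicinity_classify(rec, data.frame(x_um = 40, y_um = 0),
                           radius_um = 40)
  expect_equal(out$nearest_pre_um[1], 40)
  expect_false(out$in_vicinity[1])
  # pre-existing plaques never get a vicinity flag
  expect_false(out$in_vicinity[3])
  expect_true(is.na(out$nearest_pre_um[3]))
})

test_that("nearest distances equal the O(n^2) oracle on random
           configurations", {
  set.seed(314)
  for (rep in 1:20) {
    n_new <- sample(5:100, 1); n_pre <- sample(1:100, 1)
    rec <- data.frame(plaque_id = seq_len(n_new),
                      x_um = runif(n_new, 0, 688),
                      y_um = runif(n_new, 0, 512),
                      area_px = 10, area_um2 = 10, n_cores = 0L)
    rec <- classify_new(rec)
    pre <- data.frame(x_um = runif(n_pre, 0, 688),
                      y_um = runif(n_pre, 0, 512))
    out <- vicinity_classify(rec, pre)
    expect_identical(out$nearest_pre_um,
                     brute_nearest(rec[, c("x_um", "y_um")], as.matrix(pre)))
  }
})

test_that("flower clusters need at least two petals around one parent", {
  rec <- data.frame(plaque_id = 1:4,
                    x_um = c(10, 30, 300, 500), y_um = c(10, 10, 300, 500),
                    area_px = 10, area_um2 = 10,
                    n_cores = c(0L, 0L, 0L, 1L))
  rec <- classify_new(rec)
  centers <- data.frame(plaque_id = 4L, x_um = 20, y_um = 20)
  rec <- vicinity_classify(rec, centers)
  # two new plaques each within 40 um of the same pre-existing centre
  fl <- find_flowers(rec, centers)
  expect_equal(nrow(fl$flowers), 2)
  expect_equal(sort(fl$flowers$petal_id), c(1L, 2L))
  expect_equal(unique(fl$flowers$parent_id), 4L)
  expect_equal(fl$records$flower_parent_id[1:2], c(4L, 4L))
  # a single nearby new plaque makes no flower
  rec1 <- rec[c(1, 3, 4), ]
  attr(rec1, "class") <- class(rec)
  fl1 <- find_flowers(rec1, centers)
  expect_equal(nrow(fl1$flowers), 0)
})

test_that("planted flowers and categories are recovered from a rendered
           scene", {
  cfg <- scene_config(n_pre = 4, n_new = 10, p_cluster = 0.8,
                      multicore_p = 0.5, min_separation_um = 35, seed = 17)
  sc <- generate_scene(cfg)
  ren <- render_scene(sc)
  dets <- lapply(c("MX", "AB", "TR"), function(ch) {
    img <- ren$img[, , ch]
    detect_plaques(img, estimate_background(img), cfg$pixel_size_um)
  })
  names(dets) <- c("MX", "AB", "TR")
  cls <- classify_image(dets$AB, dets$MX, dets$TR)
  rec <- cls$records
  expect_equal(sum(rec$is_new), nrow(sc$new))
  expect_equal(sum(!rec$is_new), nrow(sc$pre))
  expect_equal(sum(rec$is_multicore), sum(sc$pre$n_cores >= 2))
  # truth flowers: pre-existing plaques with >= 2 new centres within 40 um
  truth_petals <- sum(vapply(seq_len(nrow(sc$pre)), function(i) {
    d <- sqrt((sc$new$x_um - sc$pre$x_um[i])^2 +
                (sc$new$y_um - sc$pre$y_um[i])^2)
    n <- sum(d < 40); if (n >= 2) n else 0L
  }, numeric(1)))
  expect_equal(nrow(cls$flowers), truth_petals)
  # fates match the planted merged/separate flags
  truth_fate <- sort(sc$pre$fate[sc$pre$n_cores >= 2])
  expect_equal(sort(rec$core_fate[rec$is_multicore]), truth_fate)
})

test_that("core fate falls back to not_applicable without a counterstain", {
  ab <- matrix(0, 60, 60); ab[disc_mask(60, 60, 30, 30, 20)] <- 100
  mx <- matrix(0, 60, 60)
  mx[disc_mask(60, 60, 25, 25, 3)] <- 100
  mx[disc_mask(60, 60, 38, 38, 3)] <- 100
  rec <- classify_multicore(classify_new(pair_channels(make_det(ab),
                                                       make_det(mx))))
  expect_true(rec$is_multicore)
  rec_na <- classify_core_fate(rec, NULL)
  expect_equal(rec_na$core_fate, "not_applicable")
  # one covering TR region -> merged; two separate TR regions -> separate
  tr_merged <- matrix(0, 60, 60)
  tr_merged[disc_mask(60, 60, 31, 31, 15)] <- 100
  expect_equal(classify_core_fate(rec, make_det(tr_merged))$core_fate,
               "merged")
  tr_sep <- matrix(0, 60, 60)
  tr_sep[disc_mask(60, 60, 25, 25, 3)] <- 100
  tr_sep[disc_mask(60, 60, 38, 38, 3)] <- 100
  expect_equal(classify_core_fate(rec, make_det(tr_sep))$core_fate,
               "separate")
})

test_that("every plaque is exactly one of pre-existing or new", {
  sc <- generate_scene(small_scene_config())
  ren <- render_scene(sc, channels = c("MX", "AB"))
  ab <- ren$img[, , "AB"]; mx <- ren$img[, , "MX"]
  cls <- classify_image(
    detect_plaques(ab, estimate_background(ab), 0.43),
    detect_plaques(mx, estimate_background(mx), 0.43))
  rec <- cls$records
  expect_equal(sum(rec$is_new) + sum(!rec$is_new), nrow(rec))
  expect_true(all(rec$core_fate == "not_applicable"))
})

test_that("vicinity and flower labels are scale equivariant", {
  set.seed(9)
  rec <- data.frame(plaque_id = 1:30, x_um = runif(30, 0, 688),
                    y_um = runif(30, 0, 512), area_px = 10, area_um2 = 10,
                    n_cores = 0L)
  rec <- classify_new(rec)
  pre <- data.frame(plaque_id = 101:105, x_um = runif(5, 0, 688),
                    y_um = runif(5, 0, 512))
  a <- vicinity_classify(rec, pre, radius_um = 40)
  fa <- find_flowers(a, pre, radius_um = 40)
  s <- 2.7
  rec2 <- rec; rec2$x_um <- rec$x_um * s; rec2$y_um <- rec$y_um * s
  pre2 <- pre; pre2$x_um <- pre$x_um * s; pre2$y_um <- pre$y_um * s
  b <- vicinity_classify(rec2, pre2, radius_um = 40 * s)
  fb <- find_flowers(b, pre2, radius_um = 40 * s)
  expect_identical(a$in_vicinity, b$in_vicinity)
  expect_identical(fa$flowers$petal_id, fb$flowers$petal_id)
  expect_equal(a$nearest_pre_um * s, b$nearest_pre_um)
})
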