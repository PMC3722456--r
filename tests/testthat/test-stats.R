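test_that("the K2 omnibus statistic matches frozen reference values", {
  # reference values computed with an independent implementation of the
  # D'Agostino-Pearson omnibus test on these exact samples
  s1 <- c(2.3, 1.1, 4.5, 3.3, 2.2, 5.1, 0.7, 3.9, 2.8, 1.5, 4.2, 3.0)
  r1 <- dagostino_k2(s1)
  expect_equal(r1$statistic, 0.6786741201, tolerance = 1e-9)
  expect_equal(r1$p_value, 0.7122423402, tolerance = 1e-9)
  s2 <- (1:30)^2 / 10
  r2 <- dagostino_k2(s2)
  expect_equal(r2$statistic, 3.8582005416, tolerance = 1e-9)
  expect_equal(r2$p_value, 0.1452788513, tolerance = 1e-9)
  expect_error(dagostino_k2(1:7), "n >= 8")
  expect_error(dagostino_k2(rep(2, 20)), "constant")
})

test_that("the normality gate routes by sample size and distribution", {
  expect_warning(g <- normality_gate(list(rnorm(5))), "n < 8")
  expect_equal(g$route, "nonparametric")
  expect_warning(g2 <- normality_gate(list(rep(1, 20))), "constant")
  expect_equal(g2$route, "nonparametric")
  # clear calls on big samples
  set.seed(2)
  expect_equal(normality_gate(list(rnorm(500, 10, 2)))$route, "parametric")
  expect_equal(normality_gate(list(rexp(500)))$route, "nonparametric")
  # one bad sample forces the nonparametric route for all
  expect_equal(normality_gate(list(rnorm(500), rexp(500)))$route,
               "nonparametric")
})

test_that("Dunn z^2 equals the tie-corrected Kruskal-Wallis H for two
           groups", {
  set.seed(42)
  for (rep in 1:5) {
    x <- round(rnorm(16), 1)  # rounding induces ties
    g <- rep(c("a", "b"), each = 8)
    z <- dunn_test(x, g)$z
    expect_equal(z^2, unname(kruskal.test(x, factor(g))$statistic))
  }
})

test_that("Dunn multiplicity adjustment follows p.adjust", {
  set.seed(5)
  x <- rnorm(24); g <- rep(letters[1:4], each = 6)
  d <- dunn_test(x, g, method = "bonferroni")
  expect_equal(d$p_adjusted, pmin(1, p.adjust(d$p_value, "bonferroni")))
  expect_equal(nrow(d), choose(4, 2))
  dh <- dunn_test(x, g, method = "holm")
  expect_equal(dh$p_adjusted, pmin(1, p.adjust(dh$p_value, "holm")))
})

test_that("compare_groups routes, degenerates and validates", {
  # identical values in every group: H = 0, p = 1
  d0 <- data.frame(v = rep(3, 12), g = rep(c("a", "b", "c"), each = 4))
  r0 <- suppressWarnings(compare_groups(d0, "v", "g"))
  expect_equal(r0$omnibus$statistic, 0)
  expect_equal(r0$omnibus$p_value, 1)
  expect_null(r0$posthoc)
  # forced nonparametric route reproduces kruskal.test
  set.seed(8)
  d <- data.frame(v = c(rnorm(6), rnorm(6) + 3, rnorm(6)),
                  g = rep(c("a", "b", "c"), each = 6))
  r <- compare_groups(d, "v", "g", gate = "nonparametric")
  ref <- kruskal.test(d$v, factor(d$g))
  expect_equal(r$omnibus$statistic, unname(ref$statistic))
  expect_equal(r$omnibus$p_value, ref$p.value)
  if (r$omnibus$p_value < 0.05) expect_s3_class(r$posthoc, "data.frame")
  # parametric route reproduces one-way ANOVA
  rp <- compare_groups(d, "v", "g", gate = "parametric")
  ref_aov <- summary(aov(v ~ g, data = d))[[1]]
  expect_equal(rp$omnibus$statistic, ref_aov$`F value`[1])
  expect_error(compare_groups(d[d$g == "a", ], "v", "g"), "2 groups")
})

test_that("rank-based comparison is invariant under monotone transforms", {
  set.seed(31)
  d <- data.frame(v = rexp(18) + 0.1, g = rep(c("a", "b", "c"), each = 6))
  r1 <- compare_groups(d, "v", "g", gate = "nonparametric")
  d2 <- d; d2$v <- log(d$v)        # strictly monotone transform
  r2 <- compare_groups(d2, "v", "g", gate = "nonparametric")
  expect_equal(r1$omnibus$statistic, r2$omnibus$statistic)
  expect_equal(r1$omnibus$p_value, r2$omnibus$p_value)
})

test_that("core-size regression recovers a noiseless line exactly", {
  rec <- data.frame(n_cores = rep(1:4, each = 5))
  rec$area_um2 <- 100 + 50 * rec$n_cores
  fit <- suppressWarnings(core_size_regression(rec))
  expect_equal(fit$slope, 50)
  expect_equal(fit$intercept, 100)
  expect_equal(fit$r_squared, 1)
  # degenerate inputs
  expect_error(core_size_regression(data.frame(n_cores = 1:2,
                                               area_um2 = c(1, 2))),
               "3 plaques")
  expect_error(core_size_regression(data.frame(n_cores = rep(2, 10),
                                               area_um2 = rnorm(10, 100))),
               "constant")
})

test_that("proportion summaries do per-animal arithmetic and exclusions", {
  tab <- data.frame(
    animal_id = c("a1", "a2"), group_label = "g1",
    n_plaques = c(150, 80), n_new = c(100, 0),
    n_new_in_vicinity = c(22, 0), n_flower_petals = c(4, 0),
    n_multicore = c(6, 2), n_large = c(20, 10),
    n_large_multicore = c(3, 1))
  out <- summarize_proportions(tab)
  g <- out[out$group == "g1", ]
  # one animal: 100 new, 22 in vicinity -> 22 %
  vic <- g[g$quantity == "new_in_vicinity_of_new", ]
  expect_equal(vic$mean, 0.22)
  expect_equal(vic$n_animals, 1)       # a2 has zero new plaques
  expect_equal(vic$n_excluded, 1)
  # all-pre-existing animal: % new contributes 0, vicinity % is excluded
  newp <- g[g$quantity == "new_of_all", ]
  expect_equal(newp$mean, mean(c(100 / 150, 0)))
  expect_true(all(out$mean[!is.na(out$mean)] >= 0 &
                    out$mean[!is.na(out$mean)] <= 1))
  expect_equal(newp$sem, sd(c(100 / 150, 0)) / sqrt(2))
})
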