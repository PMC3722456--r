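## Group-level statistics: normality gate, cross-group comparisons,
## core-count-vs-size regression and summary proportions.

#' D'Agostino-Pearson omnibus K2 normality test
#'
#' Combines the transformed skewness and kurtosis statistics into the K2
#' omnibus statistic, chi-squared with 2 degrees of freedom under normality
#' (D'Agostino, Belanger & D'Agostino 1990). Requires n >= 8.
#'
#' @param x numeric vector.
#' @return list with `statistic` (K2), `p_value`, `z_skewness`,
#'   `z_kurtosis`, `n`.
#' @export
dagostino_k2 <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson K2 requires n >= 8")
  if (stats::sd(x) == 0) stop("sample is constant")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  ## skewness: D'Agostino's transformation to normality
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))

  ## kurtosis: Anscombe & Glynn transformation
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (b2 - Eb2) / sqrt(Vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  Z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xs * sqrt(2 / (A - 4))))^(1 / 3)) *
    sqrt(9 * A / 2)

  K2 <- Z1^2 + Z2^2
  list(statistic = K2, p_value = stats::pchisq(K2, 2, lower.tail = FALSE),
       z_skewness = Z1, z_kurtosis = Z2, n = n)
}

#' Normality gate for the choice of statistical test
#'
#' Tests every sample with the D'Agostino-Pearson omnibus K2 test at
#' `alpha = 0.05`; the parametric route is taken only when every sample
#' passes (p > alpha). Samples below the test's validity floor (n < 8) or
#' constant samples force the nonparametric route with a warning.
#'
#' @param samples a list of numeric vectors (or a single vector).
#' @param alpha significance level of the gate (default 0.05).
#' @return list with `route` (`"parametric"`/`"nonparametric"`), `tests`
#'   (data.frame `n`, `statistic`, `p_value` per sample; NA when not
#'   testable), `alpha`.
#' @export
normality_gate <- function(samples, alpha = 0.05) {
  if (is.numeric(samples)) samples <- list(samples)
  res <- data.frame(n = vapply(samples, function(s) sum(is.finite(s)),
                               integer(1)),
                    statistic = NA_real_, p_value = NA_real_)
  testable <- TRUE
  for (i in seq_along(samples)) {
    s <- samples[[i]][is.finite(samples[[i]])]
    if (length(s) < 8) {
      warning("sample ", i, " has n < 8: routing nonparametric")
      testable <- FALSE
    } else if (stats::sd(s) == 0) {
      warning("sample ", i, " is constant: routing nonparametric")
      testable <- FALSE
    } else {
      k2 <- dagostino_k2(s)
      res$statistic[i] <- k2$statistic
      res$p_value[i] <- k2$p_value
    }
  }
  route <- if (testable && all(res$p_value > alpha)) "parametric"
           else "nonparametric"
  list(route = route, tests = res, alpha = alpha)
}

#' Dunn's post hoc test
#'
#' Pairwise rank comparisons after a Kruskal-Wallis test: z-statistics on
#' mean-rank differences with the tie-corrected variance, adjusted for
#' multiplicity over all pairs (Bonferroni by default, Holm by config).
#'
#' @param x numeric response.
#' @param g group factor.
#' @param method multiplicity adjustment, `"bonferroni"` or `"holm"`.
#' @return data.frame `group1`, `group2`, `z`, `p_value`, `p_adjusted`.
#' @export
dunn_test <- function(x, g, method = c("bonferroni", "holm")) {
  method <- match.arg(method)
  g <- factor(g)
  ok <- is.finite(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(g[ok])
  N <- length(x)
  r <- rank(x)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mr <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[[i]] + 1 / ns[[j]]))
    z[k] <- (mr[[i]] - mr[[j]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p_value = p,
             p_adjusted = pmin(1, stats::p.adjust(p, method = method)))
}

#' Compare a response across groups
#'
#' Applies the [normality_gate()] to the per-group samples and routes to a
#' one-way ANOVA with Tukey's HSD (parametric) or a tie-corrected
#' Kruskal-Wallis test with Dunn's post hoc comparisons (nonparametric,
#' post hoc only when the omnibus p < 0.05).
#'
#' @param data data.frame with one row per statistical unit (animal).
#' @param response,group column names in `data`.
#' @param posthoc_method multiplicity adjustment for Dunn's test.
#' @param gate optional override of the routing (`"parametric"`/
#'   `"nonparametric"`); default applies the normality gate.
#' @return list with `route`, `gate`, `omnibus` (list `method`, `statistic`,
#'   `p_value`), `posthoc` (data.frame or NULL), `groups` summary.
#' @export
compare_groups <- function(data, response, group,
                           posthoc_method = "bonferroni", gate = NULL) {
  stopifnot(all(c(response, group) %in% names(data)))
  x <- data[[response]]; gg <- factor(data[[group]])
  ok <- is.finite(x) & !is.na(gg)
  x <- x[ok]; gg <- droplevels(gg[ok])
  if (nlevels(gg) < 2) stop("need at least 2 groups")
  if (any(tapply(x, gg, length) == 0)) stop("empty group")
  samples <- split(x, gg)
  gate_res <- NULL
  if (is.null(gate)) {
    gate_res <- suppressWarnings(normality_gate(samples))
    gate <- gate_res$route
  }
  groups <- data.frame(group = names(samples),
                       n = vapply(samples, length, integer(1)),
                       median = vapply(samples, stats::median, numeric(1)),
                       mean = vapply(samples, mean, numeric(1)))
  rownames(groups) <- NULL
  if (gate == "parametric") {
    fit <- stats::aov(x ~ gg)
    an <- summary(fit)[[1]]
    omnibus <- list(method = "one-way ANOVA", statistic = an$`F value`[1],
                    p_value = an$`Pr(>F)`[1])
    posthoc <- if (omnibus$p_value < 0.05) {
      tk <- stats::TukeyHSD(fit)$gg
      data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                 p_adjusted = tk[, "p adj"], row.names = NULL)
    } else NULL
  } else {
    if (stats::sd(x) == 0) {
      # all observations tied across every group: no evidence of any
      # difference; the tie-corrected statistic degenerates to 0
      omnibus <- list(method = "Kruskal-Wallis (tie-corrected)",
                      statistic = 0, p_value = 1)
    } else {
      kw <- stats::kruskal.test(x, gg)
      omnibus <- list(method = "Kruskal-Wallis (tie-corrected)",
                      statistic = unname(kw$statistic),
                      p_value = kw$p.value)
    }
    posthoc <- if (!is.nan(omnibus$p_value) && omnibus$p_value < 0.05)
      dunn_test(x, gg, posthoc_method) else NULL
    }
  list(route = gate, gate = gate_res, omnibus = omnibus, posthoc = posthoc,
       groups = groups)
}

#' Core-count versus plaque-size regression
#'
#' Ordinary least squares of antibody plaque area (um^2) on the number of
#' dense cores, the per-plaque association between precursor count and
#' final plaque size.
#'
#' @param records data.frame with `area_um2` and `n_cores` columns.
#' @return list with `slope`, `intercept`, `r_squared`, `p_value` (F test),
#'   `n`, `fit` (the `lm` object).
#' @export
core_size_regression <- function(records) {
  stopifnot(all(c("area_um2", "n_cores") %in% names(records)))
  d <- records[is.finite(records$area_um2) & is.finite(records$n_cores), ]
  if (nrow(d) < 3) stop("need at least 3 plaques")
  if (length(unique(d$n_cores)) < 2)
    stop("core count is constant: regression undefined")
  fit <- stats::lm(area_um2 ~ n_cores, data = d)
  sm <- summary(fit)
  p <- if (is.null(sm$fstatistic)) NA_real_ else
    unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared, p_value = p, n = nrow(d), fit = fit)
}

sem <- function(x) stats::sd(x) / sqrt(length(x))

prop_summary <- function(num, den) {
  # per-animal proportions with zero denominators excluded and counted
  ok <- den > 0
  vals <- num[ok] / den[ok]
  list(per_animal = ifelse(den > 0, num / den, NA_real_),
       mean = if (any(ok)) mean(vals) else NA_real_,
       sem = if (sum(ok) > 1) sem(vals) else NA_real_,
       n = sum(ok), n_excluded = sum(!ok),
       pooled = if (sum(den) > 0) sum(num) / sum(den) else NA_real_)
}

#' Summarise study-level plaque proportions
#'
#' Per group and overall: % new of all plaques, % new-in-vicinity of new,
#' % flower-petal of new-in-vicinity, % multicore of large plaques and
#' % merged of multicore (when core fate is available), each as a
#' per-animal mean +/- SEM with zero-denominator animals excluded and
#' counted.
#'
#' @param table a study table: one row per animal with columns `animal_id`,
#'   `group_label`, `n_plaques`, `n_new`, `n_new_in_vicinity`,
#'   `n_flower_petals`, `n_multicore`, `n_large`, `n_large_multicore` and
#'   optionally `n_merged`.
#' @return data.frame: one row per `(group, quantity)` (plus an `"overall"`
#'   group) with `mean`, `sem`, `n_animals`, `n_excluded`, `pooled`
#'   (plaque-pooled proportion). Values are fractions in `[0, 1]`.
#' @export
summarize_proportions <- function(table) {
  stopifnot(nrow(table) > 0)
  need <- c("animal_id", "group_label", "n_plaques", "n_new",
            "n_new_in_vicinity", "n_flower_petals", "n_multicore",
            "n_large", "n_large_multicore")
  stopifnot(all(need %in% names(table)))
  quantities <- list(
    new_of_all = c("n_new", "n_plaques"),
    new_in_vicinity_of_new = c("n_new_in_vicinity", "n_new"),
    flower_petal_of_vicinity = c("n_flower_petals", "n_new_in_vicinity"),
    multicore_of_large = c("n_large_multicore", "n_large")
  )
  if ("n_merged" %in% names(table))
    quantities$merged_of_multicore <- c("n_merged", "n_multicore")
  groups <- c(split(seq_len(nrow(table)), table$group_label),
              list(overall = seq_len(nrow(table))))
  out <- do.call(rbind, lapply(names(groups), function(gname) {
    ix <- groups[[gname]]
    do.call(rbind, lapply(names(quantities), function(q) {
      nm <- quantities[[q]]
      s <- prop_summary(table[[nm[1]]][ix], table[[nm[2]]][ix])
      data.frame(group = gname, quantity = q, mean = s$mean, sem = s$sem,
                 n_animals = s$n, n_excluded = s$n_excluded,
                 pooled = s$pooled)
    }))
  }))
  rownames(out) <- NULL
  out
}
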