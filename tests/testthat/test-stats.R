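test_that("group summaries use the n-1 standard deviation", {
  cohort <- example_cohort()
  gs <- group_summary(cohort)
  r1 <- gs |> dplyr::filter(region == "R1", measure == "mfPhNR_RAD")
  raw <- cohort |>
    dplyr::filter(region == "R1", measure == "mfPhNR_RAD") |>
    dplyr::pull(value)
  expect_equal(r1$mean, mean(raw))
  expect_equal(r1$sd, sd(raw))
  expect_equal(r1$n, 21L)

  const <- tibble::tibble(
    eye_id = c("a", "b", "c"), group = "patient", region_type = "ring",
    region = "R1", measure = "mfPhNR_RAD", value = 4, units = "nV_per_deg2"
  )
  expect_equal(group_summary(const)$sd, 0)
  expect_error(group_summary(cohort[0, ]), class = "mfphnr_domain_error")
})

test_that("summary-statistics ANOVA is identical to the raw-data F test", {
  set.seed(14)
  for (i in 1:10) {
    n1 <- sample(5:30, 1)
    n2 <- sample(5:30, 1)
    x <- rnorm(n1, 10, 2)
    y <- rnorm(n2, 12, 3)
    raw <- anova_oneway(c(x, y), rep(c("a", "b"), c(n1, n2)))
    summ <- anova_from_summary(mean(x), sd(x), n1, mean(y), sd(y), n2)
    expect_equal(summ$f, raw$f, tolerance = 1e-9)
    expect_equal(summ$p, raw$p, tolerance = 1e-9)
    expect_equal(summ$df2, raw$df2)
  }
  # identical groups give F = 0
  expect_equal(anova_from_summary(5, 1, 10, 5, 1, 10)$f, 0)
  expect_equal(anova_oneway(rep(c(3, 3), 5), rep(c("a", "b"), 5))$f, 0)
  # degenerate: zero pooled variance with unequal means
  expect_warning(out <- anova_from_summary(1, 0, 5, 2, 0, 5), "infinite")
  expect_equal(out$f, Inf)
  expect_error(anova_oneway(1:6, rep("a", 6)), class = "mfphnr_domain_error")
})

test_that("computed normative limits follow the one-sided lower bound formula", {
  lim <- normative_limits(tibble::tibble(
    region_type = "sector", region = "ST", measure = "mfPhNR_RAD",
    mean = 5.041, sd = 1.431, n = 20
  ))
  expect_equal(lim$limit, 5.041 - qt(0.975, 19) * 1.431 / sqrt(20), tolerance = 1e-12)
  expect_equal(round(lim$limit, 3), 4.371)

  # SD 0 collapses the limit onto the mean
  lim0 <- normative_limits(tibble::tibble(
    region_type = "ring", region = "R1", measure = "GCL_T",
    mean = 30, sd = 0, n = 15
  ))
  expect_equal(lim0$limit, 30)

  # supplied limits pass through unchanged
  supplied <- tibble::tibble(
    region_type = "ring", region = "R1", measure = "mfPhNR_RAD", limit = 26.92
  )
  out <- normative_limits(method = "supplied", limits = supplied)
  expect_equal(out$limit, 26.92)
  expect_equal(out$method, "supplied")

  expect_error(
    normative_limits(tibble::tibble(
      region_type = "ring", region = "R1", measure = "GCL_T",
      mean = 30, sd = 1, n = 1
    )),
    class = "mfphnr_domain_error"
  )
})

test_that("abnormality classification is strict and monotone in the limit", {
  cohort <- tibble::tibble(
    eye_id = sprintf("P%02d", 1:5), group = "patient", region_type = "ring",
    region = "R1", measure = "mfPhNR_RAD",
    value = c(1, 2, 3, 4, 5), units = "nV_per_deg2"
  )
  lim <- function(l) {
    tibble::tibble(
      region_type = "ring", region = "R1",
      measure = "mfPhNR_RAD", limit = l
    )
  }
  # value exactly at the limit counts as normal
  out <- classify_abnormal(cohort, lim(3))
  expect_equal(out$n_abnormal, 2L)
  expect_equal(out$pct_abnormal, 40)
  # raising the limit never decreases the abnormal count
  counts <- vapply(
    seq(0, 6, by = 0.5),
    function(l) classify_abnormal(cohort, lim(l))$n_abnormal,
    integer(1)
  )
  expect_true(all(diff(counts) >= 0))
  # missing limit for a region errors
  expect_error(
    classify_abnormal(
      cohort |> dplyr::mutate(region = "R2"),
      lim(3)
    ),
    class = "mfphnr_domain_error"
  )
})

test_that("structure-function regression matches its algebraic identities", {
  # exact line: R^2 = 1 and a zero-width confidence interval
  x <- c(1, 2, 3, 4, 5)
  fit <- morphofunctional_regression(2 * x, x)
  expect_equal(fit$estimate, 2)
  expect_equal(fit$r2, 1)
  expect_equal(fit$ci_high - fit$ci_low, 0, tolerance = 1e-9)

  # slope = r * sd(dependent) / sd(independent)
  set.seed(2)
  rad <- rnorm(25, 10, 3)
  gcl <- 0.6 * rad + rnorm(25, 0, 2)
  fit2 <- morphofunctional_regression(rad, gcl)
  expect_equal(
    fit2$estimate,
    cor(rad, gcl) * sd(rad) / sd(gcl),
    tolerance = 1e-9
  )
  expect_equal(fit2$r2, cor(rad, gcl)^2, tolerance = 1e-12)

  expect_error(morphofunctional_regression(1:5, rep(3, 5)), class = "mfphnr_domain_error")
  expect_error(morphofunctional_regression(1:2, 1:2), class = "mfphnr_domain_error")
})

test_that("pearson correlation agrees with the direct-sum formula", {
  set.seed(3)
  x <- rnorm(15)
  y <- rnorm(15)
  out <- pearson_cor(x, y)
  expect_equal(out$r, brute_force_pearson(x, y), tolerance = 1e-12)
  expect_equal(out$r_squared, out$r^2)
  # p from the t transform with n-2 df
  tval <- out$r * sqrt(13 / (1 - out$r^2))
  expect_equal(out$p, 2 * pt(abs(tval), 13, lower.tail = FALSE), tolerance = 1e-12)
  # perfectly anti-correlated pair
  expect_equal(pearson_cor(x, -x)$r, -1)
})

test_that("trend fits on individuals equal trend fits on group means for balanced data", {
  set.seed(4)
  levels <- c("Area1", "Area2", "Area3")
  indiv <- tidyr::expand_grid(
    eye = 1:12, region = levels,
    group = c("control", "patient")
  ) |>
    dplyr::mutate(value = rnorm(dplyr::n(), 30 - 5 * (match(region, levels) - 1), 2))
  means <- indiv |>
    dplyr::group_by(group, region) |>
    dplyr::summarise(value = mean(value), .groups = "drop")
  fi <- trend_fit(indiv, levels)
  fm <- trend_fit(means, levels)
  expect_equal(
    fi$per_group[c("group", "slope", "intercept")],
    fm$per_group[c("group", "slope", "intercept")],
    tolerance = 1e-9
  )
  # identical group means across levels give slope 0
  flat <- means |> dplyr::mutate(value = 7)
  expect_equal(trend_fit(flat, levels)$per_group$slope, c(0, 0))
  expect_error(trend_fit(means, "Area1"), class = "mfphnr_domain_error")
  # tidiers
  expect_named(tidy(fi), c("group", "slope", "intercept", "n"))
  expect_true(is.numeric(glance(fi)$interaction_p))
})
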