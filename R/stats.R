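#' Group summaries of a cohort table
#'
#' Mean and standard deviation (n-1 denominator) of each regional measure
#' by group.
#'
#' @param cohort A tidy cohort table (see [load_cohort()]).
#' @return A tibble: `group`, `region_type`, `region`, `measure`, `units`,
#'   `mean`, `sd`, `n`.
#' @export
#' @examples
#' cohort <- load_cohort(mfphnr_example("oag_cohort.csv"))
#' group_summary(cohort)
group_summary <- function(cohort) {
  if (nrow(cohort) == 0) abort("empty cohort", class = "mfphnr_domain_error")
  cohort |>
    group_by(.data$group, .data$region_type, .data$region, .data$measure, .data$units) |>
    summarise(
      mean = mean(.data$value),
      sd = sd(.data$value),
      n = n(),
      .groups = "drop"
    )
}

#' One-way ANOVA for a two-group comparison
#'
#' `anova_oneway()` computes the classical one-way F test for a group
#' factor from raw values; `anova_from_summary()` computes the identical
#' statistic from the two groups' summary statistics,
#' \deqn{F = \frac{n_1 n_2}{n_1+n_2}\,\frac{(\bar x_1-\bar x_2)^2}{s_p^2},
#' \quad s_p^2 = \frac{(n_1-1)s_1^2+(n_2-1)s_2^2}{n_1+n_2-2},}
#' with degrees of freedom (1, n1+n2-2). The two forms agree exactly when
#' the summaries are computed from the raw data; the summary form is what
#' allows a published control group to be compared against individual
#' patient values.
#'
#' @param values Numeric vector of raw values.
#' @param groups Factor-like vector with exactly two levels.
#' @return A one-row tibble: `f`, `df1`, `df2`, `p`.
#' @export
#' @examples
#' anova_oneway(c(1, 2, 3, 5, 6, 7), rep(c("a", "b"), each = 3))
anova_oneway <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) {
    abort("exactly two groups are required", class = "mfphnr_domain_error")
  }
  if (length(values) < 3) {
    abort("need at least three observations", class = "mfphnr_domain_error")
  }
  split_vals <- split(values, groups)
  if (all(vapply(split_vals, function(v) sd(v) == 0, logical(1)))) {
    # degenerate: no within-group variance; fall back on the summary form
    return(anova_from_summary(
      mean(split_vals[[1]]), 0, length(split_vals[[1]]),
      mean(split_vals[[2]]), 0, length(split_vals[[2]])
    ))
  }
  fit <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  tibble(
    f = unname(fit$statistic),
    df1 = unname(fit$parameter[1]),
    df2 = unname(fit$parameter[2]),
    p = unname(fit$p.value)
  )
}

#' @rdname anova_oneway
#' @param m1,s1,n1 Mean, SD and size of the first group.
#' @param m2,s2,n2 Mean, SD and size of the second group.
#' @export
anova_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 + n2 < 3) abort("need at least three observations", class = "mfphnr_domain_error")
  if (s1 < 0 || s2 < 0) abort("SDs must be non-negative", class = "mfphnr_domain_error")
  df2 <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df2
  if (sp2 == 0) {
    if (m1 == m2) {
      f <- 0
    } else {
      warn("zero pooled variance with unequal means: F is infinite")
      f <- Inf
    }
  } else {
    f <- (n1 * n2 / (n1 + n2)) * (m1 - m2)^2 / sp2
  }
  tibble(f = f, df1 = 1, df2 = df2, p = pf(f, 1, df2, lower.tail = FALSE))
}

#' Normative lower limits from control data
#'
#' One-sided lower 95% limits below which a patient value is classified as
#' abnormal. In `"computed"` mode the limit is the lower bound of the
#' control mean, `mean - t(0.975, n-1) * sd / sqrt(n)`. In `"supplied"`
#' mode a table of published limits is passed through unchanged (the mode
#' used to reproduce the bundled cohort's abnormality counts, since the
#' exact rule behind the published limits is not recoverable for every
#' region).
#'
#' @param control_summary Tibble with `region_type`, `region`, `measure`,
#'   `mean`, `sd`, `n` (as from [group_summary()] or the bundled control
#'   summary). Ignored when `method = "supplied"`.
#' @param method `"computed"` or `"supplied"`.
#' @param limits For `method = "supplied"`: tibble with `region_type`,
#'   `region`, `measure`, `limit`.
#' @param conf Confidence level of the two-sided interval whose lower
#'   bound is used (default 0.95, i.e. `t(0.975, n-1)`).
#' @return A tibble: `region_type`, `region`, `measure`, `limit`, `method`.
#' @export
#' @examples
#' normative_limits(tibble::tibble(
#'   region_type = "sector", region = "ST", measure = "mfPhNR_RAD",
#'   mean = 5.041, sd = 1.431, n = 20
#' ))
normative_limits <- function(control_summary = NULL,
                             method = c("computed", "supplied"),
                             limits = NULL, conf = 0.95) {
  method <- match.arg(method)
  if (method == "supplied") {
    if (is.null(limits)) abort("supplied mode needs `limits`", class = "mfphnr_domain_error")
    return(limits |>
      select("region_type", "region", "measure", "limit") |>
      mutate(method = "supplied"))
  }
  if (is.null(control_summary)) {
    abort("computed mode needs `control_summary`", class = "mfphnr_domain_error")
  }
  if (any(control_summary$n < 2)) {
    abort("need at least two control eyes per region", class = "mfphnr_domain_error")
  }
  control_summary |>
    mutate(
      limit = .data$mean - qt(1 - (1 - conf) / 2, .data$n - 1) * .data$sd / sqrt(.data$n),
      method = "computed"
    ) |>
    select("region_type", "region", "measure", "limit", "method")
}

#' Classify patient values against normative limits
#'
#' A value is abnormal when it is strictly below the regional limit; a
#' value exactly at the limit counts as normal.
#'
#' @param cohort A tidy cohort table (patient rows are classified; other
#'   groups are ignored).
#' @param limits A limits table from [normative_limits()].
#' @return A tibble per region and measure: `n`, `n_normal`, `n_abnormal`,
#'   `pct_abnormal` (percent, full precision).
#' @export
classify_abnormal <- function(cohort, limits) {
  d <- cohort |>
    filter(.data$group == "patient") |>
    dplyr::inner_join(limits, by = c("region_type", "region", "measure"))
  missing <- cohort |>
    filter(.data$group == "patient") |>
    dplyr::anti_join(limits, by = c("region_type", "region", "measure"))
  if (nrow(missing)) {
    abort(
      paste(
        "no normative limit for:",
        paste(unique(paste(missing$region, missing$measure)), collapse = ", ")
      ),
      class = "mfphnr_domain_error"
    )
  }
  d |>
    group_by(.data$region_type, .data$region, .data$measure) |>
    summarise(
      n = n(),
      n_abnormal = sum(.data$value < .data$limit),
      n_normal = .data$n - .data$n_abnormal,
      pct_abnormal = 100 * .data$n_abnormal / .data$n,
      .groups = "drop"
    )
}

#' Structure-function regression
#'
#' Ordinary least-squares regression of a functional measure (mfPhNR RAD,
#' dependent) on the matched morphological measure (GCL thickness,
#' independent), with the t-based 95% confidence interval of the slope and
#' the squared Pearson correlation.
#'
#' @param rad,gcl Paired numeric vectors (one value per eye).
#' @param conf Confidence level for the slope interval.
#' @return A one-row tibble: `estimate` (slope), `ci_low`, `ci_high`,
#'   `r2`, `p`, `intercept`, `n`.
#' @export
#' @examples
#' morphofunctional_regression(c(1, 2, 3, 5), c(2, 4, 5, 9))
morphofunctional_regression <- function(rad, gcl, conf = 0.95) {
  keep <- complete.cases(rad, gcl)
  rad <- rad[keep]
  gcl <- gcl[keep]
  if (length(rad) < 3) abort("need at least three pairs", class = "mfphnr_domain_error")
  if (sd(gcl) == 0) {
    abort("independent variable has zero variance", class = "mfphnr_domain_error")
  }
  fit <- lm(rad ~ gcl)
  # a perfect fit triggers a precision warning from summary.lm; the
  # degenerate case (zero-width CI, R^2 = 1) is well defined here
  ci <- suppressWarnings(confint(fit, "gcl", level = conf))
  s <- suppressWarnings(summary(fit))
  tibble(
    estimate = unname(coef(fit)["gcl"]),
    ci_low = ci[1],
    ci_high = ci[2],
    r2 = s$r.squared,
    p = unname(s$coefficients["gcl", "Pr(>|t|)"]),
    intercept = unname(coef(fit)["(Intercept)"]),
    n = length(rad)
  )
}

#' Pearson correlation with significance test
#'
#' Product-moment correlation of paired values, its square, and the
#' p value from the t transform with n-2 degrees of freedom.
#'
#' @param x,y Paired numeric vectors.
#' @return A one-row tibble: `r`, `r_squared`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) abort("need at least three pairs", class = "mfphnr_domain_error")
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble(
    r = unname(ct$estimate),
    r_squared = unname(ct$estimate)^2,
    p = ct$p.value,
    n = length(x)
  )
}

#' Eccentricity / sector trend fit with a group interaction
#'
#' Fits the change of a measure across ordered region levels (coded 0, 1,
#' 2, ... in the given order) separately per group, and tests whether the
#' slopes differ between groups via the group-by-index interaction term of
#' a pooled linear model. Individual values and group means give the same
#' slopes for balanced complete data; either can be supplied.
#'
#' @param data A tibble with columns `value`, `group`, and the region
#'   column named by `region_col`.
#' @param region_levels Character vector giving the region order; the
#'   first level is coded 0.
#' @param region_col Name of the region column (default `"region"`).
#' @return An object of class `mfphnr_trend`: a list with `per_group`
#'   (tibble of `group`, `slope`, `intercept`, `n`) and `interaction_p`
#'   (NA when a group has a single observation per level pattern too
#'   degenerate to test).
#' @export
#' @examples
#' d <- tibble::tibble(
#'   region = rep(c("Area1", "Area2", "Area3"), 2),
#'   value = c(45.2, 33.2, 24.0, 26.8, 23.9, 20.2),
#'   group = rep(c("control", "patient"), each = 3)
#' )
#' trend_fit(d, c("Area1", "Area2", "Area3"))
trend_fit <- function(data, region_levels, region_col = "region") {
  if (length(region_levels) < 2) {
    abort("need at least two region levels", class = "mfphnr_domain_error")
  }
  d <- data |>
    filter(.data[[region_col]] %in% region_levels) |>
    mutate(index = match(.data[[region_col]], region_levels) - 1)
  if (nrow(d) == 0) abort("no data at the requested levels", class = "mfphnr_domain_error")
  per_group <- d |>
    group_by(.data$group) |>
    summarise(
      slope = unname(coef(lm(.data$value ~ .data$index))[2]),
      intercept = unname(coef(lm(.data$value ~ .data$index))[1]),
      n = n(),
      .groups = "drop"
    )
  interaction_p <- NA_real_
  if (dplyr::n_distinct(d$group) == 2 && nrow(d) >= 5) {
    pooled <- lm(value ~ index * group, data = d)
    ct <- suppressWarnings(summary(pooled))$coefficients
    term <- grep(":", rownames(ct), value = TRUE)
    if (length(term) == 1 && !is.na(ct[term, "Pr(>|t|)"])) {
      interaction_p <- ct[term, "Pr(>|t|)"]
    }
  }
  structure(
    list(per_group = per_group, interaction_p = interaction_p, levels = region_levels),
    class = "mfphnr_trend"
  )
}

#' @export
print.mfphnr_trend <- function(x, ...) {
  cat("<trend fit> levels:", paste(x$levels, collapse = " -> "), "\n")
  print(x$per_group)
  cat("group x index interaction p =", format(x$interaction_p, digits = 3), "\n")
  invisible(x)
}

#' @describeIn trend_fit Per-group slopes and intercepts as a tibble.
#' @param x An `mfphnr_trend`.
#' @param ... Unused.
#' @export
tidy.mfphnr_trend <- function(x, ...) x$per_group

#' @describeIn trend_fit One-row tibble with the interaction p value.
#' @export
glance.mfphnr_trend <- function(x, ...) {
  tibble(interaction_p = x$interaction_p, n_levels = length(x$levels))
}
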