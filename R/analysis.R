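#' Run the full cohort analysis
#'
#' Orchestrates the statistical pipeline on a tidy cohort table: group
#' summaries, one-way ANOVA per region (from raw data when both groups
#' carry individual values, otherwise from the control summary statistics
#' against the patient individuals), normative-limit classification,
#' structure-function regressions with Pearson correlations for every
#' paired region, and the eccentricity trend fits (RAD across rings, GCL
#' thickness across areas) with a group interaction. When published
#' reference values are available (they are bundled for the example
#' cohort) a reconciliation table compares every recomputed quantity to
#' its printed counterpart at the printed precision.
#'
#' @param cohort A tidy cohort table; defaults to the bundled 21-eye OAG
#'   cohort.
#' @param control_summary Control regional summary (`region_type`,
#'   `region`, `measure`, `mean`, `sd`, `n`); defaults to the bundled
#'   20-eye control summary. Ignored for regions where the cohort itself
#'   contains control individuals.
#' @param cl_mode `"supplied"` (default: use `limits`) or `"computed"`
#'   (derive limits from the control summary as in [normative_limits()]).
#' @param limits Normative limits table for `cl_mode = "supplied"`;
#'   defaults to the bundled published limits.
#' @param published Optional list with elements `anova` and `regressions`
#'   holding printed reference tables for reconciliation; defaults to the
#'   bundled ones. Set to `NULL` to skip reconciliation.
#' @param sig_level Significance threshold reported alongside p values.
#' @return An object of class `mfphnr_report`: a list of tibbles
#'   `group_table`, `regression_table`, `classification`, `limits`,
#'   `trends` (list of `mfphnr_trend`), `reconciliation`, plus the inputs.
#' @export
#' @examples
#' rep <- run_full_analysis()
#' rep$group_table
run_full_analysis <- function(cohort = load_cohort(mfphnr_example("oag_cohort.csv")),
                              control_summary = read_fixture("control_summary.csv"),
                              cl_mode = c("supplied", "computed"),
                              limits = read_fixture("control_limits.csv"),
                              published = list(
                                anova = read_fixture("published_anova.csv"),
                                regressions = read_fixture("published_regressions.csv")
                              ),
                              sig_level = 0.01) {
  cl_mode <- match.arg(cl_mode)
  cohort <- validate_cohort(cohort)
  if (sig_level <= 0 || sig_level >= 1) {
    abort("sig_level must be in (0, 1)", class = "mfphnr_config_error")
  }
  patients <- cohort |> filter(.data$group == "patient")
  if (nrow(patients) == 0) abort("no patient eyes in cohort", class = "mfphnr_domain_error")
  pat_summary <- group_summary(patients) |> select(-"group")

  has_controls <- any(cohort$group == "control")
  ctrl_summary <- if (has_controls) {
    group_summary(cohort |> filter(.data$group == "control")) |> select(-"group")
  } else {
    control_summary
  }

  # group comparison: raw ANOVA when control individuals exist, otherwise
  # the summary-statistics form against the published control moments
  anova_tbl <- pat_summary |>
    left_join(
      ctrl_summary |>
        select("region_type", "region", "measure",
          control_mean = "mean", control_sd = "sd", control_n = "n"
        ),
      by = c("region_type", "region", "measure")
    )
  anova_tbl <- anova_tbl |>
    bind_cols(purrr::pmap_dfr(
      anova_tbl[c("control_mean", "control_sd", "control_n", "mean", "sd", "n")],
      function(control_mean, control_sd, control_n, mean, sd, n) {
        anova_from_summary(control_mean, control_sd, control_n, mean, sd, n)
      }
    ))

  lim <- if (cl_mode == "supplied") {
    normative_limits(method = "supplied", limits = limits)
  } else {
    normative_limits(ctrl_summary, method = "computed")
  }
  classification <- classify_abnormal(cohort, lim)

  group_table <- anova_tbl |>
    rename(patient_mean = "mean", patient_sd = "sd", patient_n = "n") |>
    left_join(classification, by = c("region_type", "region", "measure")) |>
    mutate(significant = .data$p < sig_level) |>
    select(
      "region_type", "region", "measure", "units",
      "control_mean", "control_sd", "control_n",
      "patient_mean", "patient_sd", "patient_n",
      "f", "df1", "df2", "p", "significant",
      "n_normal", "n_abnormal", "pct_abnormal"
    )

  # structure-function regressions on the patient individuals
  wide <- patients |>
    select("eye_id", "region_type", "region", "measure", "value")
  regression_table <- region_pairs() |>
    bind_cols(purrr::pmap_dfr(
      region_pairs(),
      function(rad_region_type, rad_region, gcl_region_type, gcl_region) {
        rad <- wide |>
          filter(
            .data$region_type == rad_region_type, .data$region == rad_region,
            .data$measure == "mfPhNR_RAD"
          ) |>
          arrange(.data$eye_id)
        gcl <- wide |>
          filter(
            .data$region_type == gcl_region_type, .data$region == gcl_region,
            .data$measure == "GCL_T"
          ) |>
          arrange(.data$eye_id)
        paired <- dplyr::inner_join(rad, gcl, by = "eye_id", suffix = c("_rad", "_gcl"))
        fit <- morphofunctional_regression(paired$value_rad, paired$value_gcl)
        cor <- pearson_cor(paired$value_rad, paired$value_gcl)
        bind_cols(fit, cor |> select("r"))
      }
    )) |>
    mutate(significant = .data$p < sig_level)

  # eccentricity trends: patient individuals; control individuals when
  # present, otherwise the control regional means
  trend_input <- function(measure_name, type, levels) {
    pat <- patients |>
      filter(.data$measure == measure_name, .data$region_type == type) |>
      select("region", "value", "group")
    ctl <- if (has_controls) {
      cohort |>
        filter(
          .data$group == "control", .data$measure == measure_name,
          .data$region_type == type
        ) |>
        select("region", "value", "group")
    } else {
      ctrl_summary |>
        filter(.data$measure == measure_name, .data$region_type == type) |>
        mutate(group = "control") |>
        select("region", value = "mean", "group")
    }
    bind_rows(pat, ctl)
  }
  trends <- list(
    mfPhNR_RAD = trend_fit(
      trend_input("mfPhNR_RAD", "ring", c("R1", "R2", "R3+R4")),
      c("R1", "R2", "R3+R4")
    ),
    GCL_T = trend_fit(
      trend_input("GCL_T", "area", c("Area1", "Area2", "Area3")),
      c("Area1", "Area2", "Area3")
    )
  )

  reconciliation <- NULL
  if (!is.null(published)) {
    reconciliation <- reconcile_report(group_table, regression_table, published)
  }

  structure(
    list(
      group_table = group_table,
      regression_table = regression_table,
      classification = classification,
      limits = lim,
      trends = trends,
      reconciliation = reconciliation,
      sig_level = sig_level,
      cl_mode = cl_mode,
      cohort = cohort
    ),
    class = "mfphnr_report"
  )
}

# Compare recomputed quantities to published ones at the published
# precision (2 dp for F, slopes and R2; 1 dp for percentages).
reconcile_report <- function(group_table, regression_table, published) {
  out <- list()
  if (!is.null(published$anova)) {
    g <- group_table |>
      dplyr::inner_join(published$anova,
        by = c("region_type", "region", "measure"),
        suffix = c("", "_pub")
      )
    out$anova <- bind_rows(
      tibble(
        quantity = paste("F", g$region, g$measure),
        computed = round(g$f, 2), published = g$f_pub
      ),
      tibble(
        quantity = paste("n_abnormal", g$region, g$measure),
        computed = g$n_abnormal, published = g$n_abnormal_pub
      ),
      tibble(
        quantity = paste("pct_abnormal", g$region, g$measure),
        computed = round(g$pct_abnormal, 1), published = g$pct_abnormal_pub
      )
    )
  }
  if (!is.null(published$regressions)) {
    r <- regression_table |>
      dplyr::inner_join(published$regressions,
        by = c("rad_region_type", "rad_region", "gcl_region_type", "gcl_region"),
        suffix = c("", "_pub")
      )
    out$regressions <- bind_rows(
      tibble(
        quantity = paste("slope", r$rad_region),
        computed = round(r$estimate, 2), published = r$estimate_pub
      ),
      tibble(
        quantity = paste("R2", r$rad_region),
        computed = round(r$r2, 2), published = r$r2_pub
      )
    )
  }
  bind_rows(out) |>
    mutate(
      difference = .data$computed - .data$published,
      match = abs(.data$difference) < 0.05 + 1e-9
    )
}

#' @export
print.mfphnr_report <- function(x, ...) {
  cat("Macular structure-function analysis report\n")
  cat(
    "  cohort:", dplyr::n_distinct(x$cohort$eye_id[x$cohort$group == "patient"]),
    "patient eyes;", dplyr::n_distinct(x$cohort$eye_id[x$cohort$group == "control"]),
    "control eyes in table\n"
  )
  cat("  normative limits:", x$cl_mode, "\n")
  cat("\nGroup comparison (per region):\n")
  print(x$group_table |>
    mutate(across(c("patient_mean", "patient_sd"), ~ round(.x, 3)),
      f = round(.data$f, 2), pct_abnormal = round(.data$pct_abnormal, 1)
    ) |>
    select(
      "region", "measure", "control_mean", "patient_mean", "f", "p",
      "n_abnormal", "pct_abnormal"
    ), n = Inf)
  cat("\nStructure-function regressions (patients):\n")
  print(x$regression_table |>
    mutate(across(c("estimate", "ci_low", "ci_high", "r2"), ~ round(.x, 2))) |>
    select("rad_region", "gcl_region", "estimate", "ci_low", "ci_high", "r2", "p"), n = Inf)
  cat("\nEccentricity trends:\n")
  for (nm in names(x$trends)) {
    cat(" ", nm, "\n")
    print(x$trends[[nm]]$per_group |> mutate(across(c("slope", "intercept"), ~ round(.x, 2))))
  }
  if (!is.null(x$reconciliation)) {
    n_bad <- sum(!x$reconciliation$match)
    cat(
      "\nReconciliation vs published values:",
      sum(x$reconciliation$match), "of", nrow(x$reconciliation),
      "quantities match at printed precision\n"
    )
    if (n_bad > 0) print(x$reconciliation |> filter(!.data$match), n = Inf)
  }
  invisible(x)
}

#' @describeIn run_full_analysis Long tibble of every quantity in the
#'   report (group comparisons and regressions).
#' @param x An `mfphnr_report`.
#' @param ... Unused.
#' @export
tidy.mfphnr_report <- function(x, ...) {
  bind_rows(
    x$group_table |>
      tidyr::pivot_longer(
        c(
          "control_mean", "control_sd", "patient_mean", "patient_sd",
          "f", "p", "n_abnormal", "pct_abnormal"
        ),
        names_to = "statistic", values_to = "value"
      ) |>
      mutate(table = "group_comparison") |>
      select("table", "region_type", "region", "measure", "statistic", "value"),
    x$regression_table |>
      tidyr::pivot_longer(c("estimate", "ci_low", "ci_high", "r2", "r", "p"),
        names_to = "statistic", values_to = "value"
      ) |>
      mutate(
        table = "structure_function",
        region_type = .data$rad_region_type, region = .data$rad_region,
        measure = "mfPhNR_RAD~GCL_T"
      ) |>
      select("table", "region_type", "region", "measure", "statistic", "value")
  )
}

#' @describeIn run_full_analysis One-row summary: cohort sizes, number of
#'   significant comparisons, reconciliation status.
#' @export
glance.mfphnr_report <- function(x, ...) {
  tibble(
    n_patients = dplyr::n_distinct(x$cohort$eye_id[x$cohort$group == "patient"]),
    n_regions = nrow(x$group_table),
    n_significant = sum(x$group_table$significant),
    n_reconciled = if (is.null(x$reconciliation)) NA_integer_ else sum(x$reconciliation$match),
    n_reconcilable = if (is.null(x$reconciliation)) NA_integer_ else nrow(x$reconciliation)
  )
}
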