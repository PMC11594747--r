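#' Plot regional means against eccentricity or sector position
#'
#' Group means (with +/- 1 SD bars where individual values exist) of a
#' measure across its ordered regions, one line per group — the classical
#' way eccentricity-dependent RAD or thickness loss is displayed.
#'
#' @param report An `mfphnr_report` from [run_full_analysis()].
#' @param measure `"mfPhNR_RAD"` or `"GCL_T"`.
#' @return A ggplot object.
#' @export
plot_eccentricity_trend <- function(report, measure = c("mfPhNR_RAD", "GCL_T")) {
  measure <- match.arg(measure)
  type <- if (measure == "mfPhNR_RAD") "ring" else "area"
  levels <- if (measure == "mfPhNR_RAD") {
    c("R1", "R2", "R3+R4")
  } else {
    c("Area1", "Area2", "Area3")
  }
  pat <- report$group_table |>
    filter(.data$measure == !!measure, .data$region_type == type)
  d <- bind_rows(
    pat |> mutate(group = "patient", mean = .data$patient_mean, sd = .data$patient_sd),
    pat |> mutate(group = "control", mean = .data$control_mean, sd = .data$control_sd)
  ) |>
    mutate(region = factor(.data$region, levels = levels))
  ylab <- if (measure == "mfPhNR_RAD") {
    "mfPhNR RAD (nV/deg²)"
  } else {
    "GCL thickness (µm)"
  }
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$region, y = .data$mean,
    group = .data$group, colour = .data$group
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - .data$sd,
      ymax = .data$mean + .data$sd
    )) +
    ggplot2::labs(x = NULL, y = ylab, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot structure-function scatter with regression lines
#'
#' Patient-level mfPhNR RAD against GCL thickness for each paired region,
#' with the OLS fit overlaid.
#'
#' @param report An `mfphnr_report`.
#' @param pairs Subset of [region_pairs()] to display (default all).
#' @return A ggplot object, faceted by region pair.
#' @export
plot_structure_function <- function(report, pairs = region_pairs()) {
  patients <- report$cohort |> filter(.data$group == "patient")
  d <- purrr::pmap_dfr(pairs, function(rad_region_type, rad_region,
                                       gcl_region_type, gcl_region) {
    rad <- patients |>
      filter(
        .data$region_type == rad_region_type, .data$region == rad_region,
        .data$measure == "mfPhNR_RAD"
      )
    gcl <- patients |>
      filter(
        .data$region_type == gcl_region_type, .data$region == gcl_region,
        .data$measure == "GCL_T"
      )
    dplyr::inner_join(
      rad |> select("eye_id", rad = "value"),
      gcl |> select("eye_id", gcl = "value"),
      by = "eye_id"
    ) |>
      mutate(pair = paste(rad_region, "vs", gcl_region))
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gcl, y = .data$rad)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::facet_wrap(~pair, scales = "free") +
    ggplot2::labs(
      x = "GCL thickness (µm)",
      y = "mfPhNR RAD (nV/deg²)"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn run_full_analysis Default visualization of a report:
#'   eccentricity trends or structure-function scatter.
#' @param object An `mfphnr_report`.
#' @param type `"trend"` or `"structure_function"`.
#' @export
autoplot.mfphnr_report <- function(object, type = c("trend", "structure_function"), ...) {
  type <- match.arg(type)
  if (type == "trend") {
    plot_eccentricity_trend(object, "mfPhNR_RAD")
  } else {
    plot_structure_function(object)
  }
}

#' @describeIn first_order_kernel Overlay of the extracted element
#'   kernels.
#' @param object A `kernel_set`.
#' @export
autoplot.kernel_set <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$time_ms, y = .data$nv,
    group = .data$element_id
  )) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_vline(xintercept = c(50, 90), linetype = "dashed") +
    ggplot2::labs(x = "time from stimulus onset (ms)", y = "amplitude (nV)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
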