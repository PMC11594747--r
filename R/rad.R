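#' Baseline-to-trough response amplitude density (RAD)
#'
#' The mfPhNR statistic: the difference between the pre-stimulus baseline
#' and the most negative point of the response trough with an implicit
#' time between 50 and 90 ms from stimulus onset, normalized by the
#' stimulated area to give an amplitude *density* in nV/deg^2. If the
#' minimum is attained at several samples the earliest is reported.
#'
#' @param kernel Numeric kernel voltages (nV).
#' @param area Stimulated area, deg^2.
#' @param time_ms Time axis of `kernel`, ms relative to stimulus onset.
#' @param baseline_window Window (ms, closed) averaged for the baseline.
#' @param trough_window Window (ms, closed) searched for the trough.
#'
#' @return A one-row tibble: `rad` (nV/deg^2), `trough_time_ms`,
#'   `baseline_nv`, `trough_nv`.
#' @export
#' @examples
#' tpl <- element_response_template(waveform_params(trough_amp = 25), area = 1)
#' measure_rad(tpl, area = 1, time_ms = seq_along(tpl) - 1)
measure_rad <- function(kernel, area, time_ms,
                        baseline_window = c(-10, 0),
                        trough_window = c(50, 90)) {
  if (length(kernel) != length(time_ms)) {
    abort("kernel and time_ms must have the same length", class = "mfphnr_domain_error")
  }
  in_win <- function(w) time_ms >= w[1] & time_ms <= w[2]
  bl <- in_win(baseline_window)
  tr <- in_win(trough_window)
  if (!any(bl) || !any(tr)) {
    abort("baseline or trough window lies outside the kernel support",
      class = "mfphnr_domain_error"
    )
  }
  if (area <= 0) abort("area must be positive", class = "mfphnr_domain_error")
  baseline <- mean(kernel[bl])
  ti <- which(tr)
  imin <- ti[which.min(kernel[ti])] # which.min returns the earliest minimum
  trough <- kernel[imin]
  tibble(
    rad = (baseline - trough) / area,
    trough_time_ms = time_ms[imin],
    baseline_nv = baseline,
    trough_nv = trough
  )
}

#' Per-element RAD values of a kernel set
#'
#' Applies [measure_rad()] to every element kernel, normalizing each by
#' its own element area. Negative densities (trough above baseline, seen
#' only in pathological noise) are kept but flagged.
#'
#' @param kernel_set A `kernel_set` from [first_order_kernel()].
#' @inheritParams measure_rad
#' @return A tibble: `element_id`, `area_deg2`, `rad`, `trough_time_ms`,
#'   `flag_negative`.
#' @export
rad_by_element <- function(kernel_set,
                           baseline_window = c(-10, 0),
                           trough_window = c(50, 90)) {
  stopifnot(inherits(kernel_set, "kernel_set"))
  els <- kernel_set$elements
  purrr::map_dfr(seq_len(nrow(els)), function(i) {
    m <- measure_rad(
      kernel_set$kernels[i, ], els$area_deg2[i], kernel_set$time_ms,
      baseline_window, trough_window
    )
    tibble(
      element_id = els$element_id[i],
      area_deg2 = els$area_deg2[i],
      rad = m$rad,
      trough_time_ms = m$trough_time_ms,
      flag_negative = m$rad < 0
    )
  })
}

weighted_rad <- function(rad, area, weighting) {
  if (weighting == "area") sum(rad * area) / sum(area) else mean(rad)
}

#' Aggregate per-element RADs into concentric rings
#'
#' Averages element densities into the ring regions used in the analysis:
#' R1 (0-5 deg), R2 (5-10 deg), and the combined R3+R4 (10-20 deg), which
#' is the unweighted mean of the R3 and R4 ring values. Within a ring the
#' default is an area-weighted mean of the member elements (so the ring
#' value equals total amplitude over total area); `weighting =
#' "unweighted"` averages element densities directly.
#'
#' @param rads Tibble from [rad_by_element()] (needs `element_id`, `rad`,
#'   `area_deg2`).
#' @param topography Element table from [build_dartboard()].
#' @param weighting `"area"` (default) or `"unweighted"`.
#' @param eye_id Identifier attached to the output rows.
#' @return A tibble of regional measures: `eye_id`, `region_type`
#'   (`"ring"`), `region` (R1, R2, R3+R4), `measure` (`"mfPhNR_RAD"`),
#'   `value`, `units`.
#' @export
aggregate_rings <- function(rads, topography, weighting = c("area", "unweighted"),
                            eye_id = "sim") {
  weighting <- match.arg(weighting)
  d <- dplyr::inner_join(rads, topography[, c("element_id", "ring")], by = "element_id")
  ring_levels <- c("R1", "R2", "R3", "R4")
  missing <- setdiff(ring_levels, unique(d$ring))
  if (length(missing)) {
    abort(paste("empty ring(s):", paste(missing, collapse = ", ")),
      class = "mfphnr_domain_error"
    )
  }
  per_ring <- d |>
    group_by(.data$ring) |>
    summarise(value = weighted_rad(.data$rad, .data$area_deg2, weighting)) |>
    ungroup()
  v <- setNames(per_ring$value, per_ring$ring)
  tibble(
    eye_id = eye_id,
    region_type = "ring",
    region = c("R1", "R2", "R3+R4"),
    measure = "mfPhNR_RAD",
    value = c(v[["R1"]], v[["R2"]], mean(c(v[["R3"]], v[["R4"]]))),
    units = "nV_per_deg2"
  )
}

#' Aggregate per-element RADs into macular sectors
#'
#' Sector values for the central disc (S1 = ring R1) and the four
#' quadrants of the 5-20 degree annulus. For each quadrant the R2, R3 and
#' R4 portions are first averaged within themselves (area-weighted by
#' default), and the sector value is the unweighted mean of the three
#' portion values, mirroring the ring-combination rule.
#'
#' @inheritParams aggregate_rings
#' @return A tibble of regional measures with `region_type = "sector"` and
#'   regions S1, ST, SN, IN, IT.
#' @export
aggregate_sectors <- function(rads, topography, weighting = c("area", "unweighted"),
                              eye_id = "sim") {
  weighting <- match.arg(weighting)
  d <- dplyr::inner_join(
    rads, topography[, c("element_id", "ring", "sector")],
    by = "element_id"
  )
  quadrants <- c("ST", "SN", "IN", "IT")
  outer_rings <- c("R2", "R3", "R4")
  per_portion <- d |>
    filter(.data$sector %in% quadrants, .data$ring %in% outer_rings) |>
    group_by(.data$sector, .data$ring) |>
    summarise(value = weighted_rad(.data$rad, .data$area_deg2, weighting), .groups = "drop")
  n_expected <- length(quadrants) * length(outer_rings)
  if (nrow(per_portion) < n_expected) {
    have <- paste(per_portion$sector, per_portion$ring)
    want <- as.vector(outer(quadrants, outer_rings, paste))
    abort(paste("empty sector portion(s):", paste(setdiff(want, have), collapse = ", ")),
      class = "mfphnr_domain_error"
    )
  }
  per_sector <- per_portion |>
    group_by(.data$sector) |>
    summarise(value = mean(.data$value)) |>
    ungroup()
  s1 <- d |> filter(.data$ring == "R1")
  if (nrow(s1) == 0) abort("empty ring(s): R1", class = "mfphnr_domain_error")
  tibble(
    eye_id = eye_id,
    region_type = "sector",
    region = c("S1", quadrants),
    measure = "mfPhNR_RAD",
    value = unname(c(
      weighted_rad(s1$rad, s1$area_deg2, weighting),
      setNames(per_sector$value, per_sector$sector)[quadrants]
    )),
    units = "nV_per_deg2"
  )
}
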