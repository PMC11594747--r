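#' Multifocal stimulus configuration
#'
#' Parameters of the dartboard stimulus used for multifocal photopic
#' negative response (mfPhNR) recording: a circular field of 60 scaled
#' dart elements out to 20 degrees of eccentricity, contrast-reversed
#' between black and white around a photopic mean luminance, driven by a
#' binary maximum-length sequence (m-sequence).
#'
#' @param n_elements Number of dart elements (default 60).
#' @param max_ecc Outer eccentricity of the stimulated field, degrees.
#' @param background_luminance Mean screen luminance, cd/m^2.
#' @param on_luminance,off_luminance Luminance of the white and black
#'   element states, cd/m^2.
#' @param stimulus_frequency Stimulation rate, Hz. One m-sequence step is
#'   presented per stimulation period.
#' @param mseq_order Register length (bits) of the m-sequence; the
#'   sequence has `2^mseq_order - 1` steps.
#'
#' @return A list of class `stimulus_config`.
#' @export
#' @examples
#' cfg <- stimulus_config()
#' cfg$mseq_order
stimulus_config <- function(n_elements = 60L,
                            max_ecc = 20,
                            background_luminance = 200,
                            on_luminance = 400,
                            off_luminance = 0,
                            stimulus_frequency = 7,
                            mseq_order = 12L) {
  if (any(c(background_luminance, on_luminance, off_luminance) < 0)) {
    abort("luminances must be non-negative", class = "mfphnr_config_error")
  }
  if (mseq_order < 2) {
    abort("mseq_order must be at least 2", class = "mfphnr_config_error")
  }
  if (max_ecc <= 0 || n_elements < 1) {
    abort("max_ecc and n_elements must be positive", class = "mfphnr_config_error")
  }
  structure(
    list(
      n_elements = as.integer(n_elements),
      max_ecc = max_ecc,
      background_luminance = background_luminance,
      on_luminance = on_luminance,
      off_luminance = off_luminance,
      stimulus_frequency = stimulus_frequency,
      mseq_order = as.integer(mseq_order)
    ),
    class = "stimulus_config"
  )
}

# Ring boundaries (deg) and the number of wedges per annulus.  12 wedges in
# the two inner rings and 18 in the two outer ones give 60 elements whose
# angular size shrinks with eccentricity, and every wedge boundary set
# contains the horizontal and vertical meridians (30 and 20 divide 90), so
# each element lies wholly inside one quadrant.
ring_defs <- function(max_ecc = 20) {
  tibble(
    ring = c("R1", "R2", "R3", "R4"),
    inner_ecc = c(0, 5, 10, 15) * max_ecc / 20,
    outer_ecc = c(5, 10, 15, 20) * max_ecc / 20,
    n_wedges = c(12L, 12L, 18L, 18L)
  )
}

#' Build the dartboard stimulus layout
#'
#' Tiles the central 20-degree disc with 60 dart elements: four concentric
#' annuli (rings R1-R4 with boundaries at 5, 10, 15 and 20 degrees), each
#' divided into angular wedges aligned to the horizontal and vertical
#' meridians. Every element is labelled with its ring and with the macular
#' sector containing it (S1 for the central 5-degree disc, otherwise one of
#' the four quadrants ST/SN/IN/IT).
#'
#' @param config A [stimulus_config()].
#' @param laterality `"OD"` (right eye, default) or `"OS"`; sector labels
#'   are anatomical, so left-eye layouts are mirrored about the vertical
#'   meridian before labelling.
#'
#' @return A tibble with one row per element: `element_id`, `inner_ecc`,
#'   `outer_ecc`, `theta_start`, `theta_end` (degrees of polar angle,
#'   counter-clockwise from the positive x axis), `area_deg2`, `ring`,
#'   `sector`.
#' @export
#' @examples
#' els <- build_dartboard()
#' table(els$ring)
#' sum(els$area_deg2) - pi * 20^2
build_dartboard <- function(config = stimulus_config(), laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  stopifnot(inherits(config, "stimulus_config"))
  rings <- ring_defs(config$max_ecc)
  if (sum(rings$n_wedges) != config$n_elements) {
    abort("ring layout does not match n_elements", class = "mfphnr_config_error")
  }
  els <- purrr::pmap_dfr(rings, function(ring, inner_ecc, outer_ecc, n_wedges) {
    th <- seq(0, 360, length.out = n_wedges + 1)
    tibble(
      inner_ecc = inner_ecc,
      outer_ecc = outer_ecc,
      theta_start = th[-length(th)],
      theta_end = th[-1],
      ring = ring
    )
  })
  els <- els |>
    mutate(
      element_id = row_number(),
      area_deg2 = pi * (.data$outer_ecc^2 - .data$inner_ecc^2) *
        (.data$theta_end - .data$theta_start) / 360,
      centroid_ecc = (.data$inner_ecc + .data$outer_ecc) / 2,
      centroid_theta = (.data$theta_start + .data$theta_end) / 2,
      centroid_x = .data$centroid_ecc * cospi(.data$centroid_theta / 180),
      centroid_y = .data$centroid_ecc * sinpi(.data$centroid_theta / 180),
      sector = ifelse(
        .data$outer_ecc <= rings$outer_ecc[1],
        "S1",
        assign_sector(.data$centroid_x, .data$centroid_y, laterality)
      )
    ) |>
    select(
      "element_id", "inner_ecc", "outer_ecc", "theta_start", "theta_end",
      "area_deg2", "ring", "sector"
    )
  els
}

#' Assign a macular quadrant sector to a point
#'
#' Labels a point in visual-field degrees (fovea at the origin) with one of
#' the four anatomical quadrants: superior temporal (ST), superior nasal
#' (SN), inferior nasal (IN), inferior temporal (IT). The package works in
#' a right-eye (OD) frame where temporal is negative x and superior is
#' positive y; left-eye (OS) coordinates are mirrored in x before the
#' quadrant lookup, so the returned labels are anatomical rather than
#' screen-sided. Points exactly on the vertical midline are assigned to the
#' temporal side, points on the horizontal midline to the superior side.
#'
#' @param x,y Coordinates in degrees; vectors are recycled to a common
#'   length. The origin is undefined and raises an error.
#' @param laterality `"OD"` or `"OS"`.
#'
#' @return A character vector of sector labels.
#' @export
#' @examples
#' assign_sector(-3, 3, "OD") # ST
#' assign_sector(-3, 3, "OS") # SN
assign_sector <- function(x, y, laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  n <- max(length(x), length(y))
  x <- rep_len(x, n)
  y <- rep_len(y, n)
  if (any(x == 0 & y == 0)) {
    abort("sector undefined at the fovea (0, 0)", class = "mfphnr_domain_error")
  }
  if (laterality == "OS") x <- -x
  temporal <- x <= 0
  superior <- y >= 0
  dplyr::case_when(
    superior & temporal ~ "ST",
    superior & !temporal ~ "SN",
    !superior & !temporal ~ "IN",
    .default = "IT"
  )
}

#' Build the OCT posterior-pole superpixel grid
#'
#' The posterior-pole analysis grid of the macular OCT protocol: an 8 x 8
#' array of superpixels covering the central 30 x 25 degrees, centred on
#' the fovea. Each superpixel is 3.75 x 3.125 degrees; thickness values are
#' attached later (see [simulate_gcl_grid()] or your own data).
#'
#' @param laterality `"OD"` or `"OS"`, used for the anatomical quadrant
#'   label attached to each superpixel.
#'
#' @return A tibble with columns `row`, `col` (1-8, row 1 superior, col 1
#'   temporal for OD), `center_x`, `center_y` (degrees from the fovea,
#'   OD anatomical frame), `width`, `height`, `sector`.
#' @export
#' @examples
#' grid <- build_posterior_pole_grid()
#' nrow(grid)
build_posterior_pole_grid <- function(laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  width <- 30 / 8
  height <- 25 / 8
  g <- tidyr::expand_grid(row = 1:8, col = 1:8) |>
    mutate(
      center_x = -15 + (.data$col - 0.5) * width,
      center_y = 12.5 - (.data$row - 0.5) * height,
      width = width,
      height = height,
      sector = assign_sector(.data$center_x, .data$center_y, laterality)
    )
  g
}
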