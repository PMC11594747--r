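# Concentric OCT analysis areas (degrees of eccentricity of the superpixel
# center; half-open [inner, outer)).  The outer bound of Area 2 is taken as
# 9.37 degrees, consistent with the inner bound of Area 3.
area_defs <- function() {
  tibble(
    area = c("Area1", "Area2", "Area3"),
    inner_radius = c(0, 6.35, 9.37),
    outer_radius = c(6.35, 9.37, 12.5)
  )
}

#' Assign posterior-pole superpixels to concentric areas
#'
#' Each superpixel belongs to the concentric area containing its center's
#' radial distance from the fovea: Area 1 inside 6.35 degrees, Area 2 from
#' 6.35 to 9.37, Area 3 from 9.37 to 12.5 (half-open intervals on the
#' center distance). Superpixels whose centers fall beyond 12.5 degrees
#' are left unassigned (`NA`).
#'
#' @param grid Superpixel tibble from [build_posterior_pole_grid()].
#' @return The grid with columns `ecc` (center distance, degrees) and
#'   `area`.
#' @export
#' @examples
#' g <- map_superpixels_to_areas(build_posterior_pole_grid())
#' table(g$area, useNA = "ifany")
map_superpixels_to_areas <- function(grid) {
  ad <- area_defs()
  grid |>
    mutate(
      ecc = sqrt(.data$center_x^2 + .data$center_y^2),
      area = dplyr::case_when(
        .data$ecc < ad$outer_radius[1] ~ ad$area[1],
        .data$ecc < ad$outer_radius[2] ~ ad$area[2],
        .data$ecc < ad$outer_radius[3] ~ ad$area[3],
        .default = NA_character_
      )
    )
}

#' Assign superpixels to the four 13-superpixel quadrant sectors
#'
#' The quadrant sectors (ST, SN, IN, IT) of the posterior-pole grid are
#' bounded by the horizontal and vertical midlines through the fovea. Each
#' quadrant holds 16 superpixels, of which the 3 nearest the fovea are
#' excluded (the central region is analyzed separately as Area 1), leaving
#' the 13 superpixels per sector used for regional thickness. Ties in the
#' exclusion rank are broken by `(row, col)` order.
#'
#' @param grid Superpixel tibble from [build_posterior_pole_grid()].
#' @param laterality `"OD"` or `"OS"`; quadrant labels are anatomical.
#' @return The grid with columns `ecc` and `sector_set` (the sector label
#'   for members of a 13-superpixel set, `NA` otherwise).
#' @export
#' @examples
#' g <- map_superpixels_to_sectors(build_posterior_pole_grid())
#' table(g$sector_set)
map_superpixels_to_sectors <- function(grid, laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  grid |>
    mutate(
      ecc = sqrt(.data$center_x^2 + .data$center_y^2),
      quadrant = assign_sector(.data$center_x, .data$center_y, laterality)
    ) |>
    group_by(.data$quadrant) |>
    arrange(.data$ecc, .data$row, .data$col, .by_group = TRUE) |>
    mutate(sector_set = ifelse(row_number() <= 3, NA_character_, .data$quadrant)) |>
    ungroup() |>
    arrange(.data$row, .data$col) |>
    select(-"quadrant")
}

#' Regional GCL thickness from a populated superpixel grid
#'
#' Averages superpixel thicknesses (unweighted) over the concentric areas
#' and/or the 13-superpixel quadrant sectors.
#'
#' @param grid A superpixel tibble with a `thickness` column (um), e.g.
#'   from [simulate_gcl_grid()] or your own measurements joined onto
#'   [build_posterior_pole_grid()].
#' @param by Which regionalizations to compute: `"area"`, `"sector"`, or
#'   both (default).
#' @param laterality `"OD"` or `"OS"` for the sector assignment.
#' @param eye_id Identifier attached to the output rows.
#' @return A tibble of regional measures: `eye_id`, `region_type`,
#'   `region`, `measure` (`"GCL_T"`), `value` (um), `units`,
#'   `n_superpixels`.
#' @export
regional_thickness <- function(grid, by = c("area", "sector"),
                               laterality = c("OD", "OS"), eye_id = "sim") {
  by <- match.arg(by, several.ok = TRUE)
  laterality <- match.arg(laterality)
  if (!"thickness" %in% names(grid)) {
    abort("grid has no `thickness` column", class = "mfphnr_domain_error")
  }
  one <- function(g, label_col, type) {
    members <- g |> filter(!is.na(.data[[label_col]]))
    bad <- members |> filter(is.na(.data$thickness) | .data$thickness <= 0)
    if (nrow(bad)) {
      abort(
        sprintf(
          "missing or non-positive thickness in superpixel (row %d, col %d)",
          bad$row[1], bad$col[1]
        ),
        class = "mfphnr_domain_error"
      )
    }
    members |>
      group_by(region = .data[[label_col]]) |>
      summarise(value = mean(.data$thickness), n_superpixels = n(), .groups = "drop") |>
      mutate(eye_id = eye_id, region_type = type, measure = "GCL_T", units = "um") |>
      select("eye_id", "region_type", "region", "measure", "value", "units", "n_superpixels")
  }
  out <- list()
  if ("area" %in% by) {
    out$area <- one(map_superpixels_to_areas(grid), "area", "area")
  }
  if ("sector" %in% by) {
    out$sector <- one(map_superpixels_to_sectors(grid, laterality), "sector_set", "sector")
  }
  bind_rows(out)
}

#' Simulate a posterior-pole GCL thickness grid
#'
#' Constructs superpixel thicknesses whose regional averages hit the
#' requested area and/or sector targets exactly in the noise-free case and
#' in expectation otherwise. The deterministic part is the minimum-norm
#' deviation from a uniform baseline subject to the regional-mean
#' constraints; independent Gaussian noise is added per superpixel.
#'
#' @param sector_means Named numeric (names among ST, SN, IN, IT), um.
#' @param area_means Named numeric (names among Area1, Area2, Area3), um.
#' @param noise_sd Per-superpixel noise standard deviation, um.
#' @param seed Optional integer seed.
#' @param laterality `"OD"` or `"OS"`.
#' @return A superpixel tibble with a `thickness` column.
#' @export
#' @examples
#' g <- simulate_gcl_grid(sector_means = c(ST = 27.2, IT = 28.5, IN = 28.9, SN = 29.6))
#' regional_thickness(g, by = "sector")
simulate_gcl_grid <- function(sector_means = NULL, area_means = NULL,
                              noise_sd = 0, seed = NULL,
                              laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  if (is.null(sector_means) && is.null(area_means)) {
    abort("supply at least one of sector_means or area_means",
      class = "mfphnr_domain_error"
    )
  }
  targets <- c(area_means, sector_means)
  if (any(targets <= 0)) {
    abort("thickness targets must be positive", class = "mfphnr_domain_error")
  }
  grid <- build_posterior_pole_grid(laterality)
  g <- map_superpixels_to_areas(grid)
  g$sector_set <- map_superpixels_to_sectors(grid, laterality)$sector_set
  n <- nrow(g)
  rows <- list()
  for (a in names(area_means)) {
    member <- !is.na(g$area) & g$area == a
    if (!any(member)) abort(paste("unknown area:", a), class = "mfphnr_domain_error")
    rows[[a]] <- member / sum(member)
  }
  for (s in names(sector_means)) {
    member <- !is.na(g$sector_set) & g$sector_set == s
    if (!any(member)) abort(paste("unknown sector:", s), class = "mfphnr_domain_error")
    rows[[s]] <- member / sum(member)
  }
  A <- do.call(rbind, rows)
  b <- as.numeric(targets)
  v0 <- rep(mean(b), n)
  # minimum-norm correction: v = v0 + A'(AA')^-1 (b - A v0)
  v <- v0 + as.vector(crossprod(A, solve(tcrossprod(A), b - A %*% v0)))
  if (!is.null(seed)) set.seed(seed)
  if (noise_sd > 0) v <- v + rnorm(n, 0, noise_sd)
  grid$thickness <- v
  grid
}
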