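cohort_columns <- c("eye_id", "group", "region_type", "region", "measure", "value", "units")

valid_regions <- list(
  ring = c("R1", "R2", "R3+R4"),
  area = c("Area1", "Area2", "Area3"),
  sector = c("S1", "ST", "SN", "IN", "IT")
)

measure_units <- c(mfPhNR_RAD = "nV_per_deg2", GCL_T = "um")

#' Path to a bundled example file
#'
#' The package ships a small set of plain-text fixtures: the open-angle
#' glaucoma cohort table (`oag_cohort.csv`, 21 eyes with regional mfPhNR
#' RAD and GCL thickness values), the control group's regional summary
#' statistics (`control_summary.csv`, 20 eyes), the published normative
#' lower limits (`control_limits.csv`), and the published group-comparison
#' and regression results used for reconciliation (`published_anova.csv`,
#' `published_regressions.csv`).
#'
#' @param file File name, or `NULL` to list the available files.
#' @return A file path (or a character vector of file names).
#' @export
#' @examples
#' mfphnr_example()
#' mfphnr_example("oag_cohort.csv")
mfphnr_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "mfphnr")))
  }
  path <- system.file("extdata", file, package = "mfphnr")
  if (path == "") abort(paste("no bundled file named", file), class = "mfphnr_io_error")
  path
}

#' Read and validate a tidy cohort table
#'
#' Reads a cohort CSV with columns `eye_id`, `group` (control/patient),
#' `region_type` (ring/area/sector), `region`, `measure` (mfPhNR_RAD or
#' GCL_T), `value`, `units`, and enforces the schema: known labels, units
#' consistent with the measure, finite values, and uniqueness of
#' `(eye_id, region_type, region, measure)`.
#'
#' @param path CSV path. Lines starting with `#` are treated as comments.
#' @return A validated tibble.
#' @export
#' @examples
#' cohort <- load_cohort(mfphnr_example("oag_cohort.csv"))
#' dplyr::count(cohort, measure)
load_cohort <- function(path) {
  d <- readr::read_csv(
    path,
    comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      eye_id = readr::col_character(),
      group = readr::col_character(),
      region_type = readr::col_character(),
      region = readr::col_character(),
      measure = readr::col_character(),
      # read as text and convert via strtod: readr's fast double parser
      # can be off by one ulp, which would break exact round-trips
      value = readr::col_character(),
      units = readr::col_character()
    )
  )
  d$value <- as.numeric(d$value)
  validate_cohort(d)
}

#' @rdname load_cohort
#' @param cohort A data frame to validate against the cohort schema.
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols)) {
    abort(paste("missing column(s):", paste(missing_cols, collapse = ", ")),
      class = "mfphnr_io_error"
    )
  }
  cohort <- as_tibble(cohort)[cohort_columns]
  bad_row <- function(i, field, why) {
    abort(sprintf("row %d, field `%s`: %s", i, field, why), class = "mfphnr_io_error")
  }
  chk <- function(ok, field, why) {
    if (any(!ok)) bad_row(which(!ok)[1], field, why)
  }
  chk(cohort$group %in% c("control", "patient"), "group", "must be control or patient")
  chk(
    cohort$region_type %in% names(valid_regions), "region_type",
    "must be ring, area or sector"
  )
  ok_region <- mapply(
    function(rt, r) r %in% valid_regions[[rt]],
    cohort$region_type, cohort$region
  )
  chk(ok_region, "region", "label not valid for its region_type")
  chk(cohort$measure %in% names(measure_units), "measure", "unknown measure")
  chk(
    cohort$units == measure_units[cohort$measure], "units",
    "inconsistent with measure"
  )
  chk(is.finite(cohort$value), "value", "must be finite")
  key <- paste(cohort$eye_id, cohort$region_type, cohort$region, cohort$measure)
  if (anyDuplicated(key)) {
    bad_row(anyDuplicated(key), "eye_id", "duplicated (eye, region, measure) key")
  }
  cohort
}

#' Write a cohort table to CSV
#'
#' Full-precision writer; [load_cohort()] of the result is the identity on
#' the values.
#'
#' @param cohort A validated cohort tibble.
#' @param path Output CSV path.
#' @return The input, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- validate_cohort(cohort)
  # 17 significant digits round-trip IEEE doubles exactly
  out$value <- sprintf("%.17g", out$value)
  readr::write_csv(out, path)
  invisible(cohort)
}

read_fixture <- function(file) {
  readr::read_csv(mfphnr_example(file), comment = "#", show_col_types = FALSE)
}

#' Region pairing between functional and morphological maps
#'
#' The correspondence used throughout the analysis: mfPhNR rings pair with
#' OCT concentric areas of similar extent (R1 with Area 1, R2 with Area 2,
#' R3+R4 with Area 3), and the quadrant sectors pair by name.
#'
#' @return A tibble: `rad_region_type`, `rad_region`, `gcl_region_type`,
#'   `gcl_region`.
#' @export
region_pairs <- function() {
  tibble(
    rad_region_type = c("ring", "ring", "ring", "sector", "sector", "sector", "sector"),
    rad_region = c("R1", "R2", "R3+R4", "ST", "IT", "IN", "SN"),
    gcl_region_type = c("area", "area", "area", "sector", "sector", "sector", "sector"),
    gcl_region = c("Area1", "Area2", "Area3", "ST", "IT", "IN", "SN")
  )
}
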