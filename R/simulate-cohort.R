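#' Specification of a synthetic structure-function cohort
#'
#' Describes the joint distribution from which [simulate_cohort()] draws:
#' for every paired region (see [region_pairs()]) and group, the mfPhNR
#' RAD and GCL thickness of an eye follow a bivariate normal with the
#' given means and SDs and a prescribed correlation. The defaults are the
#' bundled study conditions: 20 control and 21 patient eyes, group
#' moments from the bundled regional summaries, and per-region
#' correlations equal to the square root of the published determination
#' coefficients (applied to both groups, since control correlations were
#' not published).
#'
#' @param n_controls,n_patients Eyes per group (each at least 2).
#' @param moments Tibble with one row per `(pair_id, group)`: columns
#'   `rad_region_type`, `rad_region`, `gcl_region_type`, `gcl_region`,
#'   `group`, `rad_mean`, `rad_sd`, `gcl_mean`, `gcl_sd`. Defaults to the
#'   bundled control and patient summaries.
#' @param r Numeric vector of target correlations, one per region pair (in
#'   [region_pairs()] order), or a single value recycled. Defaults to
#'   `sqrt(R2)` of the bundled published regressions.
#' @param seed Optional integer seed stored in the spec.
#' @return A list of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec(seed = 1)
#' spec$n_patients
cohort_spec <- function(n_controls = 20, n_patients = 21,
                        moments = NULL, r = NULL, seed = NULL) {
  if (n_controls < 2 || n_patients < 2) {
    abort("need at least two eyes per group", class = "mfphnr_domain_error")
  }
  pairs <- region_pairs()
  if (is.null(moments)) moments <- default_cohort_moments()
  need <- c(
    "rad_region_type", "rad_region", "gcl_region_type", "gcl_region",
    "group", "rad_mean", "rad_sd", "gcl_mean", "gcl_sd"
  )
  missing_cols <- setdiff(need, names(moments))
  if (length(missing_cols)) {
    abort(paste("moments is missing:", paste(missing_cols, collapse = ", ")),
      class = "mfphnr_domain_error"
    )
  }
  if (any(moments$rad_sd <= 0) || any(moments$gcl_sd <= 0)) {
    abort("all SDs must be positive", class = "mfphnr_domain_error")
  }
  if (is.null(r)) r <- sqrt(read_fixture("published_regressions.csv")$r2)
  r <- rep_len(r, nrow(pairs))
  if (any(abs(r) > 1)) {
    abort("|r| > 1: implied covariance is not positive definite",
      class = "mfphnr_domain_error"
    )
  }
  structure(
    list(
      n_controls = n_controls, n_patients = n_patients,
      moments = moments, pairs = pairs, r = r, seed = seed
    ),
    class = "cohort_spec"
  )
}

default_cohort_moments <- function() {
  summ <- bind_rows(
    read_fixture("control_summary.csv") |> mutate(group = "control"),
    read_fixture("oag_summary.csv") |> mutate(group = "patient")
  )
  pairs <- region_pairs()
  rad <- summ |> filter(.data$measure == "mfPhNR_RAD")
  gcl <- summ |> filter(.data$measure == "GCL_T")
  pairs |>
    cross_groups() |>
    left_join(
      rad |> select(
        rad_region_type = "region_type", rad_region = "region",
        "group", rad_mean = "mean", rad_sd = "sd"
      ),
      by = c("rad_region_type", "rad_region", "group")
    ) |>
    left_join(
      gcl |> select(
        gcl_region_type = "region_type", gcl_region = "region",
        "group", gcl_mean = "mean", gcl_sd = "sd"
      ),
      by = c("gcl_region_type", "gcl_region", "group")
    )
}

cross_groups <- function(pairs) {
  bind_rows(
    pairs |> mutate(group = "control"),
    pairs |> mutate(group = "patient")
  )
}

#' Simulate a structure-function cohort table
#'
#' Draws, for every eye, region pair and group, a (RAD, GCL thickness)
#' pair from the bivariate normal prescribed by the [cohort_spec()], and
#' returns the result as a tidy cohort table in the same schema as
#' [load_cohort()]. Regions are drawn independently of one another; the
#' prescribed dependence is between the functional and morphological
#' measure of the *same* region, which is the relationship the
#' structure-function statistics estimate.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed; overrides `spec$seed`.
#' @return A tidy cohort tibble (`eye_id`, `group`, `region_type`,
#'   `region`, `measure`, `value`, `units`).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(seed = 7))
#' dplyr::count(cohort, group, measure)
simulate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(seed)) seed <- spec$seed
  if (!is.null(seed)) set.seed(seed)
  sizes <- c(control = spec$n_controls, patient = spec$n_patients)
  prefix <- c(control = "C", patient = "P")
  out <- purrr::map_dfr(c("control", "patient"), function(grp) {
    n <- sizes[[grp]]
    ids <- sprintf("%s%02d", prefix[[grp]], seq_len(n))
    purrr::map_dfr(seq_len(nrow(spec$pairs)), function(i) {
      mom <- spec$moments |>
        filter(
          .data$group == grp,
          .data$rad_region == spec$pairs$rad_region[i],
          .data$rad_region_type == spec$pairs$rad_region_type[i]
        )
      if (nrow(mom) != 1 || !is.finite(mom$rad_mean) || !is.finite(mom$gcl_mean)) {
        abort("moments must contain one complete row per pair and group",
          class = "mfphnr_domain_error"
        )
      }
      rho <- spec$r[i]
      sigma <- matrix(
        c(
          mom$rad_sd^2, rho * mom$rad_sd * mom$gcl_sd,
          rho * mom$rad_sd * mom$gcl_sd, mom$gcl_sd^2
        ),
        2, 2
      )
      xy <- MASS::mvrnorm(n, mu = c(mom$rad_mean, mom$gcl_mean), Sigma = sigma)
      bind_rows(
        tibble(
          eye_id = ids, group = grp,
          region_type = spec$pairs$rad_region_type[i],
          region = spec$pairs$rad_region[i],
          measure = "mfPhNR_RAD", value = xy[, 1], units = "nV_per_deg2"
        ),
        tibble(
          eye_id = ids, group = grp,
          region_type = spec$pairs$gcl_region_type[i],
          region = spec$pairs$gcl_region[i],
          measure = "GCL_T", value = xy[, 2], units = "um"
        )
      )
    })
  })
  validate_cohort(out)
}
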