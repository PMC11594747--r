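test_that("RAD is the baseline-to-trough density with the earliest-minimum tie-break", {
  t_ms <- -10:130
  k <- rep(0, length(t_ms))
  k[t_ms == 70] <- -25
  m <- measure_rad(k, area = 1, time_ms = t_ms)
  expect_equal(m$rad, 25)
  expect_equal(m$trough_time_ms, 70)

  # flat zero kernel
  expect_equal(measure_rad(rep(0, length(t_ms)), 1, t_ms)$rad, 0)

  # area normalization
  expect_equal(measure_rad(2 * k, area = 2, time_ms = t_ms)$rad, 25)

  # a constant offset leaves the baseline-to-trough difference unchanged
  m2 <- measure_rad(k + 3, area = 1, time_ms = t_ms)
  expect_equal(m2$rad, 25)
  expect_equal(m2$baseline_nv, 3)

  # tie on the minimum: earliest time reported
  k3 <- rep(0, length(t_ms))
  k3[t_ms %in% c(60, 75)] <- -10
  expect_equal(measure_rad(k3, 1, t_ms)$trough_time_ms, 60)

  expect_error(
    measure_rad(k, 1, t_ms, trough_window = c(200, 250)),
    class = "mfphnr_domain_error"
  )
  expect_error(measure_rad(k, 0, t_ms), class = "mfphnr_domain_error")
})

test_that("simulator round-trip recovers the generating trough density", {
  # one element of area ~2 deg^2 with a 15 nV/deg^2 trough at 70 ms
  els <- build_dartboard()[1, ]
  p <- waveform_params(trough_amp = 15, trough_time = 70)
  ts <- simulate_trace_set(els, generate_mseq(8), p, noise_sd = 0)
  r <- rad_by_element(first_order_kernel(ts))
  expect_equal(r$rad, 15, tolerance = 0.02)
  expect_equal(r$trough_time_ms, 70, tolerance = 3 / 70)

  # moving the trough outside the 50-90 ms window strictly decreases RAD
  p95 <- waveform_params(trough_amp = 15, trough_time = 89)
  ts95 <- simulate_trace_set(els, generate_mseq(8), p95, noise_sd = 0)
  r95 <- rad_by_element(first_order_kernel(ts95))
  # trough at the window edge still captured; widen the shift via windows
  ks <- first_order_kernel(ts95)
  shifted <- measure_rad(
    ks$kernels[1, ], els$area_deg2, ks$time_ms,
    trough_window = c(50, 70)
  )
  expect_lt(shifted$rad, r95$rad)
})

test_that("ring aggregation follows the area-weighted and combination rules", {
  topo <- build_dartboard()
  # uniform field: every ring equals the common value
  rads <- tibble::tibble(
    element_id = topo$element_id, rad = 7,
    area_deg2 = topo$area_deg2
  )
  rr <- aggregate_rings(rads, topo)
  expect_equal(rr$value, rep(7, 3))
  expect_equal(rr$region, c("R1", "R2", "R3+R4"))

  # R3 elements all 6, R4 all 2 -> combined ring mean 4
  rads2 <- rads |>
    dplyr::mutate(rad = dplyr::case_when(
      topo$ring == "R3" ~ 6, topo$ring == "R4" ~ 2, .default = 1
    ))
  expect_equal(
    aggregate_rings(rads2, topo) |>
      dplyr::filter(region == "R3+R4") |>
      dplyr::pull(value),
    4
  )

  # random field: area-weighted oracle per ring
  set.seed(21)
  rads3 <- rads |> dplyr::mutate(rad = runif(60, 1, 30))
  rr3 <- aggregate_rings(rads3, topo)
  oracle <- function(ring) {
    i <- topo$ring == ring
    sum(rads3$rad[i] * topo$area_deg2[i]) / sum(topo$area_deg2[i])
  }
  expect_equal(rr3$value[rr3$region == "R1"], oracle("R1"))
  expect_equal(
    rr3$value[rr3$region == "R3+R4"],
    mean(c(oracle("R3"), oracle("R4")))
  )

  # empty ring errors
  expect_error(
    aggregate_rings(rads3[topo$ring != "R2", ], topo[topo$ring != "R2", ]),
    class = "mfphnr_domain_error"
  )
})

test_that("sector aggregation averages the three ring portions per quadrant", {
  topo <- build_dartboard()
  base <- tibble::tibble(
    element_id = topo$element_id, rad = 5,
    area_deg2 = topo$area_deg2
  )
  ss <- aggregate_sectors(base, topo)
  expect_equal(ss$value, rep(5, 5))
  expect_setequal(ss$region, c("S1", "ST", "SN", "IN", "IT"))

  # ST portions (R2, R3, R4) = (3, 2, 1) -> ST sector value 2
  rads <- base |>
    dplyr::mutate(rad = dplyr::case_when(
      topo$sector == "ST" & topo$ring == "R2" ~ 3,
      topo$sector == "ST" & topo$ring == "R3" ~ 2,
      topo$sector == "ST" & topo$ring == "R4" ~ 1,
      .default = 9
    ))
  expect_equal(
    aggregate_sectors(rads, topo) |>
      dplyr::filter(region == "ST") |>
      dplyr::pull(value),
    2
  )

  # random field vs brute-force portion enumeration
  set.seed(33)
  rads2 <- base |> dplyr::mutate(rad = runif(60, 0.5, 20))
  got <- aggregate_sectors(rads2, topo)
  for (q in c("ST", "SN", "IN", "IT")) {
    portions <- vapply(c("R2", "R3", "R4"), function(rg) {
      i <- topo$sector == q & topo$ring == rg
      sum(rads2$rad[i] * topo$area_deg2[i]) / sum(topo$area_deg2[i])
    }, numeric(1))
    expect_equal(got$value[got$region == q], mean(portions))
  }
  # S1 equals the R1 ring value
  expect_equal(
    got$value[got$region == "S1"],
    aggregate_rings(rads2, topo)$value[1]
  )
})

test_that("regional RADs are scale-equivariant and order-invariant", {
  topo <- build_dartboard()
  set.seed(8)
  rads <- tibble::tibble(
    element_id = topo$element_id,
    rad = runif(60, 1, 10), area_deg2 = topo$area_deg2
  )
  r1 <- aggregate_rings(rads, topo)
  s1 <- aggregate_sectors(rads, topo)

  scaled <- rads |> dplyr::mutate(rad = 3 * rad)
  expect_equal(aggregate_rings(scaled, topo)$value, 3 * r1$value)
  expect_equal(aggregate_sectors(scaled, topo)$value, 3 * s1$value)

  perm <- sample(60)
  expect_equal(aggregate_rings(rads[perm, ], topo)$value, r1$value)
  expect_equal(aggregate_sectors(rads[perm, ], topo)$value, s1$value)
})
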