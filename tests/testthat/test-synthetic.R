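test_that("cohort generation is deterministic and respects degenerate scales", {
  spec <- cohort_spec(seed = 11)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 24)
  # zero variance on LEDD collapses it to the location parameter
  spec0 <- cohort_spec(covariates = list(
    age_at_onset = c(50, 9), duration_before_implant = c(9, 4),
    time_since_implant = c(3.5, 2.5), ledd = c(900, 0), vat = c(150, 60)),
    seed = 2)
  expect_true(all(generate_cohort(spec0)$ledd == 900))
})

test_that("time covariates sum to chronological age and durations are nonnegative", {
  co <- generate_cohort(cohort_spec(seed = 5))
  expect_equal(co$age,
               co$age_at_onset + co$duration_before_implant + co$time_since_implant)
  expect_true(all(co$duration_before_implant >= 0))
  expect_true(all(co$time_since_implant >= 0))
})

test_that("pre-implant duration correlates 0.79 with overall disease duration", {
  spec <- cohort_spec(n_participants = 1000,
                      session_plan = data.frame(state = "ON", retained_n = 1000),
                      seed = 7)
  co <- generate_cohort(spec)
  r <- cor(co$duration_before_implant,
           co$duration_before_implant + co$time_since_implant)
  expect_lt(abs(r - 0.79), 0.15)
})

test_that("session dropout reproduces the 24/22/18 unbalanced design", {
  sess <- attr(generate_cohort(cohort_spec(seed = 3)), "sessions")
  expect_equal(as.integer(table(sess$state)[c("ON", "OFF", "ON2")]),
               c(24L, 22L, 18L))
  # dropout truncates: anyone with ON2 also has OFF
  on2 <- unique(sess$participant[sess$state == "ON2"])
  off <- unique(sess$participant[sess$state == "OFF"])
  expect_true(all(on2 %in% off))
  expect_error(cohort_spec(session_plan = data.frame(
    state = c("ON", "OFF"), retained_n = c(20, 24))), "non-increasing")
})

test_that("simulated measurements are reproducible, 12 min at 10 Hz, with HbR = -HbO", {
  spec <- cohort_spec(seed = 1)
  grid <- tiny_grid()
  p <- generate_cohort(spec)[1, ]
  t1 <- simulate_measurement(p, "ON", grid, spec, seed = 9)
  t2 <- simulate_measurement(p, "ON", grid, spec, seed = 9)
  expect_identical(t1$hbo, t2$hbo)
  expect_equal(dim(t1), c(2, 7200))
  expect_equal(t1$fs, 10)
  expect_identical(t1$hbr, -t1$hbo)
  gt <- attr(t1, "ground_truth")
  expect_lt(gt$spectral_radius, 1)
})

test_that("null generator yields mutually independent channels with floor-level DC", {
  spec <- cohort_spec(effects = list(gain_base = 0, gain_direction = 0),
                      duration_s = 720, seed = 4)
  grid <- tiny_grid()
  p <- generate_cohort(spec)[1, ]
  ts <- simulate_measurement(p, "OFF", grid, spec, seed = 21)
  dc <- estimate_connectivity(ts)
  off <- dc$dc[row(dc$dc) != col(dc$dc)]
  # noise floor: sqrt-of-order-1/n scale fluctuations only
  expect_lt(max(off), 0.15)
  expect_gt(min(diag(dc$dc)), 0.9)
})

test_that("an unstable coupling configuration is refused with the spectral radius", {
  spec <- cohort_spec(effects = list(gain_base = 0.9, gain_direction = 0.6),
                      ar_self = 0.9)
  p <- generate_cohort(cohort_spec(seed = 1))[1, ]
  expect_error(simulate_measurement(p, "ON", tiny_grid(), spec, seed = 1),
               "spectral radius")
})

test_that("mean DC direction difference increases strictly with the direction gain", {
  grid <- tiny_grid()
  p <- generate_cohort(cohort_spec(seed = 2))[1, ]
  gaps <- vapply(c(0, 0.1, 0.2), function(g) {
    spec <- cohort_spec(effects = list(gain_base = 0.08, gain_direction = g),
                        duration_s = 360)
    d <- vapply(1:4, function(s) {
      ts <- simulate_measurement(p, "OFF", grid, spec, seed = 100 + s)
      dc <- estimate_connectivity(ts)
      dc$dc["l_s1_l2", "l_s1_l1"] - dc$dc["l_s1_l1", "l_s1_l2"]
    }, numeric(1))
    mean(d)
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
})

test_that("artifact injection breaks the HbO/HbR anticorrelation and CBSI restores it", {
  spec <- cohort_spec(seed = 6, duration_s = 120)
  p <- generate_cohort(spec)[1, ]
  ts <- simulate_measurement(p, "ON", tiny_grid(), spec, seed = 3)
  expect_identical(inject_artifacts(ts, rate = 0), ts)
  art <- inject_artifacts(ts, rate = 2, amplitude = 5, seed = 8)
  expect_gt(length(attr(art, "ground_truth")$artifact_times), 0)
  cors <- vapply(seq_len(nrow(art$hbo)),
                 function(i) cor(art$hbo[i, ], art$hbr[i, ]), numeric(1))
  expect_true(all(cors > -1 + 1e-6))
  fixed <- cbsi_correct(art)
  cors2 <- vapply(seq_len(nrow(fixed$hbo)),
                  function(i) cor(fixed$hbo[i, ], fixed$hbr[i, ]), numeric(1))
  expect_equal(cors2, rep(-1, length(cors2)), tolerance = 1e-12)
})

test_that("raw-intensity synthesis inverts the Beer-Lambert conversion", {
  optics <- optics_config()
  spec <- cohort_spec(seed = 9, duration_s = 60)
  p <- generate_cohort(spec)[1, ]
  ts <- simulate_measurement(p, "ON", tiny_grid(), spec, seed = 5)
  # zero concentration change -> constant intensities
  z <- hemo_ts(matrix(0, 2, 50), matrix(0, 2, 50), 10, c("a", "b"))
  I <- generate_raw_intensities(z, optics)
  expect_true(all(I$intensities[[1]] == I$intensities[[1]][1, 1]))
  # round trip: exact on the mean-referenced gauge
  tsg <- mbll_gauge(ts, optics)
  rt <- mbll_convert(generate_raw_intensities(tsg, optics), optics)
  expect_equal(rt$hbo, tsg$hbo, tolerance = 1e-10)
  expect_equal(rt$hbr, tsg$hbr, tolerance = 1e-10)
  # arbitrary series: recovered up to a per-channel additive constant
  rt2 <- mbll_convert(generate_raw_intensities(ts, optics), optics)
  expect_equal(rt2$hbo - rowMeans(rt2$hbo), ts$hbo - rowMeans(ts$hbo),
               tolerance = 1e-8)
  # doubling pathlength x DPF halves inferred concentration changes
  optics2 <- optics_config(distance_cm = 6)
  half <- mbll_convert(generate_raw_intensities(tsg, optics), optics2)
  expect_equal(half$hbo, tsg$hbo / 2, tolerance = 1e-6)
})
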