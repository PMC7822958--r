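test_that("order 20 at 10 Hz records a 2 s lag window and 0.5 Hz native resolution", {
  ts <- random_ts(C = 2, n = 1000, seed = 1)
  v <- fit_var(standardize(ts), p = 20)
  expect_equal(v$lag_window_s, 2)
  H <- transfer_function(v, pad_to = 1000)
  expect_equal(H$native_resolution_hz, 0.5)
  # padded grid spacing is fs / pad_to
  expect_equal(diff(H$f[1:2]), 10 / 1000)
})

test_that("white noise fits to near-zero coefficients", {
  set.seed(10)
  x <- matrix(rnorm(3 * 10000), 3)
  v <- fit_var(hemo_ts(x, -x, 10), p = 5)
  expect_lt(max(abs(v$A)), 0.05)
})

test_that("a known 2-channel VAR(1) is recovered by OLS", {
  A <- rbind(c(0.5, 0.3), c(0, 0.5))
  set.seed(99)
  n <- 10000
  x <- matrix(0, 2, n)
  e <- matrix(rnorm(2 * n), 2)
  for (t in 2:n) x[, t] <- A %*% x[, t - 1] + e[, t]
  v <- fit_var(hemo_ts(x, -x, 10), p = 1)
  expect_lt(max(abs(v$A[, , 1] - A)), 0.05)
  expect_lt(max(abs(v$Sigma - diag(2))), 0.1)
})

test_that("rank-deficient regressors are refused", {
  x <- matrix(rnorm(600), 3)
  x[3, ] <- x[1, ]  # duplicated channel
  expect_error(fit_var(hemo_ts(x, -x, 10), p = 2), "rank-deficient")
})

test_that("the transfer function matches the closed form and is diagonal for decoupled systems", {
  # diagonal VAR -> H diagonal at every frequency
  Ad <- array(diag(c(0.4, -0.2, 0.6)), c(3, 3, 1))
  vd <- manual_var(Ad, diag(3))
  Hd <- transfer_function(vd, pad_to = 200)
  for (k in seq_along(Hd$f)) {
    expect_lt(max(Mod(Hd$H[, , k] * (1 - diag(3)))), 1e-14)
  }
  # closed form for a coupled 2-channel VAR(1)
  A <- rbind(c(0.5, 0.3), c(-0.2, 0.4))
  v <- manual_var(A, diag(2))
  H <- transfer_function(v, pad_to = 1000)
  for (k in c(2, 10, 47)) {
    z <- exp(-2i * pi * H$f[k] / 10)
    expect_equal(H$H[, , k], solve(diag(2) - A * z), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("directed coherence is normalized per sink and matches brute force", {
  A <- rbind(c(0.5, 0.3), c(-0.1, 0.4))
  Sigma <- diag(c(1.3, 0.6))
  v <- manual_var(A, Sigma)
  H <- transfer_function(v, pad_to = 1000)
  sp <- directed_coherence(H, Sigma)
  # sink-wise normalization at every frequency
  norms <- apply(sp$dc^2, c(1, 3), sum)
  expect_lt(max(abs(norms - 1)), 1e-10)
  # brute-force oracle at 0.09 Hz (grid point 0.09 = 9 * 10/1000)
  k <- which(abs(sp$f - 0.09) < 1e-9)
  expect_equal(sp$dc[, , k], bf_dc_var1(A, Sigma, 0.09, 10), tolerance = 1e-12,
               ignore_attr = TRUE)
  # decoupled equal-noise system: gamma_ii = 1, gamma_ij = 0 everywhere
  v0 <- manual_var(array(diag(c(0.5, 0.5)), c(2, 2, 1)), diag(2))
  sp0 <- directed_coherence(transfer_function(v0, pad_to = 100), diag(2))
  expect_equal(max(abs(sp0$dc[1, 1, ] - 1)), 0, tolerance = 1e-12)
  expect_equal(max(abs(sp0$dc[1, 2, ])), 0, tolerance = 1e-12)
})

test_that("band-max picks the in-band maximum with inclusive edges", {
  # constructed spectra object with a known peak
  C <- 2
  f <- seq(0, 0.5, by = 0.01)
  dc <- array(0.2, c(C, C, length(f)))
  peak <- which(abs(f - 0.09) < 1e-9)
  dc[2, 1, peak] <- 0.9
  edge <- which(abs(f - 0.06) < 1e-9)
  dc[1, 2, edge] <- 0.7
  sp <- structure(list(f = f, dc = dc, fs = 10, weighted = TRUE,
                       channels = c("a", "b")), class = "dc_spectra")
  bm <- band_max(sp, band = c(0.06, 0.12))
  expect_equal(bm$dc["b", "a"], 0.9)       # interior peak found
  expect_equal(bm$dc["a", "b"], 0.7)       # the 0.06 Hz edge participates
  expect_equal(bm$dc["a", "a"], 0.2)       # constant-in-band spectrum
  expect_error(band_max(sp, band = c(0.061, 0.0615)), "no grid frequency")
})

test_that("connectivity estimation is invariant to channel sign flips", {
  ts <- unidir_ts(n = 3000, seed = 12)
  dc1 <- estimate_connectivity(ts, order = 10)
  flipped <- hemo_ts(ts$hbo * c(1, -1), ts$hbr * c(1, -1), ts$fs, ts$channels)
  dc2 <- estimate_connectivity(flipped, order = 10)
  expect_equal(dc1$dc, dc2$dc, tolerance = 1e-10)
})

test_that("the full pipeline emits a 32x32 DC matrix in [0,1] on a 12-min recording", {
  spec <- cohort_spec(seed = 2)
  grid <- make_grid()
  p <- generate_cohort(spec)[1, ]
  ts <- simulate_measurement(p, "ON", grid, spec, seed = 31)
  dc <- estimate_connectivity(ts, grid = grid)
  expect_equal(dim(dc$dc), c(32, 32))
  expect_true(all(dc$dc >= 0 & dc$dc <= 1))
  expect_equal(dc$pad_to, 7200)
  # driven direction dominates on every stream
  tab <- extract_stream_connections(dc, grid)
  expect_gt(mean(tab$dc[tab$direction == "rostro_caudal"]),
            mean(tab$dc[tab$direction == "caudo_rostral"]))
})

test_that("independent channels stay below a time-shift surrogate null", {
  # channel-wise circular time shifts destroy cross-channel coupling while
  # preserving each channel's spectrum: an estimate on independent data
  # should not exceed the surrogate 95th percentile in most runs
  set.seed(77)
  wins <- 0L
  runs <- 10L
  for (r in seq_len(runs)) {
    x <- matrix(rnorm(2 * 2000), 2)
    x[1, ] <- stats::filter(x[1, ], 0.5, method = "recursive")
    x[2, ] <- stats::filter(x[2, ], 0.5, method = "recursive")
    dc <- estimate_connectivity(hemo_ts(x, -x, 10), order = 10)
    null_dc <- replicate(19, {
      sh <- sample(200:1800, 1)
      xs <- rbind(x[1, ], x[2, c((sh + 1):2000, 1:sh)])
      d <- estimate_connectivity(hemo_ts(xs, -xs, 10), order = 10)
      max(d$dc[row(d$dc) != col(d$dc)])
    })
    if (max(dc$dc[row(dc$dc) != col(dc$dc)]) <= quantile(null_dc, 0.95)) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins / runs, 0.9)
})

test_that("simulate() from a fitted VAR reproduces the coupling structure", {
  ts <- unidir_ts(n = 6000, gain = 0.4, seed = 5)
  v <- fit_var(standardize(ts), p = 10)
  y <- simulate(v, nsim = 6000, seed = 6)
  v2 <- fit_var(y, p = 10)
  # the dominant x -> y lag coefficient survives the round trip
  k <- which.max(abs(v$A["y", "x", ]))
  expect_equal(v2$A["y", "x", k], v$A["y", "x", k], tolerance = 0.1)
})
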