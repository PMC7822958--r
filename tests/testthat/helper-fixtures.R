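# Shared fixtures: everything is generated in code at test time.

# small grids used across tests
tiny_grid <- function() make_grid(n_streams = 1, n_levels = 2,
                                  hemispheres = "left")
small_grid <- function() make_grid(n_streams = 2, n_levels = 3,
                                   hemispheres = "left")

# a fast cohort spec: short recordings, small cohort
fast_spec <- function(n = 6, duration_s = 120, seed = 1L, ...) {
  cohort_spec(n_participants = n,
              session_plan = data.frame(state = c("ON", "OFF"),
                                        retained_n = c(n, n)),
              duration_s = duration_s, seed = seed, ...)
}

# random hemoglobin series (HbO, HbR independent unless anti = TRUE)
random_ts <- function(C = 3, n = 500, fs = 10, anti = FALSE, seed = 1) {
  set.seed(seed)
  hbo <- matrix(rnorm(C * n), C)
  hbr <- if (anti) -hbo else matrix(rnorm(C * n), C)
  hemo_ts(hbo, hbr, fs, sprintf("ch%02d", seq_len(C)))
}

# simulate a 2-channel unidirectionally coupled series (x drives y)
unidir_ts <- function(n = 7200, fs = 10, gain = 0.3, lag = 5, seed = 1) {
  set.seed(seed)
  drive <- dcgradient:::band_noise(n + 200, fs, c(0.06, 0.12))
  ex <- rnorm(n + 200) + drive
  ey <- rnorm(n + 200)
  x <- stats::filter(ex, 0.3, method = "recursive")
  y <- numeric(n + 200)
  for (t in seq_len(n + 200)) {
    y[t] <- 0.3 * (if (t > 1) y[t - 1] else 0) +
      gain * (if (t > lag) x[t - lag] else 0) + ey[t]
  }
  m <- rbind(x = x[201:(n + 200)], y = y[201:(n + 200)])
  hemo_ts(m, -m, fs, c("x", "y"))
}

# connection-table-shaped data from a known linear model (independent of
# the signal pipeline): used as ground truth for the statistics module
make_lmm_table <- function(n_participants = 12,
                           states = c("ON", "OFF"),
                           n_streams = 2, n_pairs = 2,
                           hemispheres = c("left", "right"),
                           direction_effect = 0,
                           state_dir_dur_slope = 0,
                           sd_participant_stream = 0.02,
                           sd_participant_level = 0.02,
                           sd_noise = 0.05, seed = 1) {
  set.seed(seed)
  participants <- sprintf("p%02d", seq_len(n_participants))
  dur <- runif(n_participants, 2, 16)
  grid <- expand.grid(participant = participants, state = states,
                      hemisphere = hemispheres,
                      stream = seq_len(n_streams),
                      level_pair = paste(seq_len(n_pairs), seq_len(n_pairs) + 1,
                                         sep = "-"),
                      direction = c("rostro_caudal", "caudo_rostral"),
                      stringsAsFactors = FALSE)
  ps_re <- matrix(rnorm(n_participants * n_streams, 0, sd_participant_stream),
                  n_participants)
  pl_re <- matrix(rnorm(n_participants * n_pairs, 0, sd_participant_level),
                  n_participants)
  pi <- match(grid$participant, participants)
  li <- match(grid$level_pair, unique(grid$level_pair))
  rc <- grid$direction == "rostro_caudal"
  on <- grid$state %in% c("ON", "ON2")
  grid$dc <- 0.3 + direction_effect * rc +
    state_dir_dur_slope * rc * on * dur[pi] +
    ps_re[cbind(pi, grid$stream)] + pl_re[cbind(pi, li)] +
    rnorm(nrow(grid), 0, sd_noise)
  grid$duration_before_implant <- dur[pi]
  grid$time_since_implant <- runif(n_participants, 1, 6)[pi]
  grid$age_at_onset <- runif(n_participants, 40, 65)[pi]
  grid$ledd <- runif(n_participants, 300, 1500)[pi]
  grid$vat <- runif(n_participants, 50, 250)[pi]
  grid$level <- as.integer(substr(grid$level_pair, 1, 1))
  grid$hemisphere_label <- ifelse(grid$hemisphere == "left", "ipsi", "contra")
  grid
}

# independent brute-force directed coherence for a VAR(1): written directly
# from the definition, no shared code with the package implementation
bf_dc_var1 <- function(A, Sigma, f, fs) {
  C <- nrow(A)
  z <- exp(-2i * pi * f / fs)
  H <- solve(diag(C) - A * z)
  sig <- sqrt(diag(Sigma))
  out <- matrix(0, C, C)
  for (i in seq_len(C)) {
    den <- sqrt(sum(sig^2 * Mod(H[i, ])^2))
    for (j in seq_len(C)) out[i, j] <- sig[j] * Mod(H[i, j]) / den
  }
  out
}

# wrap an explicit coefficient array as a fitted-VAR object so the
# package's spectral path can be exercised without estimation
manual_var <- function(A_array, Sigma, fs = 10, channels = NULL) {
  if (length(dim(A_array)) == 2) A_array <- array(A_array, c(dim(A_array), 1))
  C <- dim(A_array)[1]
  if (is.null(channels)) channels <- sprintf("c%d", seq_len(C))
  dimnames(A_array) <- list(channels, channels, NULL)
  dimnames(Sigma) <- list(channels, channels)
  structure(list(A = A_array, Sigma = Sigma, order = dim(A_array)[3],
                 fs = fs, n_samples_fit = 1000L,
                 lag_window_s = dim(A_array)[3] / fs,
                 spectral_radius = NA_real_, residuals = NULL,
                 channels = channels),
            class = "fnirs_var")
}
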