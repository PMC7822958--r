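#' Cohort and signal-generator specification
#'
#' Defines the synthetic study: cohort size, session plan with dropout,
#' covariate distributions, and the effect sizes that are injected into the
#' directed coupling strengths of the generative vector autoregressive
#' signal model. Defaults emulate the deep-brain-stimulation cohort the
#' pipeline is designed for: 24 patients measured ON stimulation, 22
#' retained for the steady-state OFF measurement and 18 for the second ON
#' measurement (ON2), 12-minute recordings at 10 Hz, and a narrowband
#' oscillatory drive in the 0.06-0.12 Hz band that enters the most rostral
#' channel of each stream and propagates caudally with lag.
#'
#' Covariate distributions are truncated-at-zero normals (location, scale);
#' published patient tables motivate the defaults (e.g. chronological age
#' around 61.5 +/- 9.9 years arises as onset age + pre-implant duration +
#' time since implantation). `duration_cor` sets the construction
#' correlation between the disease duration before implantation and the
#' overall disease duration (default 0.79).
#'
#' Effect sizes are additive changes of the directed coupling gains per
#' edge, covariates entering as z-scores of their generating distribution.
#' Interaction effects are injected antisymmetrically — a positive
#' modulation `m` adds `+m` to the rostro-caudal and `-m` to the
#' caudo-rostral gain — so that an injected effect appears in the
#' direction contrast of the estimated connectivity (the covariate effects
#' they emulate have exactly this push-pull signature):
#' \describe{
#'   \item{gain_base}{baseline coupling gain, both directions}
#'   \item{gain_direction}{extra rostro-caudal gain (the gradient)}
#'   \item{gain_state_direction}{extra rostro-caudal gain when stimulated
#'     (ON or ON2)}
#'   \item{gain_state_duration_direction}{stimulated-state rostro-caudal
#'     gain per SD of pre-implant disease duration (negative by default:
#'     late-implanted patients lose the gradient ON stimulation)}
#'   \item{gain_vat_direction}{rostro-caudal gain per SD of VAT}
#'   \item{gain_ledd_direction}{rostro-caudal gain per SD of LEDD}
#' }
#'
#' @param n_participants Cohort size.
#' @param session_plan Data frame with columns `state` and `retained_n`;
#'   retained counts must be non-increasing (dropout).
#' @param covariates Named list of `c(location, scale)` pairs for
#'   `age_at_onset`, `duration_before_implant`, `time_since_implant`,
#'   `ledd`, `vat`.
#' @param duration_cor Target Pearson correlation between pre-implant and
#'   overall disease duration.
#' @param effects Named list of coupling effect sizes (see Details).
#' @param fs Sampling rate, Hz.
#' @param duration_s Recording length, seconds.
#' @param drive_band Frequency band (Hz) of the narrowband drive.
#' @param coupling_lag Propagation lag between neighboring levels, samples.
#' @param ar_self First-order autoregressive coefficient of each channel.
#' @param drive_sd,noise_sd Innovation SDs of the band drive (rostral
#'   channels) and the white noise (all channels).
#' @param hbo_scale Output amplitude scale of the HbO traces (mM).
#' @param seed Integer seed making the whole cohort reproducible.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 24,
                        session_plan = data.frame(
                          state = c("ON", "OFF", "ON2"),
                          retained_n = c(24, 22, 18)),
                        covariates = list(
                          age_at_onset = c(50, 9),
                          duration_before_implant = c(9, 4),
                          time_since_implant = c(3.5, 2.5),
                          ledd = c(900, 350),
                          vat = c(150, 60)),
                        duration_cor = 0.79,
                        effects = list(
                          gain_base = 0.10,
                          gain_direction = 0.08,
                          gain_state_direction = 0.02,
                          gain_state_duration_direction = -0.04,
                          gain_vat_direction = 0.03,
                          gain_ledd_direction = 0.025),
                        fs = 10, duration_s = 720,
                        drive_band = c(0.06, 0.12),
                        coupling_lag = 5, ar_self = 0.3,
                        drive_sd = 1, noise_sd = 1,
                        hbo_scale = 1e-3,
                        seed = 1L) {
  if (n_participants < 1) stop("configuration error: n_participants < 1")
  if (any(diff(session_plan$retained_n) > 0)) {
    stop("configuration error: retained_n must be non-increasing over sessions")
  }
  if (max(session_plan$retained_n) > n_participants) {
    stop("configuration error: retained_n exceeds cohort size")
  }
  for (nm in names(covariates)) {
    if (covariates[[nm]][2] < 0) {
      stop("configuration error: negative scale for covariate ", nm)
    }
  }
  defaults <- list(gain_base = 0, gain_direction = 0,
                   gain_state_direction = 0,
                   gain_state_duration_direction = 0,
                   gain_vat_direction = 0, gain_ledd_direction = 0)
  unknown <- setdiff(names(effects), names(defaults))
  if (length(unknown)) {
    stop("configuration error: unknown effect(s): ",
         paste(unknown, collapse = ", "))
  }
  defaults[names(effects)] <- effects
  if (!all(vapply(defaults, is.finite, logical(1)))) {
    stop("configuration error: effect sizes must be finite")
  }
  structure(list(n_participants = n_participants,
                 session_plan = session_plan,
                 covariates = covariates, duration_cor = duration_cor,
                 effects = defaults, fs = fs, duration_s = duration_s,
                 drive_band = drive_band, coupling_lag = coupling_lag,
                 ar_self = ar_self, drive_sd = drive_sd, noise_sd = noise_sd,
                 hbo_scale = hbo_scale, seed = as.integer(seed)),
            class = "cohort_spec")
}

# truncated-at-zero normal draws by rejection
rtnorm0 <- function(n, location, scale) {
  if (scale == 0) return(rep(location, n))
  x <- stats::rnorm(n, location, scale)
  while (any(bad <- x < 0)) x[bad] <- stats::rnorm(sum(bad), location, scale)
  x
}

# correlation r between d and t such that cor(d, d + t) equals target.
# cor(d, d + t) is minimized at r = -sd_t/sd_d with value
# sqrt(1 - (sd_t/sd_d)^2); search the increasing branch above the minimum.
solve_component_cor <- function(target, sd_d, sd_t) {
  f <- function(r) {
    (sd_d + r * sd_t) / sqrt(sd_d^2 + 2 * r * sd_d * sd_t + sd_t^2) - target
  }
  lo <- max(-sd_t / sd_d, -0.999)
  if (f(lo) > 0) {
    warning(sprintf(paste0("duration correlation target %.3f below the ",
                           "minimum %.3f achievable with the given scales; ",
                           "using the minimum"), target, f(lo) + target))
    return(lo)
  }
  stats::uniroot(f, c(lo, 0.9999), tol = 1e-10)$root
}

#' Generate a synthetic participant cohort
#'
#' Draws one record per participant: side of disease onset, age at onset,
#' disease duration before implantation, time since implantation (these
#' three sum to the chronological age by construction), LEDD and VAT.
#' Pre-implant duration and time since implantation are drawn jointly so
#' that the correlation between pre-implant duration and overall disease
#' duration matches `spec$duration_cor`. Deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame of class `participant_cohort`, one row per
#'   participant, with a `sessions` attribute listing the measurement
#'   sessions each participant is retained for.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_participants
  cv <- spec$covariates
  sd_d <- cv$duration_before_implant[2]; sd_t <- cv$time_since_implant[2]
  if (sd_d > 0 && sd_t > 0) {
    r <- solve_component_cor(spec$duration_cor, sd_d, sd_t)
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    d <- cv$duration_before_implant[1] + sd_d * z1
    t <- cv$time_since_implant[1] + sd_t * (r * z1 + sqrt(1 - r^2) * z2)
    bad <- d < 0 | t < 0
    while (any(bad)) {
      m <- sum(bad)
      z1 <- stats::rnorm(m); z2 <- stats::rnorm(m)
      d[bad] <- cv$duration_before_implant[1] + sd_d * z1
      t[bad] <- cv$time_since_implant[1] + sd_t * (r * z1 + sqrt(1 - r^2) * z2)
      bad <- d < 0 | t < 0
    }
  } else {
    d <- rtnorm0(n, cv$duration_before_implant[1], sd_d)
    t <- rtnorm0(n, cv$time_since_implant[1], sd_t)
  }
  cohort <- data.frame(
    participant = sprintf("p%02d", seq_len(n)),
    side_of_onset = sample(c("left", "right"), n, replace = TRUE),
    age_at_onset = rtnorm0(n, cv$age_at_onset[1], cv$age_at_onset[2]),
    duration_before_implant = d,
    time_since_implant = t,
    ledd = rtnorm0(n, cv$ledd[1], cv$ledd[2]),
    vat = rtnorm0(n, cv$vat[1], cv$vat[2]),
    stringsAsFactors = FALSE)
  cohort$age <- cohort$age_at_onset + cohort$duration_before_implant +
    cohort$time_since_implant
  # dropout: truncate each participant's session list, deterministically
  plan <- spec$session_plan
  n_sessions <- integer(n)
  n_sessions[seq_len(min(plan$retained_n[1], n))] <- 1
  if (nrow(plan) > 1) {
    for (k in 2:nrow(plan)) {
      keep <- sample(which(n_sessions == k - 1), plan$retained_n[k])
      n_sessions[keep] <- k
    }
  }
  sessions <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (n_sessions[i] == 0) return(NULL)
    data.frame(participant = cohort$participant[i],
               state = plan$state[seq_len(n_sessions[i])],
               stringsAsFactors = FALSE)
  }))
  structure(cohort, sessions = sessions,
            class = c("participant_cohort", "data.frame"))
}

# band-limited Gaussian noise, unit variance, via Fourier masking
band_noise <- function(n, fs, band) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f) # fold to [0, fs/2]
  X[f < band[1] | f > band[2]] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / stats::sd(y)
}

# directed coupling gains for one measurement. Direction-interaction
# effects enter antisymmetrically: a positive modulation strengthens the
# rostro-caudal and weakens the caudo-rostral coupling, so the injected
# effect is expressed in the direction contrast of the estimated DC even
# though standardization couples the two directions' estimates through the
# channel variances.
coupling_gains <- function(participant, state, spec) {
  e <- spec$effects
  cv <- spec$covariates
  z <- function(value, nm) {
    if (cv[[nm]][2] == 0) 0 else (value - cv[[nm]][1]) / cv[[nm]][2]
  }
  stim_on <- state %in% c("ON", "ON2")
  m <- stim_on * e$gain_state_direction +
    stim_on * e$gain_state_duration_direction *
      z(participant$duration_before_implant, "duration_before_implant") +
    e$gain_vat_direction * z(participant$vat, "vat") +
    e$gain_ledd_direction * z(participant$ledd, "ledd")
  list(rostro_caudal = e$gain_base + e$gain_direction + m,
       caudo_rostral = e$gain_base - m)
}

# build lag-indexed coupling edge list for an analyzed grid
grid_edges <- function(grid, gains) {
  ana <- grid[grid$analyzed, , drop = FALSE]
  edges <- list()
  for (h in unique(ana$hemisphere)) {
    for (s in sort(unique(ana$stream[ana$hemisphere == h]))) {
      ch <- ana[ana$hemisphere == h & ana$stream == s, ]
      ch <- ch[order(ch$level), ]
      for (k in seq_len(nrow(ch) - 1)) {
        edges[[length(edges) + 1]] <-
          list(src = ch$id[k], dst = ch$id[k + 1], gain = gains$rostro_caudal)
        edges[[length(edges) + 1]] <-
          list(src = ch$id[k + 1], dst = ch$id[k], gain = gains$caudo_rostral)
      }
    }
  }
  edges
}

# companion-matrix spectral radius of a VAR coefficient array A[ , , lag]
companion_spectral_radius <- function(A) {
  C <- dim(A)[1]; p <- dim(A)[3]
  M <- matrix(0, C * p, C * p)
  for (k in seq_len(p)) M[1:C, (k - 1) * C + 1:C] <- A[, , k]
  if (p > 1) M[(C + 1):(C * p), 1:(C * (p - 1))] <- diag(C * (p - 1))
  max(Mod(eigen(M, only.values = TRUE)$values))
}

#' Simulate one fNIRS measurement with known directed coupling
#'
#' Generates the HbO/HbR traces of a single session from a stable generative
#' vector autoregressive model over the analyzed channels of `grid`. A
#' band-limited Gaussian drive inside `spec$drive_band` enters the most
#' rostral channel of each stream and propagates caudally through lagged
#' linear coupling; a weaker caudo-rostral coupling runs in the opposite
#' direction. The rostro-caudal coupling gain is
#' baseline + direction effect + state and covariate interaction terms (see
#' [cohort_spec()]). HbR is exactly `-HbO` before any artifact injection.
#'
#' @param participant One row of a [generate_cohort()] data frame (or a
#'   list with the same fields).
#' @param state Session state, one of `"ON"`, `"OFF"`, `"ON2"`.
#' @param grid A [build_channel_grid()].
#' @param spec A [cohort_spec()].
#' @param seed Integer seed for this measurement.
#' @return A [hemo_ts()] with attribute `ground_truth`: a list with the
#'   directed `coupling` edge list, the per-direction `gains`, `drive_band`,
#'   and the companion `spectral_radius` of the generative model.
#' @export
simulate_measurement <- function(participant, state, grid, spec,
                                 seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  gains <- coupling_gains(participant, state, spec)
  edges <- grid_edges(grid, gains)
  ids <- grid$id
  C <- length(ids)
  L <- max(spec$coupling_lag, 1)
  A <- array(0, c(C, C, L))
  for (i in seq_len(C)) A[i, i, 1] <- A[i, i, 1] + spec$ar_self
  for (e in edges) {
    A[match(e$dst, ids), match(e$src, ids), spec$coupling_lag] <-
      A[match(e$dst, ids), match(e$src, ids), spec$coupling_lag] + e$gain
  }
  rho <- companion_spectral_radius(A)
  if (rho >= 1) {
    stop(sprintf(paste0("configuration error: implied VAR unstable ",
                        "(companion spectral radius %.3f >= 1); ",
                        "reduce coupling gains"), rho))
  }
  n <- round(spec$duration_s * spec$fs)
  burn <- 40 * L + 200
  N <- n + burn
  # innovations: white noise everywhere, band drive into level-1 channels
  E <- matrix(stats::rnorm(C * N, 0, spec$noise_sd), C, N)
  ana <- grid[grid$analyzed, , drop = FALSE]
  rostral <- ana$id[ana$level == min(ana$level)]
  for (id in rostral) {
    E[match(id, ids), ] <- E[match(id, ids), ] +
      spec$drive_sd * band_noise(N, spec$fs, spec$drive_band)
  }
  X <- matrix(0, C, N)
  a1 <- A[, , 1]; aL <- if (L > 1) A[, , L] else NULL
  sparse1 <- all(a1 == diag(diag(a1)))  # default: lag-1 term is diagonal
  d1 <- diag(a1)
  for (t in seq_len(N)) {
    x <- E[, t]
    if (t > 1) x <- x + if (sparse1) d1 * X[, t - 1] else a1 %*% X[, t - 1]
    if (!is.null(aL) && t > L) x <- x + aL %*% X[, t - L]
    X[, t] <- x
  }
  X <- X[, (burn + 1):N, drop = FALSE]
  hbo <- spec$hbo_scale * X
  rownames(hbo) <- ids
  ts <- hemo_ts(hbo, -hbo, spec$fs, ids)
  attr(ts, "ground_truth") <- list(
    coupling = edges, gains = gains, drive_band = spec$drive_band,
    spectral_radius = rho, artifact_times = integer(0))
  ts
}

#' Inject motion artifacts with the CBSI-detectable signature
#'
#' Adds spike events with the SAME sign to HbO and HbR of every channel
#' (the common-mode signature of head motion that correlation-based signal
#' improvement removes). Event onsets follow a Poisson process; each event
#' is an exponentially decaying spike (decay time constant 0.5 s) with
#' amplitude `amplitude` times the channel's HbO standard deviation and a
#' random per-channel sign. Event times are appended to the
#' `ground_truth$artifact_times` attribute.
#'
#' @param ts A [hemo_ts()].
#' @param rate Events per minute (>= 0).
#' @param amplitude Event amplitude in multiples of the channel SD.
#' @param seed Integer seed.
#' @return The artifacted [hemo_ts()].
#' @export
inject_artifacts <- function(ts, rate = 2, amplitude = 5, seed = 1L) {
  if (rate < 0) stop("configuration error: rate must be >= 0")
  if (rate == 0) return(ts)
  set.seed(seed)
  n <- ncol(ts$hbo); C <- nrow(ts$hbo)
  minutes <- n / ts$fs / 60
  n_events <- stats::rpois(1, rate * minutes)
  if (n_events == 0) return(ts)
  times <- sort(sample(seq_len(n), n_events))
  kernel <- exp(-(0:round(2 * ts$fs)) / (0.5 * ts$fs))
  sds <- apply(ts$hbo, 1, stats::sd)
  hbo <- ts$hbo; hbr <- ts$hbr
  for (tt in times) {
    idx <- tt:min(n, tt + length(kernel) - 1)
    k <- kernel[seq_along(idx)]
    signs <- sample(c(-1, 1), C, replace = TRUE)
    bump <- (amplitude * sds * signs) %o% k
    hbo[, idx] <- hbo[, idx] + bump
    hbr[, idx] <- hbr[, idx] + bump  # same sign: the motion signature
  }
  out <- hemo_ts(hbo, hbr, ts$fs, ts$channels)
  gt <- attr(ts, "ground_truth")
  if (is.null(gt)) gt <- list()
  gt$artifact_times <- sort(c(gt$artifact_times, times))
  attr(out, "ground_truth") <- gt
  out
}

#' Synthesize raw dual-wavelength intensities from a hemoglobin series
#'
#' Inverse of the modified Beer-Lambert conversion: computes the optical
#' densities implied by the concentration changes and emits intensity
#' traces `I = I0 * 10^(-dOD)` per wavelength. Forward conversion with
#' [mbll_convert()] recovers `ts` up to the per-channel additive baseline
#' constant fixed by the mean-intensity reference; it recovers `ts` exactly
#' when `ts` is in the mean-intensity gauge (see [mbll_gauge()]).
#'
#' @param ts A [hemo_ts()].
#' @param optics An [optics_config()].
#' @param I0 Baseline intensity (arbitrary units).
#' @return An [optical_ts()].
#' @export
generate_raw_intensities <- function(ts, optics = optics_config(), I0 = 1) {
  M <- mbll_matrix(optics)
  od1 <- M[1, 1] * ts$hbo + M[1, 2] * ts$hbr
  od2 <- M[2, 1] * ts$hbo + M[2, 2] * ts$hbr
  optical_ts(list(I0 * 10^(-od1), I0 * 10^(-od2)),
             wavelengths = optics$wavelengths, fs = ts$fs,
             channels = ts$channels)
}

#' Simulate a full study: cohort, sessions, measurements
#'
#' Draws the cohort, then simulates one measurement per retained
#' participant-session with a per-measurement seed derived from
#' `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param grid A [build_channel_grid()].
#' @param artifact_rate Motion events per minute (0 = clean signals).
#' @param artifact_amplitude Event amplitude, channel SDs.
#' @return A list with `cohort`, `sessions` (data frame participant/state)
#'   and `measurements` (list of [hemo_ts()] keyed `participant.state`).
#' @export
simulate_study <- function(spec, grid = make_grid(),
                           artifact_rate = 0, artifact_amplitude = 5) {
  cohort <- generate_cohort(spec)
  sessions <- attr(cohort, "sessions")
  measurements <- vector("list", nrow(sessions))
  names(measurements) <- paste(sessions$participant, sessions$state, sep = ".")
  for (i in seq_len(nrow(sessions))) {
    p <- cohort[cohort$participant == sessions$participant[i], ]
    mseed <- (spec$seed * 1009L + i * 7919L) %% .Machine$integer.max
    ts <- simulate_measurement(p, sessions$state[i], grid, spec, seed = mseed)
    if (artifact_rate > 0) {
      ts <- inject_artifacts(ts, artifact_rate, artifact_amplitude,
                             seed = mseed + 1L)
    }
    measurements[[i]] <- ts
  }
  list(cohort = cohort, sessions = sessions, measurements = measurements)
}
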