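#' Beat template: sum-of-Gaussians morphology for one beat class
#'
#' Each beat is modelled as a sum of Gaussian deflections (P, Q, R, S, T)
#' placed relative to the R-wave center at time 0. `rr_scale` is a
#' multiplicative prematurity factor applied to the RR interval preceding a
#' beat of this class (e.g. 0.7 = premature supraventricular beat).
#'
#' @param class_symbol One of "N", "S", "V", "E".
#' @param waves data.frame with columns `wave` (label), `center` (s, relative
#'   to the nominal R position), `amp` (mV), `width` (s, Gaussian sd).
#' @param rr_scale Prematurity factor in (0.3, 1.5].
#' @return A `beat_template` object.
#' @export
beat_template <- function(class_symbol, waves, rr_scale = 1) {
  stopifnot(class_symbol %in% c("N", "S", "V", "E"))
  waves <- as.data.frame(waves)
  stopifnot(all(c("wave", "center", "amp", "width") %in% names(waves)))
  r <- waves$amp[waves$wave == "R"]
  if (length(r) != 1L || r <= 0) stop("R amplitude must be > 0", call. = FALSE)
  if (any(waves$width <= 0)) stop("wave widths must be > 0", call. = FALSE)
  if (rr_scale <= 0.3 || rr_scale > 1.5)
    stop("rr_scale must lie in (0.3, 1.5]", call. = FALSE)
  structure(list(class_symbol = class_symbol, waves = waves,
                 rr_scale = rr_scale), class = "beat_template")
}

#' Default beat templates for the four classes
#'
#' N: full P-QRS-T, on-time. S: premature (rr_scale 0.7) with reduced P.
#' V: moderately premature (0.85), absent P, QRS widened 3x, inverted T.
#' E: on-time but with the R center displaced +60 ms and R amplitude raised.
#' Amplitudes in mV, times in seconds relative to the nominal R position.
#'
#' @return Named list of [beat_template()]s.
#' @export
default_templates <- function() {
  base <- data.frame(
    wave   = c("P", "Q", "R", "S", "T"),
    center = c(-0.20, -0.035, 0.00, 0.035, 0.30),
    amp    = c(0.15, -0.12, 1.00, -0.20, 0.30),
    width  = c(0.025, 0.010, 0.012, 0.012, 0.060))
  n <- base
  s <- base; s$amp[s$wave == "P"] <- 0.04
  v <- base
  v$amp[v$wave == "P"] <- 0
  qrs <- v$wave %in% c("Q", "R", "S")
  v$width[qrs] <- v$width[qrs] * 3
  v$amp[v$wave == "T"] <- -0.30
  e <- base
  e$center[e$wave == "R"] <- 0.06
  e$amp[e$wave == "R"] <- 1.5
  list(N = beat_template("N", n, 1.0),
       S = beat_template("S", s, 0.7),
       V = beat_template("V", v, 0.85),
       E = beat_template("E", e, 1.0))
}

#' Render a single beat waveform from a template
#'
#' Evaluates the sum of Gaussians on a sample grid spanning all waves
#' (4 sd on either side).
#'
#' @param template A [beat_template()].
#' @param fs Sampling frequency, Hz.
#' @return Numeric vector (mV) with attributes `t0` (time of first sample
#'   relative to the nominal R position, s) and `fs`.
#' @export
synth_beat <- function(template, fs) {
  w <- template$waves[template$waves$amp != 0, , drop = FALSE]
  if (any(w$width * fs < 2))
    stop("fs too low to resolve the narrowest wave (width*fs < 2)",
         call. = FALSE)
  t0 <- min(w$center - 4 * w$width)
  t1 <- max(w$center + 4 * w$width)
  n <- round((t1 - t0) * fs)
  t <- t0 + (seq_len(n) - 1) / fs
  y <- rep(0, n)
  for (i in seq_len(nrow(w)))
    y <- y + w$amp[i] * exp(-(t - w$center[i])^2 / (2 * w$width[i]^2))
  attr(y, "t0") <- t0
  attr(y, "fs") <- fs
  y
}

#' Simulation configuration for the synthetic Holter generator
#'
#' @param fs Sampling frequency, Hz (>= 100).
#' @param duration Recording length, s.
#' @param n_leads Number of leads.
#' @param mean_hr Mean heart rate, bpm.
#' @param hr_jitter_sd SD of additive Gaussian RR jitter, s.
#' @param class_probs Named probability vector over c(N, S, V, E); must sum
#'   to 1.
#' @param noise List with `baseline_amp` (mV), `baseline_freq` (Hz),
#'   `white_sd` (mV), `powerline_amp` (mV), `powerline_freq` (Hz).
#' @param lead_gain Per-lead multiplicative gain (length `n_leads`).
#' @param seed Integer RNG seed.
#' @param templates Named list of beat templates (default
#'   [default_templates()]).
#' @param patient_id Optional string.
#' @return A `sim_config` list.
#' @export
sim_config <- function(fs = 250, duration = 60, n_leads = 2, mean_hr = 70,
                       hr_jitter_sd = 0.02,
                       class_probs = c(N = 1, S = 0, V = 0, E = 0),
                       noise = list(baseline_amp = 0.1, baseline_freq = 0.3,
                                    white_sd = 0.02, powerline_amp = 0.02,
                                    powerline_freq = 50),
                       lead_gain = NULL, seed = 1,
                       templates = default_templates(),
                       patient_id = NULL) {
  if (fs < 100) stop("fs must be >= 100 Hz", call. = FALSE)
  if (abs(sum(class_probs) - 1) > 1e-9)
    stop("class_probs must sum to 1", call. = FALSE)
  if (any(class_probs < 0)) stop("class_probs must be >= 0", call. = FALSE)
  if (duration * mean_hr / 60 < 1)
    stop("duration too short for a single beat", call. = FALSE)
  if (is.null(lead_gain)) lead_gain <- seq(1, by = -0.15,
                                           length.out = n_leads)
  if (length(lead_gain) != n_leads)
    stop("lead_gain must have one entry per lead", call. = FALSE)
  cp <- c(N = 0, S = 0, V = 0, E = 0)
  cp[names(class_probs)] <- class_probs
  structure(list(fs = fs, duration = duration, n_leads = n_leads,
                 mean_hr = mean_hr, hr_jitter_sd = hr_jitter_sd,
                 class_probs = cp, noise = noise, lead_gain = lead_gain,
                 seed = seed, templates = templates,
                 patient_id = patient_id),
            class = "sim_config")
}

#' Add configured noise to a signal matrix
#'
#' Adds a baseline-wander sinusoid, a powerline sinusoid (both phase 0, so
#' the decomposition is exactly reproducible) and white Gaussian noise drawn
#' independently per lead from the given seed. A zero spec returns the input
#' unchanged.
#'
#' @param signal Numeric matrix, samples x leads.
#' @param fs Sampling frequency, Hz.
#' @param noise Noise spec list, see [sim_config()].
#' @param seed Integer seed for the white-noise draw.
#' @return Matrix of the same shape.
#' @export
add_noise <- function(signal, fs, noise, seed = 1) {
  signal <- as.matrix(signal)
  amps <- c(noise$baseline_amp, noise$white_sd, noise$powerline_amp)
  if (any(amps < 0)) stop("noise amplitudes/sds must be >= 0", call. = FALSE)
  if (all(amps == 0)) return(signal)
  n <- nrow(signal)
  t <- (seq_len(n) - 1) / fs
  extra <- rep(0, n)
  if (noise$baseline_amp > 0)
    extra <- extra + noise$baseline_amp * sin(2 * pi * noise$baseline_freq * t)
  if (noise$powerline_amp > 0)
    extra <- extra + noise$powerline_amp * sin(2 * pi * noise$powerline_freq * t)
  out <- signal + extra
  if (noise$white_sd > 0) {
    set.seed(seed)
    out <- out + matrix(stats::rnorm(n * ncol(signal), sd = noise$white_sd),
                        nrow = n)
  }
  out
}

#' Simulate a labelled multi-lead Holter-like recording
#'
#' Beats are placed on an RR grid (base RR = 60/mean_hr, class-dependent
#' prematurity via `rr_scale`, Gaussian jitter), rendered from the class
#' templates, summed into a base signal, then copied to each lead with a
#' per-lead gain and independent noise. Every beat is annotated at its true
#' R-wave center (template R offset included).
#'
#' @param config A [sim_config()].
#' @return List with elements `recording` ([ecg_recording()]) and
#'   `annotations` ([beat_annotations()]).
#' @export
synth_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fs <- config$fs
  n <- round(config$duration * fs)
  base_rr <- 60 / config$mean_hr
  classes <- names(config$class_probs)

  # beat schedule: nominal R positions + class draws
  t_beat <- 0.5
  beat_t <- numeric(0)
  beat_cls <- character(0)
  margin <- config$duration - 0.45
  repeat {
    cls <- sample(classes, 1, prob = config$class_probs)
    if (length(beat_t)) {
      rr <- base_rr * config$templates[[cls]]$rr_scale
      if (config$hr_jitter_sd > 0) rr <- rr + stats::rnorm(1, 0, config$hr_jitter_sd)
      rr <- max(rr, 0.25)
      t_beat <- beat_t[length(beat_t)] + rr
    }
    if (t_beat > margin) break
    beat_t <- c(beat_t, t_beat)
    beat_cls <- c(beat_cls, cls)
  }

  base <- rep(0, n)
  r_sample <- integer(length(beat_t))
  for (i in seq_along(beat_t)) {
    tpl <- config$templates[[beat_cls[i]]]
    w <- tpl$waves[tpl$waves$amp != 0, , drop = FALSE]
    for (j in seq_len(nrow(w))) {
      c_abs <- beat_t[i] + w$center[j]
      lo <- max(1L, floor((c_abs - 4 * w$width[j]) * fs) + 1L)
      hi <- min(n, ceiling((c_abs + 4 * w$width[j]) * fs) + 1L)
      if (hi < lo) next
      tt <- (seq(lo, hi) - 1) / fs
      base[lo:hi] <- base[lo:hi] +
        w$amp[j] * exp(-(tt - c_abs)^2 / (2 * w$width[j]^2))
    }
    r_off <- w$center[w$wave == "R"]
    r_sample[i] <- round((beat_t[i] + r_off) * fs)
  }

  sig <- matrix(0, nrow = n, ncol = config$n_leads)
  lead_seeds <- sample.int(.Machine$integer.max, config$n_leads)
  for (l in seq_len(config$n_leads)) {
    sig[, l] <- add_noise(matrix(config$lead_gain[l] * base, ncol = 1),
                          fs, config$noise, seed = lead_seeds[l])
  }
  rec <- ecg_recording(sig, fs,
                       lead_names = paste0("lead", seq_len(config$n_leads)),
                       patient_id = config$patient_id)
  list(recording = rec,
       annotations = beat_annotations(r_sample, beat_cls))
}
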