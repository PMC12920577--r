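#' Detect R-peaks with a derivative-square-integrate detector
#'
#' Pan-Tompkins-style: differentiate, square, moving-window integrate
#' (150 ms), then pick local maxima of the integrated energy above an
#' adaptive threshold (running signal/noise peak estimates), enforce a
#' 0.2 s refractory period, and localize each detection to the signal's
#' local maximum within +/- 50 ms. All thresholds are relative to the
#' signal's own energy, so the detector is amplitude-scale invariant.
#'
#' @param x Numeric vector (one lead, ideally bandpass-filtered).
#' @param fs Sampling frequency, Hz (>= 100).
#' @return Integer vector of 0-based peak sample indices, strictly
#'   ascending, with attribute `fs`.
#' @export
detect_r_peaks <- function(x, fs) {
  if (fs < 100) stop("fs must be >= 100 Hz", call. = FALSE)
  n <- length(x)
  refr <- round(0.2 * fs)
  if (n < refr + 2L || max(x) == min(x)) {
    out <- integer(0); attr(out, "fs") <- fs; return(out)
  }
  d <- c(0, diff(x))
  sq <- d * d
  w <- max(3L, round(0.15 * fs))
  mwi <- stats::filter(sq, rep(1 / w, w), sides = 2)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)
  if (max(mwi) <= 0) { out <- integer(0); attr(out, "fs") <- fs; return(out) }

  # candidate local maxima of the integrated energy
  is_max <- mwi[2:(n - 1)] >= mwi[1:(n - 2)] & mwi[2:(n - 1)] > mwi[3:n]
  cand <- which(is_max) + 1L
  if (!length(cand)) { out <- integer(0); attr(out, "fs") <- fs; return(out) }

  spk <- max(mwi[seq_len(min(n, round(2 * fs)))])
  npk <- 0
  thr <- npk + 0.15 * (spk - npk)
  peaks <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (mwi[i] > thr) {
      if (i - last < refr) {
        if (length(peaks) && mwi[i] > mwi[peaks[length(peaks)]]) {
          peaks[length(peaks)] <- i
          last <- i
          spk <- 0.125 * mwi[i] + 0.875 * spk
        }
      } else {
        peaks <- c(peaks, i)
        last <- i
        spk <- 0.125 * mwi[i] + 0.875 * spk
      }
    } else {
      npk <- 0.125 * mwi[i] + 0.875 * npk
    }
    thr <- npk + 0.15 * (spk - npk)
  }
  if (!length(peaks)) { out <- integer(0); attr(out, "fs") <- fs; return(out) }

  # localize to the raw-signal maximum within +/- 50 ms
  half <- round(0.05 * fs)
  loc <- vapply(peaks, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  loc <- sort(unique(loc))
  # re-enforce refractory after localization
  keep <- rep(TRUE, length(loc))
  last <- loc[1]
  for (j in seq_along(loc)[-1]) {
    if (loc[j] - last < refr) {
      keep[j] <- x[loc[j]] > x[last]
      if (keep[j]) { keep[j - 1] <- FALSE; last <- loc[j] }
    } else last <- loc[j]
  }
  out <- as.integer(loc[keep] - 1L)   # 0-based
  attr(out, "fs") <- fs
  out
}

#' Time-domain heart-rate features from an R-peak list
#'
#' RR intervals are successive peak-time differences in seconds; mean RR,
#' SDNN (sample SD of the RR series) and mean HR = 60/mean RR. With fewer
#' than two peaks the rate statistics are NA.
#'
#' @param peaks 0-based peak indices (as from [detect_r_peaks()]).
#' @param fs Sampling frequency, Hz (taken from the `fs` attribute when
#'   missing).
#' @return List with `rr` (seconds), `mean_rr`, `sdnn`, `mean_hr`,
#'   `n_beats`.
#' @export
time_features <- function(peaks, fs = attr(peaks, "fs")) {
  if (is.null(fs)) stop("fs required", call. = FALSE)
  n <- length(peaks)
  if (n < 2L)
    return(list(rr = numeric(0), mean_rr = NA_real_, sdnn = NA_real_,
                mean_hr = NA_real_, n_beats = n))
  rr <- diff(sort(as.numeric(peaks))) / fs
  mean_rr <- mean(rr)
  list(rr = rr, mean_rr = mean_rr,
       sdnn = if (length(rr) >= 2L) stats::sd(rr) else NA_real_,
       mean_hr = 60 / mean_rr, n_beats = n)
}

#' One-sided periodogram power spectral density
#'
#' PSD(f) = |FFT(x)|^2 with density normalization 1/(N*fs) and one-sided
#' folding, so that sum(power) * (fs/N) equals the signal's mean square
#' exactly (discrete Parseval identity).
#'
#' @param x Numeric vector, length >= 8.
#' @param fs Sampling frequency, Hz.
#' @return A `psd_curve` list with `freq` (Hz, ascending, up to fs/2) and
#'   `power` (nonnegative).
#' @export
power_spectrum <- function(x, fs) {
  n <- length(x)
  if (n < 8L) stop("signal too short for a periodogram (need >= 8)",
                   call. = FALSE)
  X <- stats::fft(x)
  full <- Mod(X)^2 / (n * fs)
  half <- floor(n / 2)
  idx <- seq_len(half + 1L)            # DC .. Nyquist bin
  p <- full[idx]
  fold <- 2:(if (n %% 2 == 0) half else half + 1L)
  p[fold] <- 2 * p[fold]
  structure(list(freq = (idx - 1) * fs / n, power = p), class = "psd_curve")
}

# rectangle-rule band integral over the half-open band [lo, hi): bins tile
# the spectrum, so band powers sum without double-counting shared edges
band_integral <- function(freq, power, lo, hi) {
  if (hi <= lo) return(0)
  df <- stats::median(diff(freq))
  sum(power[freq >= lo & freq < hi]) * df
}

#' Default HRV spectral bands (Hz) for RR-interval series
#' @return Named list of c(lo, hi) ranges: VLF 0.003-0.04, LF 0.04-0.15,
#'   HF 0.15-0.40.
#' @export
hrv_bands <- function() {
  list(vlf = c(0.003, 0.04), lf = c(0.04, 0.15), hf = c(0.15, 0.40))
}

#' Wide spectral bands (Hz) for raw ECG segment spectra
#'
#' Coarse morphology bands: 0.5-4 Hz (P/T-wave energy), 4-15 Hz (QRS
#' energy), 15-40 Hz (high-frequency content). Used when band powers are
#' taken from the raw-signal periodogram rather than an RR series.
#' @return Named list of c(lo, hi) ranges.
#' @export
wide_bands <- function() {
  list(vlf = c(0.5, 4), lf = c(4, 15), hf = c(15, 40))
}

#' Band powers and derived frequency-domain features from a PSD
#'
#' Integrates the PSD over the named half-open bands \[lo, hi) by the
#' rectangle rule (power per bin times bin width), so adjacent bands never
#' double-count a shared edge and band powers sum consistently with the
#' periodogram's Parseval identity. `total_power` integrates the whole
#' curve; `dominant_freq` is the frequency of the maximum-power bin.
#'
#' @param psd A `psd_curve` from [power_spectrum()].
#' @param bands Named list of c(lo, hi) ranges; see [hrv_bands()] /
#'   [wide_bands()].
#' @return List with `vlf_power`, `lf_power`, `hf_power`, `total_power`,
#'   `lf_hf_ratio` (NA when HF power is 0), `dominant_freq`.
#' @export
band_powers <- function(psd, bands = hrv_bands()) {
  stopifnot(inherits(psd, "psd_curve"))
  rng <- range(psd$freq)
  for (b in bands)
    if (b[1] < rng[1] - 1e-12 || b[2] > rng[2] + 1e-12)
      stop("band [", b[1], ", ", b[2], "] outside the frequency grid [",
           rng[1], ", ", rng[2], "]", call. = FALSE)
  v <- band_integral(psd$freq, psd$power, bands$vlf[1], bands$vlf[2])
  l <- band_integral(psd$freq, psd$power, bands$lf[1], bands$lf[2])
  h <- band_integral(psd$freq, psd$power, bands$hf[1], bands$hf[2])
  tot <- band_integral(psd$freq, psd$power, rng[1], rng[2] + 1e-12)
  list(vlf_power = v, lf_power = l, hf_power = h, total_power = tot,
       lf_hf_ratio = if (h > 0) l / h else NA_real_,
       dominant_freq = psd$freq[which.max(psd$power)])
}

phi_m <- function(x, m, r) {
  n <- length(x)
  nv <- n - m + 1L
  D <- abs(outer(x, x, "-"))
  W <- D[seq_len(nv), seq_len(nv), drop = FALSE] <= r
  if (m > 1L) for (k in seq_len(m - 1L))
    W <- W & (D[seq_len(nv) + k, seq_len(nv) + k, drop = FALSE] <= r)
  mean(log(rowSums(W) / nv))
}

#' Approximate entropy (Pincus estimator)
#'
#' ApEn(m, r) = Phi^m(r) - Phi^{m+1}(r), with Phi^m the mean log fraction
#' of template matches under the Chebyshev (max-coordinate) distance,
#' self-matches included. Lower for regular (periodic) series, higher for
#' irregular ones. Defaults m = 2, r = 0.2 * SD(series); a zero-variance
#' series resolves r to a small absolute floor and returns 0.
#'
#' @param x Numeric series, length > m + 1.
#' @param m Embedding dimension.
#' @param r Tolerance; if NULL, `r_frac * sd(x)`.
#' @param r_frac Fraction of the series SD used when `r` is NULL.
#' @return Nonnegative scalar.
#' @export
approximate_entropy <- function(x, m = 2, r = NULL, r_frac = 0.2) {
  n <- length(x)
  if (n <= m + 1L) stop("series too short for ApEn (need length > m+1)",
                        call. = FALSE)
  if (is.null(r)) r <- r_frac * stats::sd(x)
  if (!is.finite(r) || r <= 0) r <- 1e-12
  phi_m(x, m, r) - phi_m(x, m + 1L, r)
}

#' Poincare plot descriptors SD1/SD2 of an RR series
#'
#' Computed exactly as the SDs of the lagged point cloud (RR_i, RR_{i+1})
#' rotated 45 degrees: SD1 (short-axis) = SD of (RR_i - RR_{i+1})/sqrt(2),
#' SD2 (long-axis) = SD along the line of identity; population variances.
#' A numerically negative SD2 radicand is clipped to 0 with a warning.
#'
#' @param rr RR interval series, seconds, length >= 3.
#' @return List with `sd1`, `sd2` (seconds).
#' @export
poincare <- function(rr) {
  if (length(rr) < 3L) stop("need >= 3 RR intervals", call. = FALSE)
  x <- rr[-length(rr)]; y <- rr[-1]
  vp <- function(z) mean((z - mean(z))^2)
  sd1sq <- vp(x - y) / 2
  sd2sq <- vp(x) + vp(y) - sd1sq
  if (sd2sq < 0) { warning("negative SD2 radicand clipped to 0"); sd2sq <- 0 }
  list(sd1 = sqrt(sd1sq), sd2 = sqrt(sd2sq))
}

#' Names of the per-sub-window feature vector
#' @return Character vector of the 14 feature names (masks are appended
#'   with a `m_` prefix in the tensor).
#' @export
feature_names <- function() {
  c("mean_rr", "sdnn", "mean_hr", "n_beats", "vlf", "lf", "hf",
    "lf_hf_ratio", "dominant_freq", "apen", "sd1", "sd2",
    "sig_mean", "sig_sd")
}

#' Extract the model input tensor from a labelled segment set
#'
#' Each segment is split into `T` equal sub-windows. R-peaks are detected
#' once per segment per lead, then assigned to sub-windows; the RR
#' intervals attributed to a sub-window are those ending in it, so local
#' prematurity is visible even in 1 s sub-windows. Per sub-window per lead
#' the feature vector holds time-domain (mean RR, SDNN, mean HR, beat
#' count), frequency-domain (band powers of the demeaned sub-window
#' periodogram over [wide_bands()], LF/HF ratio, dominant frequency),
#' non-linear (approximate entropy, Poincare SD1/SD2) and amplitude
#' (mean, SD) entries. Missing values (too few beats for a statistic) are
#' imputed as 0 with a parallel 0/1 observed-mask channel, keeping the
#' model input fixed-size.
#'
#' @param segments A labelled `segment_set` (see [encode_and_label()]).
#' @param T Number of sub-windows per segment (default 10).
#' @param apen_m,apen_r_frac Approximate-entropy parameters.
#' @param bands Spectral bands for the sub-window periodogram.
#' @return A `feature_tensor`: list with `x` (array segments x T x leads x
#'   28), `labels`, `label_map`, `patient` (per-segment source id), `fs`,
#'   `feature_names`.
#' @export
extract_feature_tensor <- function(segments, T = 10, apen_m = 2,
                                   apen_r_frac = 0.2, bands = wide_bands()) {
  stopifnot(inherits(segments, "segment_set"))
  if (is.null(segments$labels))
    stop("segment set must be labelled first (encode_and_label)",
         call. = FALSE)
  d <- dim(segments$data)
  n_seg <- d[1]; n_lead <- d[2]; N <- d[3]
  if (T > N) stop("more sub-windows than samples per segment", call. = FALSE)
  n_sub <- N %/% T
  fs <- segments$fs
  fn <- feature_names()
  d_feat <- length(fn)
  x <- array(0, dim = c(n_seg, T, n_lead, 2 * d_feat),
             dimnames = list(NULL, NULL, NULL,
                             c(fn, paste0("m_", fn))))
  for (s in seq_len(n_seg)) {
    for (l in seq_len(n_lead)) {
      sig <- segments$data[s, l, ]
      peaks <- detect_r_peaks(sig, fs)
      pk_t <- peaks / fs
      rr_all <- if (length(peaks) >= 2L) diff(pk_t) else numeric(0)
      rr_end <- if (length(peaks) >= 2L) pk_t[-1] else numeric(0)
      for (w in seq_len(T)) {
        lo_t <- (w - 1) * n_sub / fs
        hi_t <- w * n_sub / fs
        sub <- sig[((w - 1) * n_sub + 1):(w * n_sub)]
        v <- stats::setNames(rep(NA_real_, d_feat), fn)

        in_w <- pk_t >= lo_t & pk_t < hi_t
        v["n_beats"] <- sum(in_w)
        rr_w <- rr_all[rr_end >= lo_t & rr_end < hi_t]
        if (length(rr_w) >= 1L) {
          v["mean_rr"] <- mean(rr_w)
          v["mean_hr"] <- 60 / mean(rr_w)
          if (length(rr_w) >= 2L) v["sdnn"] <- stats::sd(rr_w)
        }
        ps <- power_spectrum(sub - mean(sub), fs)
        bp <- band_powers(ps, bands)
        v["vlf"] <- bp$vlf_power; v["lf"] <- bp$lf_power
        v["hf"] <- bp$hf_power
        v["lf_hf_ratio"] <- bp$lf_hf_ratio
        v["dominant_freq"] <- bp$dominant_freq
        v["apen"] <- if (n_sub > apen_m + 1L)
          approximate_entropy(sub, m = apen_m, r_frac = apen_r_frac) else NA
        if (length(rr_w) >= 3L) {
          pc <- poincare(rr_w)
          v["sd1"] <- pc$sd1; v["sd2"] <- pc$sd2
        }
        v["sig_mean"] <- mean(sub)
        v["sig_sd"] <- stats::sd(sub)

        mask <- as.numeric(!is.na(v))
        v[is.na(v)] <- 0
        x[s, w, l, ] <- c(v, mask)
      }
    }
  }
  structure(list(x = x, labels = segments$labels,
                 label_map = segments$label_map,
                 patient = rep(segments$source_id, n_seg),
                 fs = fs, feature_names = fn),
            class = "feature_tensor")
}

#' Concatenate feature tensors along the segment axis
#' @param ... `feature_tensor` objects with identical layouts.
#' @return A combined `feature_tensor`.
#' @export
bind_feature_tensors <- function(...) {
  ts <- list(...)
  if (length(ts) == 1L && is.list(ts[[1]]) && !inherits(ts[[1]], "feature_tensor"))
    ts <- ts[[1]]
  stopifnot(all(vapply(ts, inherits, TRUE, "feature_tensor")))
  dims <- lapply(ts, function(t) dim(t$x)[-1])
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("feature tensors have incompatible layouts", call. = FALSE)
  d <- dim(ts[[1]]$x)
  n_tot <- sum(vapply(ts, function(t) dim(t$x)[1], 0))
  x <- array(0, dim = c(n_tot, d[2], d[3], d[4]),
             dimnames = dimnames(ts[[1]]$x))
  off <- 0L
  for (t in ts) {
    n <- dim(t$x)[1]
    if (n) x[(off + 1):(off + n), , , ] <- t$x
    off <- off + n
  }
  structure(list(x = x,
                 labels = unlist(lapply(ts, `[[`, "labels"), use.names = FALSE),
                 label_map = ts[[1]]$label_map,
                 patient = unlist(lapply(ts, `[[`, "patient"), use.names = FALSE),
                 fs = ts[[1]]$fs, feature_names = ts[[1]]$feature_names),
            class = "feature_tensor")
}
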