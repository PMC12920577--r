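#' Bandpass filter specification
#'
#' Defaults to the fourth-order Butterworth bandpass with 0.5 and 40 Hz
#' cutoffs used throughout the pipeline: the low edge removes baseline
#' wander and motion artifact, the high edge suppresses muscle and
#' powerline noise while preserving the clinical ECG band.
#'
#' @param order Filter order (the analogue prototype order; >= 1).
#' @param f_low Lower -3 dB cutoff, Hz.
#' @param f_high Upper -3 dB cutoff, Hz.
#' @param fs Sampling frequency the filter is designed for, Hz.
#' @return A `filter_spec` list with the designed `signal::butter`
#'   coefficients attached.
#' @export
filter_spec <- function(order = 4, f_low = 0.5, f_high = 40, fs = 360) {
  if (order < 1) stop("order must be >= 1", call. = FALSE)
  if (!(0 < f_low && f_low < f_high && f_high < fs / 2))
    stop("need 0 < f_low < f_high < fs/2", call. = FALSE)
  bt <- signal::butter(order, c(f_low, f_high) / (fs / 2), type = "pass")
  structure(list(order = order, f_low = f_low, f_high = f_high, fs = fs,
                 b = bt$b, a = bt$a), class = "filter_spec")
}

#' Magnitude response of a designed filter
#'
#' Evaluates |H(e^{i 2 pi f / fs})| directly from the transfer-function
#' polynomials, so half-power points can be measured from the design itself.
#'
#' @param spec A [filter_spec()].
#' @param f Frequencies (Hz) at which to evaluate.
#' @return Numeric vector of magnitude gains.
#' @export
filter_response <- function(spec, f) {
  w <- 2 * pi * f / spec$fs
  zb <- exp(-1i * outer(w, seq_along(spec$b) - 1))
  za <- exp(-1i * outer(w, seq_along(spec$a) - 1))
  Mod((zb %*% spec$b) / (za %*% spec$a))[, 1]
}

#' Zero-phase Butterworth bandpass filtering
#'
#' Applies the filter forward and backward (`signal::filtfilt`) per lead,
#' which cancels phase distortion and so preserves R-peak timing; the
#' effective attenuation order is doubled. Output length equals input
#' length; recording metadata is preserved.
#'
#' @param rec An [ecg_recording()].
#' @param spec A [filter_spec()]; its `fs` must match the recording.
#' @return A filtered [ecg_recording()].
#' @export
bandpass_filter <- function(rec, spec = filter_spec(fs = rec$fs)) {
  stopifnot(inherits(rec, "ecg_recording"), inherits(spec, "filter_spec"))
  if (abs(spec$fs - rec$fs) > 1e-9)
    stop("filter_spec fs (", spec$fs, ") does not match recording fs (",
         rec$fs, ")", call. = FALSE)
  n <- nrow(rec$signal)
  if (n < 3 * (2 * spec$order + 1))
    warning("signal shorter than ~3x the filter settle length; ",
            "edge effects will dominate")
  # reflect-pad (odd symmetry) so the long low-frequency transient of the
  # 0.5 Hz edge settles outside the signal, and demean: DC is outside the
  # passband anyway and large offsets otherwise leak through the edges
  pad <- min(n - 1L, round(2 * rec$fs))
  filt <- apply(rec$signal, 2, function(x) {
    mu <- mean(x)
    x <- x - mu
    xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
            2 * x[n] - rev(x[(n - pad):(n - 1)]))
    y <- signal::filtfilt(signal::Arma(b = spec$b, a = spec$a), xp)
    y[(pad + 1):(pad + n)]
  })
  out <- rec
  out$signal <- matrix(filt, nrow = n, ncol = ncol(rec$signal),
                       dimnames = dimnames(rec$signal))
  out
}

#' Min-max normalization to the unit interval
#'
#' Maps a vector affinely so min -> 0 and max -> 1. A flat vector (zero
#' range) maps to all zeros with a warning; flat segments do occur at
#' synthetic-data edges and should not abort a pipeline.
#'
#' @param x Numeric vector with finite values.
#' @return Vector in \[0, 1\].
#' @export
minmax_normalize <- function(x) {
  if (any(!is.finite(x))) stop("non-finite values in input", call. = FALSE)
  rng <- range(x)
  if (rng[2] == rng[1]) {
    warning("zero-range input; returning all zeros")
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

minmax_quiet <- function(x) {
  rng <- range(x)
  if (rng[2] == rng[1]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Sliding-window segmentation specification
#'
#' @param window_s Window duration Delta-t in seconds (default 10).
#' @param overlap_frac Fractional overlap in \[0, 1) (default 0.5, i.e. a
#'   5 s stride for a 10 s window).
#' @param fs Sampling frequency, Hz.
#' @return A `segmentation_spec` with derived `n_samples`
#'   (= round(fs * window_s)) and `stride` (= round(n_samples * (1 -
#'   overlap_frac))).
#' @export
segmentation_spec <- function(window_s = 10, overlap_frac = 0.5, fs = 360) {
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop("overlap_frac must be in [0, 1)", call. = FALSE)
  n_samples <- round(fs * window_s)
  stride <- round(n_samples * (1 - overlap_frac))
  if (n_samples < 2) stop("window too short (n_samples < 2)", call. = FALSE)
  if (stride < 1) stop("stride must be >= 1 sample", call. = FALSE)
  structure(list(window_s = window_s, overlap_frac = overlap_frac, fs = fs,
                 n_samples = n_samples, stride = stride),
            class = "segmentation_spec")
}

#' Segment a recording into overlapping fixed-length windows
#'
#' Windows start at samples 0, stride, 2*stride, ... (0-based, half-open
#' \[start, start + N)); a trailing window that does not fit entirely is
#' dropped, so the segment count is floor((L - N)/stride) + 1. Each lead of
#' each segment is min-max normalized to \[0, 1\] unless `normalize = FALSE`.
#'
#' @param rec An [ecg_recording()] (normally already bandpass-filtered).
#' @param spec A [segmentation_spec()] with matching `fs`.
#' @param normalize Apply per-lead per-segment min-max normalization.
#' @return A `segment_set`: list with `data` (array segments x leads x N),
#'   `start_samples` (0-based), `labels` (NULL until
#'   [encode_and_label()]), `fs`, `lead_names`, `source_id`.
#' @export
segment_signal <- function(rec, spec = segmentation_spec(fs = rec$fs),
                           normalize = TRUE) {
  stopifnot(inherits(rec, "ecg_recording"),
            inherits(spec, "segmentation_spec"))
  if (abs(spec$fs - rec$fs) > 1e-9)
    stop("segmentation_spec fs does not match recording fs", call. = FALSE)
  L <- nrow(rec$signal)
  N <- spec$n_samples
  n_lead <- ncol(rec$signal)
  if (L < N) {
    warning("signal shorter than one window; empty segment set")
    starts <- integer(0)
  } else {
    starts <- seq(0L, L - N, by = spec$stride)
  }
  data <- array(0, dim = c(length(starts), n_lead, N))
  n_flat <- 0L
  for (i in seq_along(starts)) {
    for (l in seq_len(n_lead)) {
      seg <- rec$signal[(starts[i] + 1):(starts[i] + N), l]
      if (normalize) {
        if (max(seg) == min(seg)) n_flat <- n_flat + 1L
        seg <- minmax_quiet(seg)
      }
      data[i, l, ] <- seg
    }
  }
  if (n_flat > 0L)
    warning(n_flat, " flat lead-segments normalized to all zeros")
  structure(list(data = data, start_samples = as.integer(starts),
                 labels = NULL, label_map = NULL,
                 n_samples = N, stride = spec$stride, fs = rec$fs,
                 lead_names = rec$lead_names,
                 source_id = if (is.null(rec$patient_id)) "" else
                   rec$patient_id),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("segment_set: %d segments x %d leads x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  if (!is.null(x$labels))
    cat("  labels:", paste(names(table(decode_labels(x$labels, x$label_map))),
                           table(decode_labels(x$labels, x$label_map)),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Deterministic label map over the class alphabet
#'
#' Assigns contiguous integer codes 0..K-1 in alphabetical symbol order,
#' so for the full four-class alphabet: E=0, N=1, S=2, V=3.
#'
#' @param symbols Character vector of class symbols (defaults to the full
#'   alphabet).
#' @return Named integer vector (the map); its names are the symbols.
#' @export
make_label_map <- function(symbols = c("N", "S", "V", "E")) {
  syms <- sort(unique(symbols))
  stats::setNames(seq_along(syms) - 1L, syms)
}

#' Encode class symbols as integer codes
#' @param symbols Character vector of class symbols.
#' @param label_map A map from [make_label_map()].
#' @return Integer codes.
#' @export
encode_labels <- function(symbols, label_map) {
  codes <- label_map[symbols]
  if (anyNA(codes))
    stop("symbols outside label map: ",
         paste(unique(symbols[is.na(codes)]), collapse = ","), call. = FALSE)
  unname(codes)
}

#' Decode integer codes back to class symbols
#' @param codes Integer codes.
#' @param label_map A map from [make_label_map()].
#' @return Character symbols.
#' @export
decode_labels <- function(codes, label_map) {
  inv <- stats::setNames(names(label_map), label_map)
  out <- inv[as.character(codes)]
  if (anyNA(out)) stop("codes outside label map", call. = FALSE)
  unname(out)
}

#' Assign one class label to every segment
#'
#' Each segment is labelled from the beats whose R-sample falls inside its
#' half-open window. The default `"severity"` rule takes the most severe
#' class present (V > S > E > N), biasing toward not missing an arrhythmic
#' window; `"majority"` takes the most frequent beat class (ties broken by
#' severity). Segments containing no annotated beat are dropped with a
#' message.
#'
#' @param segments A `segment_set` from [segment_signal()].
#' @param anns A [beat_annotations()] data.frame.
#' @param rule `"severity"` (default) or `"majority"`.
#' @return The `segment_set` with `labels` (integer codes) and `label_map`
#'   filled in; dropped segments removed.
#' @export
encode_and_label <- function(segments, anns, rule = c("severity", "majority")) {
  rule <- match.arg(rule)
  stopifnot(inherits(segments, "segment_set"))
  label_map <- make_label_map()
  severity <- c(V = 4, S = 3, E = 2, N = 1)
  n_seg <- length(segments$start_samples)
  labs <- rep(NA_character_, n_seg)
  if (nrow(anns) == 0L) {
    warning("empty annotation list; all segments dropped")
  } else {
    for (i in seq_len(n_seg)) {
      s0 <- segments$start_samples[i]
      in_win <- anns$sample >= s0 & anns$sample < s0 + segments$n_samples
      if (!any(in_win)) next
      syms <- anns$symbol[in_win]
      labs[i] <- if (rule == "severity") {
        names(which.max(severity[unique(syms)]))
      } else {
        tab <- table(syms)
        cand <- names(tab)[tab == max(tab)]
        cand[which.max(severity[cand])]
      }
    }
  }
  keep <- !is.na(labs)
  if (any(!keep))
    message(sum(!keep), " of ", n_seg, " segments contained no beats; dropped")
  segments$data <- segments$data[keep, , , drop = FALSE]
  segments$start_samples <- segments$start_samples[keep]
  segments$labels <- encode_labels(labs[keep], label_map)
  segments$label_map <- label_map
  segments
}
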