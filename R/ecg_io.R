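#' ECG recording container
#'
#' Bundles a multi-lead signal matrix (samples x leads, millivolts) with its
#' sampling frequency and lead metadata. All downstream stages (filtering,
#' segmentation, feature extraction, classification) consume only this type.
#'
#' @param signal Numeric matrix, samples x leads, in millivolts.
#' @param fs Sampling frequency in Hz (> 0).
#' @param lead_names Character vector, one name per lead.
#' @param patient_id Optional string identifying the subject.
#' @param units Optional character vector of per-lead units (default "mV").
#' @return An object of class `ecg_recording`.
#' @export
ecg_recording <- function(signal, fs, lead_names = NULL, patient_id = NULL,
                          units = NULL) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number", call. = FALSE)
  if (ncol(signal) < 1L) stop("recording needs at least one lead", call. = FALSE)
  if (anyNA(signal) || any(!is.finite(signal)))
    stop("signal contains NaN/Inf values", call. = FALSE)
  if (is.null(lead_names)) lead_names <- paste0("lead", seq_len(ncol(signal)))
  if (length(lead_names) != ncol(signal))
    stop("lead_names length must equal lead count", call. = FALSE)
  if (is.null(units)) units <- rep("mV", ncol(signal))
  colnames(signal) <- lead_names
  structure(list(signal = signal, fs = as.numeric(fs),
                 lead_names = as.character(lead_names),
                 patient_id = patient_id, units = units),
            class = "ecg_recording")
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf("ecg_recording: %d samples x %d leads @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$fs, nrow(x$signal) / x$fs))
  cat("  leads:", paste(x$lead_names, collapse = ", "), "\n")
  if (!is.null(x$patient_id)) cat("  patient:", x$patient_id, "\n")
  invisible(x)
}

#' Beat annotation list
#'
#' 0-based R-peak sample indices with class symbols in \{N, S, V, E\}
#' (normal, supraventricular, ventricular, ectopic). Stored sorted strictly
#' ascending by sample index.
#'
#' @param sample A vector of 0-based sample indices.
#' @param symbol A character vector of class symbols, same length.
#' @return A data.frame of class `beat_annotations` with columns
#'   `sample` (integer) and `symbol` (character), sorted ascending.
#' @export
beat_annotations <- function(sample, symbol) {
  if (length(sample) != length(symbol))
    stop("sample and symbol must have equal length", call. = FALSE)
  sample <- as.numeric(sample)
  if (length(sample) && any(sample < 0))
    stop("sample indices must be >= 0", call. = FALSE)
  bad <- !(symbol %in% c("N", "S", "V", "E"))
  if (any(bad))
    stop("unknown class symbols: ", paste(unique(symbol[bad]), collapse = ","),
         call. = FALSE)
  ord <- order(sample)
  df <- data.frame(sample = sample[ord], symbol = as.character(symbol[ord]),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample))
    stop("duplicate annotation sample indices", call. = FALSE)
  class(df) <- c("beat_annotations", "data.frame")
  df
}

#' Default mapping from MIT-BIH/AAMI annotation letters to \{N,S,V,E\}
#'
#' Standard AAMI grouping: \{N,L,R,e,j\} -> N; \{A,a,J,S\} -> S; \{V\} -> V.
#' Fusion/paced/unknown (\{F, E, f, Q, /\}) have no agreed place in the
#' four-symbol scheme used here, so they are unmapped by default and handled
#' per the `on_unknown` policy of [read_annotations()]; override the map to
#' route them (e.g. `c(default_symbol_map(), F = "E")`).
#'
#' @return Named character vector: names are source symbols, values targets.
#' @export
default_symbol_map <- function() {
  c(N = "N", L = "N", R = "N", e = "N", j = "N",
    A = "S", a = "S", J = "S", S = "S",
    V = "V",
    E = "E")
}

# ---- WFDB subset (single-segment, format 16) --------------------------------

parse_hea <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty WFDB header: ", hea_path, call. = FALSE)
  rec <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  if (length(rec) < 3L)
    stop("malformed WFDB record line in ", hea_path, call. = FALSE)
  name <- sub("/.*$", "", rec[[1]])
  if (grepl("/", rec[[1]]))
    stop("multi-segment WFDB records are not supported", call. = FALSE)
  nsig <- suppressWarnings(as.integer(rec[[2]]))
  fs <- suppressWarnings(as.numeric(sub("/.*$", "", rec[[3]])))
  nsamp <- if (length(rec) >= 4L) suppressWarnings(as.numeric(rec[[4]])) else NA
  if (is.na(nsig) || nsig < 1L) stop("bad signal count in header", call. = FALSE)
  if (is.na(fs) || fs <= 0) stop("bad sampling frequency in header", call. = FALSE)
  sig <- lapply(lines[seq(2L, length.out = nsig)], function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(f) < 2L) stop("malformed WFDB signal line", call. = FALSE)
    fmt <- sub("x.*$", "", f[[2]])
    gain_field <- if (length(f) >= 3L) f[[3]] else "200"
    baseline <- 0
    units <- "mV"
    g <- gain_field
    if (grepl("/", g)) { units <- sub("^.*/", "", g); g <- sub("/.*$", "", g) }
    if (grepl("\\(", g)) {
      baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", g))
      g <- sub("\\(.*$", "", g)
    }
    gain <- suppressWarnings(as.numeric(g))
    if (is.na(gain) || gain == 0) gain <- 200
    desc <- if (length(f) >= 9L) paste(f[9:length(f)], collapse = " ") else ""
    list(file = f[[1]], fmt = fmt, gain = gain, baseline = baseline,
         units = units, desc = desc)
  })
  list(name = name, nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

read_wfdb_recording <- function(path) {
  hea_path <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea_path)) stop("header not found: ", hea_path, call. = FALSE)
  hdr <- parse_hea(hea_path)
  fmts <- vapply(hdr$signals, `[[`, "", "fmt")
  if (!all(fmts == "16"))
    stop("only WFDB format 16 is supported (got ", paste(unique(fmts), collapse = ","),
         ")", call. = FALSE)
  dat_files <- unique(vapply(hdr$signals, `[[`, "", "file"))
  if (length(dat_files) != 1L)
    stop("multiple .dat files per record are not supported", call. = FALSE)
  dat_path <- file.path(dirname(hea_path), dat_files)
  if (!file.exists(dat_path)) stop("signal file not found: ", dat_path, call. = FALSE)
  n_int <- file.info(dat_path)$size / 2L
  raw <- readBin(dat_path, what = "integer", n = n_int, size = 2L,
                 signed = TRUE, endian = "little")
  nsig <- hdr$nsig
  if (length(raw) %% nsig != 0L)
    stop("signal file length not divisible by lead count", call. = FALSE)
  dig <- matrix(raw, ncol = nsig, byrow = TRUE)
  if (!is.na(hdr$nsamp) && hdr$nsamp > 0 && nrow(dig) != hdr$nsamp)
    stop("sample count in header (", hdr$nsamp, ") does not match .dat (",
         nrow(dig), ")", call. = FALSE)
  phys <- sapply(seq_len(nsig), function(j) {
    s <- hdr$signals[[j]]
    (dig[, j] - s$baseline) / s$gain
  })
  phys <- matrix(phys, ncol = nsig)
  descs <- vapply(hdr$signals, `[[`, "", "desc")
  if (any(!nzchar(descs))) descs[!nzchar(descs)] <-
      paste0("lead", which(!nzchar(descs)))
  ecg_recording(phys, hdr$fs, lead_names = descs, patient_id = hdr$name,
                units = vapply(hdr$signals, `[[`, "", "units"))
}

#' Write a recording as a WFDB-subset record (.hea + format-16 .dat)
#'
#' Digital values are quantized with the given ADC gain (counts per mV);
#' round-trip accuracy is therefore 1/(2*gain) mV.
#'
#' @param rec An [ecg_recording()].
#' @param path Record path without extension.
#' @param gain ADC gain in counts per physical unit (default 1000).
#' @return `path`, invisibly.
#' @export
write_wfdb_recording <- function(rec, path, gain = 1000) {
  stopifnot(inherits(rec, "ecg_recording"))
  name <- basename(path)
  nsig <- ncol(rec$signal)
  dig <- round(rec$signal * gain)
  if (any(abs(dig) > 32767))
    stop("signal exceeds int16 range at gain ", gain, call. = FALSE)
  hdr <- c(sprintf("%s %d %g %d", name, nsig, rec$fs, nrow(dig)),
           sprintf("%s.dat 16 %g(0)/mV 16 0 0 0 0 %s",
                   name, gain, rec$lead_names))
  writeLines(hdr, paste0(path, ".hea"))
  inter <- as.integer(t(dig))
  writeBin(inter, paste0(path, ".dat"), size = 2L, endian = "little")
  invisible(path)
}

# ---- delimited text ---------------------------------------------------------

read_delimited_recording <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!grepl("^#\\s*fs=", first))
    stop("delimited recording must start with '# fs=<Hz> leads=<name,...>'",
         call. = FALSE)
  fs <- suppressWarnings(as.numeric(sub("^#\\s*fs=([0-9.eE+-]+).*$", "\\1", first)))
  if (is.na(fs) || fs <= 0) stop("invalid fs in header: ", first, call. = FALSE)
  leads <- NULL
  if (grepl("leads=", first))
    leads <- strsplit(sub("^.*leads=([^ ]+).*$", "\\1", first), ",")[[1]]
  tab <- utils::read.csv(path, header = FALSE, comment.char = "#",
                         colClasses = "character")
  mat <- suppressWarnings(vapply(tab, as.numeric, numeric(nrow(tab))))
  mat <- matrix(mat, nrow = nrow(tab))
  if (anyNA(mat)) stop("non-numeric or missing cells in ", path, call. = FALSE)
  if (!is.null(leads) && length(leads) != ncol(mat))
    stop("header declares ", length(leads), " leads but file has ",
         ncol(mat), " columns", call. = FALSE)
  ecg_recording(mat, fs, lead_names = leads)
}

#' Write a recording as delimited text
#'
#' Format: first line `# fs=<Hz> leads=<name,...>`, then one CSV row per
#' sample, one column per lead, full double precision.
#'
#' @param rec An [ecg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_delimited_recording <- function(rec, path) {
  stopifnot(inherits(rec, "ecg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%s leads=%s", format(rec$fs),
                     paste(rec$lead_names, collapse = ",")), con)
  utils::write.table(format(rec$signal, digits = 15, trim = TRUE,
                            scientific = FALSE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an ECG recording
#'
#' Reads either a WFDB-subset record (single-segment `.hea` header plus
#' interleaved format-16 `.dat`, digital-to-physical conversion applied from
#' the header gain/baseline) or delimited text whose first line declares the
#' sampling rate and lead names. NaN or non-numeric samples are an error.
#'
#' @param path Path to the record (`.hea`, record stem, `.csv` or `.txt`).
#' @param format One of `"auto"`, `"wfdb"`, `"delimited"`.
#' @return An [ecg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "wfdb", "delimited")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.hea$", path) || file.exists(paste0(path, ".hea")))
      "wfdb" else "delimited"
  }
  if (format == "delimited" && !file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  switch(format,
         wfdb = read_wfdb_recording(path),
         delimited = read_delimited_recording(path))
}

#' Read beat annotations from CSV
#'
#' Expects a header row with columns `sample` and `symbol` (0-based sample
#' index; any symbol translatable through `symbol_map`). Unmapped symbols are
#' either dropped with a message (`on_unknown = "drop"`) or raise an error
#' (`"error"`). Output is always sorted strictly ascending by sample index.
#'
#' @param path CSV file path.
#' @param signal_length Optional signal length; indices beyond it are an error.
#' @param symbol_map Named character vector mapping source symbols to
#'   \{N,S,V,E\}; see [default_symbol_map()].
#' @param on_unknown `"drop"` (default) or `"error"`.
#' @return A [beat_annotations()] data.frame.
#' @export
read_annotations <- function(path, signal_length = NULL,
                             symbol_map = default_symbol_map(),
                             on_unknown = c("drop", "error")) {
  on_unknown <- match.arg(on_unknown)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "symbol") %in% names(tab)))
    stop("annotation CSV needs 'sample' and 'symbol' columns", call. = FALSE)
  mapped <- unname(symbol_map[as.character(tab$symbol)])
  unknown <- is.na(mapped)
  if (any(unknown)) {
    syms <- unique(tab$symbol[unknown])
    if (on_unknown == "error")
      stop("unmapped annotation symbols: ", paste(syms, collapse = ","),
           call. = FALSE)
    message("dropping ", sum(unknown), " annotations with unmapped symbols: ",
            paste(syms, collapse = ","))
    tab <- tab[!unknown, , drop = FALSE]
    mapped <- mapped[!unknown]
  }
  if (!is.null(signal_length) && length(tab$sample) &&
      any(tab$sample >= signal_length))
    stop("annotation sample index beyond signal length ", signal_length,
         call. = FALSE)
  beat_annotations(tab$sample, mapped)
}

#' Write beat annotations to CSV
#' @param anns A [beat_annotations()] data.frame.
#' @param path Output CSV path.
#' @return Number of annotations written, invisibly.
#' @export
write_annotations <- function(anns, path) {
  utils::write.csv(as.data.frame(anns)[, c("sample", "symbol")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(nrow(anns))
}

#' Write a feature table to CSV
#'
#' Writes homogeneous records (data.frame or list of equal-structure lists)
#' as a CSV with header, at full double precision so numeric values
#' round-trip within 1e-9.
#'
#' @param rows data.frame (or coercible) of feature records.
#' @param path Output CSV path.
#' @return Number of data rows written.
#' @export
write_feature_table <- function(rows, path) {
  if (!is.data.frame(rows)) rows <- do.call(rbind.data.frame, rows)
  df <- as.data.frame(rows)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  nrow(df)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return data.frame with numeric columns restored.
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
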