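#' Simulate a multi-patient synthetic Holter cohort
#'
#' One recording per synthetic patient, each with its own RNG stream
#' derived from `seed`. Defaults give roughly class-balanced *segment*
#' labels under the severity labelling rule: with ~12 beats per 10 s
#' window and per-beat abnormality probabilities of ~0.037 each, the
#' chance that a window contains no abnormal beat is ~25%.
#'
#' @param n_patients Number of patients.
#' @param duration Recording duration per patient, s.
#' @param fs Sampling frequency, Hz.
#' @param seed Integer master seed.
#' @param class_probs Per-beat class probabilities (named, sums to 1).
#' @param mean_hr Mean heart rate, bpm.
#' @param ... Further arguments to [sim_config()].
#' @return List of `list(recording, annotations)` with patient ids
#'   "P01", "P02", ...
#' @export
make_cohort <- function(n_patients, duration = 850, fs = 125, seed = 1,
                        class_probs = c(N = 0.89, S = 0.037, V = 0.037,
                                        E = 0.036),
                        mean_hr = 70, ...) {
  lapply(seq_len(n_patients), function(i) {
    cfg <- sim_config(fs = fs, duration = duration, mean_hr = mean_hr,
                      class_probs = class_probs,
                      seed = (seed * 1009L + i * 7919L) %% 2147483647L,
                      patient_id = sprintf("P%02d", i), ...)
    synth_recording(cfg)
  })
}

#' Preprocess and featurize a cohort into one model-ready dataset
#'
#' Runs the full front half of the pipeline per patient (bandpass filter,
#' overlapping segmentation with per-lead per-segment min-max
#' normalization, severity labelling, feature-tensor extraction) and
#' concatenates across patients.
#'
#' @param cohort Output of [make_cohort()] (or a compatible list).
#' @param window_s,overlap_frac Segmentation parameters.
#' @param f_low,f_high,order Bandpass parameters.
#' @param T Sub-windows per segment.
#' @param rule Segment labelling rule.
#' @return A `feature_tensor` with per-segment patient ids.
#' @export
build_dataset <- function(cohort, window_s = 10, overlap_frac = 0.5,
                          f_low = 0.5, f_high = 40, order = 4, T = 10,
                          rule = "severity") {
  tensors <- lapply(cohort, function(ci) {
    rec <- ci$recording
    fsp <- filter_spec(order = order, f_low = f_low, f_high = f_high,
                       fs = rec$fs)
    filt <- bandpass_filter(rec, fsp)
    segs <- suppressWarnings(
      segment_signal(filt, segmentation_spec(window_s, overlap_frac, rec$fs)))
    segs <- suppressMessages(encode_and_label(segs, ci$annotations, rule))
    extract_feature_tensor(segs, T = T)
  })
  bind_feature_tensors(tensors)
}

#' Split patients into train and test groups
#'
#' @param patient Per-segment patient ids.
#' @param test_frac Fraction of patients held out (at least 1 patient).
#' @param seed Seed for the patient draw.
#' @return List with `train_idx`, `test_idx`, `test_patients`.
#' @export
patient_holdout <- function(patient, test_frac = 0.25, seed = 1) {
  pats <- unique(patient)
  set.seed(seed)
  n_test <- max(1L, round(test_frac * length(pats)))
  test_p <- sample(pats, n_test)
  list(train_idx = which(!(patient %in% test_p)),
       test_idx = which(patient %in% test_p),
       test_patients = test_p)
}

#' End-to-end synthetic benchmark
#'
#' Simulate a cohort, preprocess, featurize, train the compact hybrid
#' model on the training patients and evaluate on held-out patients
#' (strict patient-level separation). This is the package's reference
#' experiment; all sizes are arguments.
#'
#' @param seed Master seed (cohort, split, training).
#' @param n_patients,duration,fs Cohort size parameters.
#' @param test_frac Held-out patient fraction.
#' @param max_epochs Training epochs.
#' @param config_overrides Named list of [model_config()] overrides
#'   applied on top of [small_model_config()].
#' @param dataset Optionally a pre-built dataset (skips simulation).
#' @return List: `metrics` ([compute_metrics()] report on the held-out
#'   patients), `auc` ([roc_auc_ovr()]), `model`, `split`, `dataset`,
#'   `history`.
#' @export
run_pipeline <- function(seed = 1, n_patients = 12, duration = 850,
                         fs = 125, test_frac = 0.25, max_epochs = 15,
                         config_overrides = list(), dataset = NULL) {
  if (is.null(dataset)) {
    cohort <- make_cohort(n_patients, duration = duration, fs = fs,
                          seed = seed)
    dataset <- build_dataset(cohort)
  }
  d <- dim(dataset$x)
  cfg <- do.call(small_model_config,
                 utils::modifyList(list(d_feat = d[4], T = d[2],
                                        n_leads = d[3]),
                                   config_overrides))
  split <- patient_holdout(dataset$patient, test_frac, seed)
  fit <- train_model(dataset$x[split$train_idx, , , , drop = FALSE],
                     dataset$labels[split$train_idx], cfg, seed = seed,
                     max_epochs = max_epochs,
                     label_map = dataset$label_map)
  pr <- predict(fit, dataset$x[split$test_idx, , , , drop = FALSE])
  y_te <- dataset$labels[split$test_idx]
  metrics <- compute_metrics(y_te, max.col(pr) - 1L, K = cfg$n_classes,
                             label_map = dataset$label_map)
  list(metrics = metrics, auc = roc_auc_ovr(y_te, pr), model = fit,
       split = split, dataset = dataset, history = fit$history,
       test_probs = pr, test_labels = y_te)
}

# ---- plain-text artifact serialization (CLI stage hand-off) ----------------

#' Write a segment set as text artifacts (manifest.json + data.csv)
#' @param segs A `segment_set`.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_segment_set <- function(segs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(segs$data)
  man <- list(n_seg = d[1], n_lead = d[2], n_samples = d[3], fs = segs$fs,
              stride = segs$stride, start_samples = segs$start_samples,
              labels = segs$labels, label_map = as.list(segs$label_map),
              lead_names = segs$lead_names, source_id = segs$source_id)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  flat <- matrix(aperm(segs$data, c(3, 2, 1)), ncol = d[3], byrow = TRUE)
  utils::write.table(format(flat, digits = 12, trim = TRUE),
                     file.path(dir, "data.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(dir)
}

#' Read a segment set written by [write_segment_set()]
#' @param dir Artifact directory.
#' @return A `segment_set`.
#' @export
read_segment_set <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  flat <- as.matrix(utils::read.csv(file.path(dir, "data.csv"),
                                    header = FALSE))
  data <- aperm(array(t(flat), dim = c(man$n_samples, man$n_lead,
                                       man$n_seg)), c(3, 2, 1))
  lm <- if (length(man$label_map)) unlist(man$label_map) else NULL
  structure(list(data = data, start_samples = man$start_samples,
                 labels = man$labels, label_map = lm,
                 n_samples = man$n_samples, stride = man$stride,
                 fs = man$fs, lead_names = man$lead_names,
                 source_id = man$source_id),
            class = "segment_set")
}

#' Write a feature tensor as text artifacts (manifest.json + features.csv)
#' @param ft A `feature_tensor`.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_feature_tensor <- function(ft, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(ft$x)
  man <- list(n_seg = d[1], T = d[2], n_lead = d[3], d_feat = d[4],
              fs = ft$fs, labels = ft$labels,
              label_map = as.list(ft$label_map), patient = ft$patient,
              feature_names = ft$feature_names,
              channel_names = dimnames(ft$x)[[4]])
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  idx <- expand.grid(seg = seq_len(d[1]), sub = seq_len(d[2]),
                     lead = seq_len(d[3]))
  vals <- matrix(ft$x, nrow = d[1] * d[2] * d[3], ncol = d[4])
  colnames(vals) <- dimnames(ft$x)[[4]]
  write_feature_table(cbind(idx, vals), file.path(dir, "features.csv"))
  invisible(dir)
}

#' Read a feature tensor written by [write_feature_tensor()]
#' @param dir Artifact directory.
#' @return A `feature_tensor`.
#' @export
read_feature_tensor <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  tab <- read_feature_table(file.path(dir, "features.csv"))
  ord <- order(tab$lead, tab$sub, tab$seg)
  tab <- tab[ord, , drop = FALSE]
  vals <- as.matrix(tab[, man$channel_names, drop = FALSE])
  x <- array(vals, dim = c(man$n_seg, man$T, man$n_lead, man$d_feat),
             dimnames = list(NULL, NULL, NULL, man$channel_names))
  structure(list(x = x, labels = man$labels,
                 label_map = unlist(man$label_map), patient = man$patient,
                 fs = man$fs, feature_names = man$feature_names),
            class = "feature_tensor")
}

#' Save a fitted model as a JSON checkpoint
#' @param model A `leadnet_model`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  ser_par <- lapply(model$params, function(p)
    list(dim = if (is.matrix(p)) dim(p) else length(p), values = as.numeric(p)))
  obj <- list(config = unclass(model$config),
              graph = list(n_nodes = model$graph$n_nodes,
                           strategy = model$graph$strategy,
                           mix = list(dim = dim(model$graph$mix),
                                      values = as.numeric(model$graph$mix))),
              standardize = model$standardize,
              label_map = as.list(model$label_map),
              best_epoch = model$best_epoch,
              params = ser_par)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by [write_model()]
#' @param path Checkpoint `.json` path.
#' @return A `leadnet_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  deser <- function(p) {
    if (length(p$dim) == 2) matrix(p$values, p$dim[1], p$dim[2]) else p$values
  }
  params <- lapply(obj$params, deser)
  mix <- matrix(obj$graph$mix$values, obj$graph$mix$dim[1],
                obj$graph$mix$dim[2])
  graph <- structure(list(n_nodes = obj$graph$n_nodes, adj = mix > 0,
                          mix = mix, strategy = obj$graph$strategy),
                     class = "lead_graph")
  cfg <- structure(obj$config, class = "model_config")
  structure(list(params = params, config = cfg, graph = graph,
                 standardize = obj$standardize,
                 label_map = unlist(obj$label_map),
                 history = NULL, best_epoch = obj$best_epoch),
            class = "leadnet_model")
}
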