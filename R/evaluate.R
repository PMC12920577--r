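#' Cross-validation folds
#'
#' Segment level: class-stratified round-robin assignment after a seeded
#' shuffle. Patient level: whole patients are dealt greedily (largest
#' first after a seeded shuffle) to the currently smallest fold, so no
#' patient's segments ever span folds.
#'
#' @param labels Integer class codes (used for stratification).
#' @param k Number of folds (>= 2).
#' @param level `"segment"` or `"patient"`.
#' @param patient Per-segment patient ids (required at patient level).
#' @param seed Integer seed.
#' @return List of k disjoint index vectors covering all segments, with
#'   attribute `level`.
#' @export
make_folds <- function(labels, k, level = c("segment", "patient"),
                       patient = NULL, seed = 1) {
  level <- match.arg(level)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  n <- length(labels)
  folds <- vector("list", k)
  set.seed(seed)
  if (level == "segment") {
    small <- table(labels)
    if (any(small < k))
      warning("some classes have fewer than k members; fold sizes uneven")
    fold_of <- integer(n)
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
    for (f in seq_len(k)) folds[[f]] <- which(fold_of == f)
  } else {
    if (is.null(patient) || !any(nzchar(patient)))
      stop("patient-level folds require patient ids", call. = FALSE)
    pats <- unique(patient)
    if (length(pats) < k)
      stop("fewer patients than folds", call. = FALSE)
    sizes <- table(patient)[pats]
    ord <- sample(seq_along(pats))
    pats <- pats[ord][order(-sizes[ord])]
    load <- rep(0L, k)
    assign <- stats::setNames(integer(length(pats)), pats)
    for (pt in pats) {
      f <- which.min(load)
      assign[pt] <- f
      load[f] <- load[f] + sum(patient == pt)
    }
    for (f in seq_len(k)) folds[[f]] <- which(assign[patient] == f)
  }
  attr(folds, "level") <- level
  folds
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

standardize_fit <- function(x) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1])
  list(mean = colMeans(m),
       sd = pmax(apply(m, 2, stats::sd), 1e-8))
}

standardize_apply <- function(x, st) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1])
  m <- sweep(sweep(m, 2, st$mean, "-"), 2, st$sd, "/")
  array(m, dim = d, dimnames = dimnames(x))
}

#' Train the hybrid classifier with Adam
#'
#' Minibatch Adam on the class-weighted cross-entropy, with per-feature
#' z-scoring fitted on the training split, per-epoch validation, and
#' early stopping on validation loss. The parameters from the best
#' validation epoch are returned. Fully deterministic given `seed`.
#'
#' @param x Feature array, segments x T x leads x d_feat.
#' @param y Integer class codes in \[0, K).
#' @param config A [model_config()].
#' @param graph Optional [build_lead_graph()] (default: full graph).
#' @param val_idx Indices of the validation split; default: a seeded
#'   stratified 15% of segments.
#' @param seed Integer seed (initialization, shuffling, dropout).
#' @param max_epochs Maximum epochs (default 15).
#' @param patience Early-stopping patience in epochs (default 5).
#' @param class_weights Optional length-K loss weights.
#' @param label_map Label map carried into the fitted model.
#' @param verbose Print per-epoch progress.
#' @return A `leadnet_model`: list with `params`, `config`, `graph`,
#'   `standardize`, `label_map`, `history` (per-epoch train/val loss and
#'   accuracy), `best_epoch`.
#' @export
train_model <- function(x, y, config, graph = NULL, val_idx = NULL, seed = 1,
                        max_epochs = 15, patience = 5, class_weights = NULL,
                        label_map = make_label_map(), verbose = FALSE) {
  n <- dim(x)[1]
  if (n == 0) stop("empty training set", call. = FALSE)
  if (length(y) != n) stop("labels/tensor length mismatch", call. = FALSE)
  if (is.null(graph)) graph <- build_lead_graph(config$n_leads, "full")
  set.seed(seed)
  if (is.null(val_idx)) {
    val_idx <- unlist(lapply(unique(y), function(cls) {
      idx <- which(y == cls)
      sample(idx, max(1L, round(0.15 * length(idx))))
    }))
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (!length(tr_idx)) stop("empty training split", call. = FALSE)

  st <- standardize_fit(x[tr_idx, , , , drop = FALSE])
  xs <- standardize_apply(x, st)
  params <- init_model_params(config, seed = seed)
  opt <- adam_init(params)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     train_acc = numeric(0), val_loss = numeric(0),
                     val_acc = numeric(0))
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  eval_split <- function(idx) {
    pr <- predict_probs(xs[idx, , , , drop = FALSE], graph, params, config)
    list(loss = cross_entropy_loss(pr, y[idx], class_weights),
         acc = mean(max.col(pr) - 1L == y[idx]))
  }
  for (ep in seq_len(max_epochs)) {
    ord <- sample(tr_idx)
    ep_loss <- 0; ep_n <- 0; ep_correct <- 0
    for (start in seq(1, length(ord), by = config$batch_size)) {
      bi <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      xb <- xs[bi, , , , drop = FALSE]
      fw <- model_fwd(xb, graph, params, config, mode = "train",
                      keep_cache = TRUE)
      loss <- cross_entropy_loss(fw$probs, y[bi], class_weights)
      dlog <- ce_grad_logits(fw$probs, y[bi], class_weights)
      grads <- model_bwd(dlog, xb, graph, params, config, fw$cache)
      upd <- adam_step(params, grads, opt, config$lr)
      params <- upd$params; opt <- upd$state
      ep_loss <- ep_loss + loss * length(bi)
      ep_correct <- ep_correct + sum(max.col(fw$probs) - 1L == y[bi])
      ep_n <- ep_n + length(bi)
    }
    ev <- eval_split(val_idx)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / ep_n,
                                   train_acc = ep_correct / ep_n,
                                   val_loss = ev$loss, val_acc = ev$acc))
    if (verbose)
      message(sprintf("epoch %2d  train loss %.4f acc %.3f | val loss %.4f acc %.3f",
                      ep, ep_loss / ep_n, ep_correct / ep_n, ev$loss, ev$acc))
    if (ev$loss < best$loss - 1e-9) {
      best <- list(loss = ev$loss, params = params, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  structure(list(params = best$params, config = config, graph = graph,
                 standardize = st, label_map = label_map, history = hist,
                 best_epoch = best$epoch),
            class = "leadnet_model")
}

predict_probs <- function(x, graph, params, config, chunk = 256L) {
  n <- dim(x)[1]
  out <- matrix(0, n, config$n_classes)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    out[idx, ] <- model_fwd(x[idx, , , , drop = FALSE], graph, params,
                            config, mode = "eval")$probs
  }
  out
}

#' Predict from a fitted model
#' @param object A `leadnet_model` from [train_model()].
#' @param x Feature array (raw scale; standardization is applied
#'   internally) or a `feature_tensor`.
#' @param type `"prob"` for the probability matrix, `"class"` for decoded
#'   symbols (through [decision_map()]).
#' @param thresholds Optional per-class thresholds for `type = "class"`.
#' @param ... Unused.
#' @return Probability matrix or character vector of class symbols.
#' @export
predict.leadnet_model <- function(object, x, type = c("prob", "class"),
                                  thresholds = NULL, ...) {
  type <- match.arg(type)
  if (inherits(x, "feature_tensor")) x <- x$x
  xs <- standardize_apply(x, object$standardize)
  pr <- predict_probs(xs, object$graph, object$params, object$config)
  colnames(pr) <- names(sort(object$label_map))
  if (type == "prob") return(pr)
  vapply(seq_len(nrow(pr)), function(i)
    decision_map(pr[i, ], object$label_map, thresholds)$label, "")
}

#' @export
print.leadnet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("leadnet_model: %d GNN + %d transformer layers, d_model %d, %d heads\n",
              cfg$n_gnn_layers, cfg$n_transformer_layers, cfg$d_model,
              cfg$heads))
  cat(sprintf("  trained %d epochs (best %d), final val acc %.3f\n",
              nrow(x$history), x$best_epoch,
              x$history$val_acc[nrow(x$history)]))
  invisible(x)
}

#' Full classification metric report
#'
#' Builds the K x K confusion matrix (rows = true, columns = predicted)
#' and derives, per class one-vs-rest: precision, sensitivity (recall),
#' specificity, F1, FNR (= 1 - sensitivity), FPR (= 1 - specificity);
#' plus overall accuracy and macro / micro / support-weighted aggregates.
#' A metric with a zero denominator is reported as 0 and flagged.
#'
#' @param y_true,y_pred Integer class codes in \[0, K).
#' @param K Number of classes.
#' @param label_map Optional label map for class names.
#' @return A `metrics_report` list with `confusion`, `accuracy`,
#'   `per_class` (data.frame), `macro`, `micro`, `weighted`, `flags`.
#' @export
compute_metrics <- function(y_true, y_pred, K = max(c(y_true, y_pred)) + 1L,
                            label_map = NULL) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred lengths differ", call. = FALSE)
  if (any(c(y_true, y_pred) < 0) || any(c(y_true, y_pred) >= K))
    stop("codes out of range [0, K)", call. = FALSE)
  cls <- 0:(K - 1L)
  cm <- table(factor(y_true, levels = cls), factor(y_pred, levels = cls))
  cm <- matrix(as.integer(cm), K, K)
  if (!is.null(label_map)) {
    nm <- names(sort(label_map))
    dimnames(cm) <- list(true = nm, pred = nm)
  }
  n <- length(y_true)
  acc <- sum(diag(cm)) / n
  flags <- character(0)
  safe <- function(num, den, what, cls_i) {
    if (den == 0) {
      flags <<- c(flags, sprintf("%s undefined for class %d (zero denominator)",
                                 what, cls_i))
      return(0)
    }
    num / den
  }
  per <- do.call(rbind, lapply(seq_len(K), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, -i])
    fp <- sum(cm[-i, i])
    tn <- n - tp - fn - fp
    prec <- safe(tp, tp + fp, "precision", i - 1L)
    sens <- safe(tp, tp + fn, "sensitivity", i - 1L)
    spec <- safe(tn, tn + fp, "specificity", i - 1L)
    f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else {
      flags <<- c(flags, sprintf("F1 undefined for class %d", i - 1L)); 0
    }
    data.frame(class = i - 1L, support = tp + fn, tp = tp, fn = fn, fp = fp,
               tn = tn, precision = prec, sensitivity = sens,
               specificity = spec, f1 = f1, fnr = 1 - sens, fpr = 1 - spec)
  }))
  if (!is.null(label_map)) per$symbol <- names(sort(label_map))
  w <- per$support / sum(per$support)
  agg <- function(col) c(macro = mean(per[[col]]),
                         weighted = sum(w * per[[col]]))
  micro_tp <- sum(per$tp)
  micro <- list(precision = micro_tp / sum(per$tp + per$fp),
                sensitivity = micro_tp / sum(per$tp + per$fn),
                f1 = micro_tp / sum(per$tp + (per$fp + per$fn) / 2))
  structure(list(confusion = cm, accuracy = acc, per_class = per,
                 macro = list(precision = agg("precision")[["macro"]],
                              sensitivity = agg("sensitivity")[["macro"]],
                              specificity = agg("specificity")[["macro"]],
                              f1 = agg("f1")[["macro"]]),
                 weighted = list(precision = agg("precision")[["weighted"]],
                                 sensitivity = agg("sensitivity")[["weighted"]],
                                 f1 = agg("f1")[["weighted"]]),
                 micro = micro, flags = flags, n = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report on %d samples: accuracy %.4f, macro F1 %.4f\n",
              x$n, x$accuracy, x$macro$f1))
  print(round(x$per_class[, c("class", "support", "precision", "sensitivity",
                              "specificity", "f1", "fnr", "fpr")], 4))
  invisible(x)
}

#' One-vs-rest ROC-AUC per class
#'
#' Rank-statistic (Mann-Whitney) AUC with midrank tie correction, per
#' class against the rest, plus the macro average over classes that occur
#' in `y_true`; absent classes get NA.
#'
#' @param y_true Integer class codes.
#' @param probs Batch x K probability (or score) matrix.
#' @return List with `per_class` (length-K vector) and `macro`.
#' @export
roc_auc_ovr <- function(y_true, probs) {
  probs <- as.matrix(probs)
  K <- ncol(probs)
  auc <- rep(NA_real_, K)
  for (i in seq_len(K)) {
    pos <- y_true == (i - 1L)
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) next
    r <- rank(probs[, i], ties.method = "average")
    auc[i] <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  list(per_class = auc, macro = mean(auc, na.rm = TRUE))
}

#' Paired t-test on per-fold scores
#'
#' t = mean(d) / (sd(d)/sqrt(n)) with the n-1 SD, df = n-1, two-sided p.
#' Zero-variance differences: t = +/-Inf with p = 0 (and a warning) when
#' the mean difference is nonzero, t = 0 with p = 1 when it is zero.
#'
#' @param a,b Equal-length (>= 2) score vectors, paired by fold.
#' @return List with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop("need equal-length vectors of length >= 2", call. = FALSE)
  d <- a - b
  n <- length(d)
  md <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (md == 0) return(list(t = 0, df = n - 1, p = 1, mean_diff = 0))
    warning("zero-variance differences with nonzero mean; t infinite")
    return(list(t = sign(md) * Inf, df = n - 1, p = 0, mean_diff = md))
  }
  t <- md / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1), mean_diff = md)
}

#' Temporal alert aggregation over a segment-label stream
#'
#' An alert is emitted at every segment where the run of consecutive
#' abnormal (non-N) classifications has reached at least `k` segments;
#' the run resets on any N. With k = 1 this is one alert per abnormal
#' segment. The reported class is the majority class of the current run
#' (ties broken by severity V > S > E).
#'
#' @param labels Character vector of segment class symbols.
#' @param k Consecutive-abnormal count required (>= 1).
#' @return data.frame with columns `index` (0-based segment index of the
#'   alert) and `class`.
#' @export
temporal_alert_aggregation <- function(labels, k) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  severity <- c(V = 3, S = 2, E = 1)
  run <- character(0)
  out_idx <- integer(0); out_cls <- character(0)
  for (i in seq_along(labels)) {
    if (labels[i] == "N") { run <- character(0); next }
    run <- c(run, labels[i])
    if (length(run) >= k) {
      tab <- table(run)
      cand <- names(tab)[tab == max(tab)]
      out_idx <- c(out_idx, i - 1L)
      out_cls <- c(out_cls, cand[which.max(severity[cand])])
    }
  }
  data.frame(index = out_idx, class = out_cls, stringsAsFactors = FALSE)
}

threshold_class_rates <- function(probs, labels, cls_sym, thr, label_map) {
  dec <- vapply(seq_len(nrow(probs)), function(i)
    decision_map(probs[i, ], label_map,
                 stats::setNames(thr, cls_sym))$label, "")
  truth <- decode_labels(labels, label_map)
  pos <- truth == cls_sym
  tp <- sum(dec == cls_sym & pos)
  fp <- sum(dec == cls_sym & !pos)
  list(sens = if (sum(pos)) tp / sum(pos) else NA_real_,
       fpr = if (sum(!pos)) fp / sum(!pos) else NA_real_,
       f1 = {
         fn <- sum(pos) - tp
         if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
       })
}

#' Optimize per-class decision thresholds on a validation set
#'
#' Grid scan over thresholds 0.00, 0.01, ..., 0.99 for each abnormal
#' class independently (other classes at 0). Objectives: minimize the
#' class FPR subject to sensitivity >= `target_sensitivity` (infeasible ->
#' threshold 0, flagged), or maximize the class F1. Ties prefer the
#' smaller threshold.
#'
#' @param probs Validation probability matrix (batch x K).
#' @param labels Validation integer codes.
#' @param objective `"min_fpr_at_sensitivity"` or `"max_f1"`.
#' @param target_sensitivity Sensitivity floor for the constrained
#'   objective.
#' @param label_map Label map.
#' @return Named threshold vector over the abnormal classes, with
#'   attribute `flags` naming infeasible constraints.
#' @export
optimize_thresholds <- function(probs, labels,
                                objective = c("min_fpr_at_sensitivity",
                                              "max_f1"),
                                target_sensitivity = 0.9,
                                label_map = make_label_map()) {
  objective <- match.arg(objective)
  if (!nrow(probs)) stop("empty validation set", call. = FALSE)
  grid <- seq(0, 0.99, by = 0.01)
  abn <- setdiff(names(sort(label_map)), "N")
  out <- stats::setNames(rep(0, length(abn)), abn)
  flags <- character(0)
  for (cls in abn) {
    rates <- lapply(grid, function(th)
      threshold_class_rates(probs, labels, cls, th, label_map))
    sens <- vapply(rates, `[[`, 0, "sens")
    fpr <- vapply(rates, `[[`, 0, "fpr")
    f1 <- vapply(rates, `[[`, 0, "f1")
    if (objective == "max_f1") {
      out[cls] <- grid[which.max(f1)]
    } else {
      feas <- which(!is.na(sens) & sens >= target_sensitivity)
      if (!length(feas)) {
        flags <- c(flags, sprintf("sensitivity >= %g infeasible for class %s",
                                  target_sensitivity, cls))
        out[cls] <- 0
      } else {
        best <- feas[which.min(fpr[feas])]
        out[cls] <- grid[best]
      }
    }
  }
  attr(out, "flags") <- flags
  out
}

#' Grid search over hyperparameters with cross-validation
#'
#' Trains every combination of the grid on each fold's training portion
#' and evaluates on the held-out fold. Best combination: lowest mean
#' validation cross-entropy, ties broken by higher mean accuracy, then by
#' enumeration order.
#'
#' @param x Feature array.
#' @param y Integer codes.
#' @param grid Named list of candidate vectors over [model_config()]
#'   arguments (e.g. `list(lr = c(1e-3, 1e-4), d_model = c(16, 32))`).
#' @param folds Folds from [make_folds()].
#' @param base_config Arguments shared by all candidates (named list,
#'   must include d_feat/T/n_leads).
#' @param seed Seed forwarded to training.
#' @param max_epochs Per-candidate training epochs.
#' @return List with `best_config` (a `model_config`), `results`
#'   (data.frame: one row per combination with mean val loss/accuracy).
#' @export
grid_search <- function(x, y, grid, folds, base_config, seed = 1,
                        max_epochs = 5) {
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  if (!nrow(combos)) stop("empty hyperparameter grid", call. = FALSE)
  res <- combos
  res$val_loss <- NA_real_
  res$val_acc <- NA_real_
  for (ci in seq_len(nrow(combos))) {
    args <- utils::modifyList(base_config, as.list(combos[ci, , drop = FALSE]))
    cfg <- do.call(model_config, args)
    losses <- accs <- numeric(0)
    for (f in seq_along(folds)) {
      te <- folds[[f]]
      tr <- setdiff(seq_len(dim(x)[1]), te)
      fit <- tryCatch(
        train_model(x[tr, , , , drop = FALSE], y[tr], cfg, seed = seed,
                    max_epochs = max_epochs, patience = max_epochs),
        error = function(e) e)
      if (inherits(fit, "error")) {
        losses <- c(losses, Inf); accs <- c(accs, 0)
        next
      }
      pr <- predict(fit, x[te, , , , drop = FALSE])
      losses <- c(losses, cross_entropy_loss(pr, y[te]))
      accs <- c(accs, mean(max.col(pr) - 1L == y[te]))
    }
    res$val_loss[ci] <- mean(losses)
    res$val_acc[ci] <- mean(accs)
  }
  ord <- order(res$val_loss, -res$val_acc, seq_len(nrow(res)))
  best_args <- utils::modifyList(base_config,
                                 as.list(combos[ord[1], , drop = FALSE]))
  list(best_config = do.call(model_config, best_args), results = res,
       best_index = ord[1])
}

mask_feature_groups <- function(x, keep, feature_names) {
  dn <- dimnames(x)[[4]]
  fn <- feature_names
  nonlinear <- c("apen", "sd1", "sd2")
  drop <- switch(keep,
                 time_freq = nonlinear,
                 nonlinear_only = setdiff(fn, nonlinear),
                 all = character(0))
  cols <- c(match(drop, dn), match(paste0("m_", drop), dn))
  if (length(cols)) x[, , , cols] <- 0
  x
}

#' Ablation runner
#'
#' Trains and evaluates structural variants of the hybrid model on a
#' fixed train/test split: `hybrid` (full model), `gnn_only` (transformer
#' stack replaced by temporal mean-pooling, i.e. 0 transformer layers),
#' `transformer_only` (identity lead graph: no inter-lead mixing),
#' `no_attention` (attention weights replaced by uniform averaging),
#' `no_tuning` (untuned learning rate, lr/10), `time_freq` and
#' `nonlinear_only` (feature-group masking: the excluded group's columns
#' and mask channels are zeroed).
#'
#' @param x Feature array.
#' @param y Integer codes.
#' @param train_idx,test_idx Index split.
#' @param config Base [model_config()].
#' @param variants Character vector of variant names (see above).
#' @param seed Training seed (shared, so rows are comparable).
#' @param max_epochs Training epochs.
#' @param feature_names Feature names (for the masking variants).
#' @param label_map Label map.
#' @return List with `table` (one row per variant: accuracy, macro F1)
#'   and `reports` (full `metrics_report` per variant).
#' @export
ablation_run <- function(x, y, train_idx, test_idx, config,
                         variants = c("hybrid", "gnn_only",
                                      "transformer_only"),
                         seed = 1, max_epochs = 10,
                         feature_names = NULL, label_map = make_label_map()) {
  known <- c("hybrid", "gnn_only", "transformer_only", "no_attention",
             "no_tuning", "time_freq", "nonlinear_only")
  bad <- setdiff(variants, known)
  if (length(bad)) stop("unknown ablation variants: ",
                        paste(bad, collapse = ","), call. = FALSE)
  if (is.null(feature_names)) feature_names <- feature_names()
  reports <- list()
  rows <- list()
  for (v in variants) {
    cfg <- config
    xv <- x
    graph <- NULL
    if (v == "gnn_only") cfg$n_transformer_layers <- 0L
    if (v == "transformer_only")
      graph <- build_lead_graph(cfg$n_leads, "identity")
    if (v == "no_attention") cfg$attention <- "uniform"
    if (v == "no_tuning") cfg$lr <- cfg$lr / 10
    if (v %in% c("time_freq", "nonlinear_only"))
      xv <- mask_feature_groups(x, v, feature_names)
    fit <- train_model(xv[train_idx, , , , drop = FALSE], y[train_idx], cfg,
                       graph = graph, seed = seed, max_epochs = max_epochs,
                       patience = max_epochs, label_map = label_map)
    pr <- predict(fit, xv[test_idx, , , , drop = FALSE])
    rep <- compute_metrics(y[test_idx], max.col(pr) - 1L,
                           K = cfg$n_classes, label_map = label_map)
    reports[[v]] <- rep
    rows[[v]] <- data.frame(variant = v, accuracy = rep$accuracy,
                            macro_f1 = rep$macro$f1,
                            macro_sens = rep$macro$sensitivity)
  }
  list(table = do.call(rbind, rows), reports = reports)
}
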