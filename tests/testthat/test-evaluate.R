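test_that("folds partition segments and respect patient boundaries", {
  y <- rep(0:3, each = 25)
  f <- make_folds(y, k = 5, seed = 3)
  expect_equal(sort(unlist(f)), 1:100)
  expect_true(all(vapply(f, length, 0L) == 20))

  # determinism
  f2 <- make_folds(y, k = 5, seed = 3)
  expect_identical(f, f2)

  # patient level: no patient id spans folds
  pat <- rep(c("a", "b", "c", "d"), times = c(30, 30, 20, 20))
  fp <- make_folds(y, k = 2, level = "patient", patient = pat, seed = 1)
  for (f_i in fp)
    for (pt in unique(pat[f_i]))
      expect_true(all(which(pat == pt) %in% f_i))

  expect_warning(make_folds(c(0, 0, 0, 1), k = 3, seed = 1), "fewer than k")
})

test_that("training is deterministic and learns separable features", {
  sep <- separable_tensor(n_per_class = 15, noise = 0.2, seed = 4)
  cfg <- model_config(d_feat = 6, T = 4, n_leads = 2, n_gnn_layers = 1,
                      n_transformer_layers = 1, d_model = 8, heads = 2,
                      dropout = 0, lr = 1e-2, batch_size = 16)
  fit <- train_model(sep$x, sep$y, cfg, seed = 7, max_epochs = 20,
                     patience = 20)
  expect_gte(fit$history$train_acc[nrow(fit$history)], 0.95)

  fit2 <- train_model(sep$x, sep$y, cfg, seed = 7, max_epochs = 20,
                      patience = 20)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$params, fit2$params)

  fit1 <- train_model(sep$x, sep$y, cfg, seed = 7, max_epochs = 1)
  expect_equal(nrow(fit1$history), 1L)

  expect_error(train_model(sep$x[0, , , , drop = FALSE], integer(0), cfg),
               "empty")
})

test_that("grid search enumerates combinations and rejects divergent rates", {
  sep <- separable_tensor(n_per_class = 10, noise = 0.3, seed = 5)
  folds <- make_folds(sep$y, k = 2, seed = 1)
  base <- list(d_feat = 6, T = 4, n_leads = 2, n_gnn_layers = 1,
               n_transformer_layers = 1, d_model = 8, heads = 2,
               dropout = 0)
  g1 <- grid_search(sep$x, sep$y, list(lr = 1e-3), folds, base,
                    max_epochs = 2)
  expect_equal(nrow(g1$results), 1L)
  expect_equal(g1$best_config$lr, 1e-3)

  g2 <- grid_search(sep$x, sep$y, list(lr = c(1e-3, 10), d_model = c(8, 16)),
                    folds, base, max_epochs = 2)
  expect_equal(nrow(g2$results), 4L)
  expect_equal(g2$best_config$lr, 1e-3)  # divergent eta = 10 must lose
})

test_that("metric report reproduces the binary closed forms", {
  # TP=90 FN=10 FP=5 TN=95 for the positive class (code 1)
  y_true <- c(rep(1L, 100), rep(0L, 100))
  y_pred <- c(rep(1L, 90), rep(0L, 10), rep(1L, 5), rep(0L, 95))
  m <- compute_metrics(y_true, y_pred, K = 2)
  pc <- m$per_class[m$per_class$class == 1L, ]
  expect_equal(pc$sensitivity, 0.9, tolerance = 1e-9)
  expect_equal(pc$precision, 90 / 95, tolerance = 1e-9)
  expect_equal(pc$specificity, 0.95, tolerance = 1e-9)
  expect_equal(m$accuracy, 0.925, tolerance = 1e-9)
  expect_equal(pc$f1, 2 * 0.9 * (90 / 95) / (0.9 + 90 / 95), tolerance = 1e-9)
  expect_equal(pc$fnr, 0.1, tolerance = 1e-9)
  expect_equal(pc$fpr, 0.05, tolerance = 1e-9)
})

test_that("metric identities hold on random multi-class predictions", {
  set.seed(21)
  for (i in 1:10) {
    K <- sample(3:5, 1)
    n <- 200
    y_true <- sample(0:(K - 1), n, TRUE)
    y_pred <- sample(0:(K - 1), n, TRUE)
    m <- compute_metrics(y_true, y_pred, K = K)
    # micro precision = micro recall = accuracy for single-label multi-class
    expect_equal(m$micro$precision, m$accuracy, tolerance = 1e-12)
    expect_equal(m$micro$sensitivity, m$accuracy, tolerance = 1e-12)
    # FNR + sensitivity = 1, FPR + specificity = 1, exactly
    expect_equal(m$per_class$fnr + m$per_class$sensitivity,
                 rep(1, K), tolerance = 1e-12)
    expect_equal(m$per_class$fpr + m$per_class$specificity,
                 rep(1, K), tolerance = 1e-12)
    # row sums of the confusion matrix equal class supports
    expect_equal(unname(rowSums(m$confusion)),
                 as.vector(table(factor(y_true, levels = 0:(K - 1)))))
  }
})

test_that("perfect and degenerate predictions are handled", {
  m <- compute_metrics(c(0L, 1L, 2L, 3L), c(0L, 1L, 2L, 3L), K = 4)
  expect_equal(m$accuracy, 1)
  expect_equal(m$per_class$f1, rep(1, 4))

  # class 3 absent from y_true: flagged, reported as 0
  m2 <- compute_metrics(c(0L, 1L, 2L), c(0L, 1L, 2L), K = 4)
  expect_true(any(grepl("class 3", m2$flags)))

  expect_error(compute_metrics(c(0L, 1L), c(0L), K = 2), "differ")
})

test_that("rank AUC equals brute-force pair counting", {
  # hand case: positives {0.9, 0.8}, negatives {0.7, 0.85} -> 3/4 concordant
  y <- c(1L, 1L, 0L, 0L)
  pr <- cbind(1 - c(0.9, 0.8, 0.7, 0.85), c(0.9, 0.8, 0.7, 0.85))
  expect_equal(roc_auc_ovr(y, pr)$per_class[2], 0.75)

  # perfect separation and pure ties
  expect_equal(roc_auc_ovr(c(1L, 1L, 0L, 0L),
                           cbind(0, c(0.9, 0.8, 0.2, 0.1)))$per_class[2], 1)
  expect_equal(roc_auc_ovr(c(1L, 1L, 0L, 0L),
                           cbind(0, rep(0.5, 4)))$per_class[2], 0.5)

  set.seed(31)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    y <- sample(0:1, n, TRUE)
    if (length(unique(y)) < 2) next
    s <- round(stats::runif(n), 2)  # rounded to force ties
    a <- roc_auc_ovr(y, cbind(1 - s, s))$per_class[2]
    expect_equal(a, auc_oracle(s[y == 1], s[y == 0]), tolerance = 1e-12)
  }

  expect_true(is.na(roc_auc_ovr(rep(1L, 4),
                                cbind(0, stats::runif(4)))$per_class[1]))
})

test_that("paired t-test matches the closed form", {
  r0 <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$t, 0); expect_equal(r0$p, 1)

  r <- paired_t_test(c(0.98, 0.97, 0.99), c(0.95, 0.96, 0.94))
  expect_equal(r$mean_diff, 0.03, tolerance = 1e-12)
  expect_equal(r$t, 0.03 / (0.02 / sqrt(3)), tolerance = 1e-9)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * stats::pt(-abs(r$t), 2), tolerance = 1e-12)

  rs <- paired_t_test(c(0.95, 0.96, 0.94), c(0.98, 0.97, 0.99))
  expect_equal(rs$t, -r$t, tolerance = 1e-12)
  expect_equal(rs$p, r$p, tolerance = 1e-12)

  expect_warning(ri <- paired_t_test(c(2, 3, 4), c(1, 2, 3)), "infinite")
  expect_equal(ri$p, 0)
})

test_that("temporal alert aggregation follows the consecutive rule", {
  a <- temporal_alert_aggregation(c("N", "V", "V", "N"), k = 2)
  expect_equal(nrow(a), 1L)
  expect_equal(a$index, 2L)
  expect_equal(a$class, "V")

  # k = 1: one alert per abnormal segment
  a1 <- temporal_alert_aggregation(c("N", "V", "S", "N", "E"), k = 1)
  expect_equal(a1$index, c(1L, 2L, 4L))

  expect_equal(nrow(temporal_alert_aggregation(rep("N", 10), k = 1)), 0L)
  # run resets on N
  a2 <- temporal_alert_aggregation(c("V", "N", "V", "N", "V"), k = 2)
  expect_equal(nrow(a2), 0L)
  expect_error(temporal_alert_aggregation(c("N"), k = 0), ">= 1")
})

test_that("threshold optimization respects its objectives", {
  lm <- make_label_map()
  set.seed(41)
  # well-separated validation probabilities
  n <- 60
  y <- sample(0:3, n, TRUE)
  pr <- matrix(0.05, n, 4)
  pr[cbind(1:n, y + 1)] <- 0.85
  pr <- pr / rowSums(pr)
  thr <- optimize_thresholds(pr, y, "min_fpr_at_sensitivity",
                             target_sensitivity = 1, label_map = lm)
  for (cls in names(thr)) {
    rates <- leadnet:::threshold_class_rates(pr, y, cls, thr[[cls]], lm)
    expect_equal(rates$fpr, 0)
    expect_equal(rates$sens, 1)
  }

  # zero thresholds reproduce plain argmax decisions
  dec0 <- vapply(seq_len(n), function(i)
    decision_map(pr[i, ], lm, stats::setNames(rep(0, 3),
                                              c("E", "S", "V")))$label, "")
  dec <- vapply(seq_len(n), function(i) decision_map(pr[i, ], lm)$label, "")
  expect_identical(dec0, dec)
})

test_that("ablation runner produces one comparable row per variant", {
  sep <- separable_tensor(n_per_class = 10, noise = 0.3, seed = 6)
  cfg <- model_config(d_feat = 6, T = 4, n_leads = 2, n_gnn_layers = 1,
                      n_transformer_layers = 1, d_model = 8, heads = 2,
                      dropout = 0, lr = 5e-3)
  idx <- seq_along(sep$y)
  tr <- idx[idx %% 4 != 0]; te <- idx[idx %% 4 == 0]
  fn <- feature_names()[1:6]
  ab <- ablation_run(sep$x, sep$y, tr, te, cfg, variants = c("hybrid"),
                     seed = 1, max_epochs = 3, feature_names = fn)
  expect_equal(nrow(ab$table), 1L)

  # identical seed/data reproduce the table bitwise
  ab2 <- ablation_run(sep$x, sep$y, tr, te, cfg, variants = c("hybrid"),
                      seed = 1, max_epochs = 3, feature_names = fn)
  expect_identical(ab$table, ab2$table)

  expect_error(ablation_run(sep$x, sep$y, tr, te, cfg,
                            variants = "nope", feature_names = fn),
               "unknown")
})

test_that("feature-group masking zeroes exactly the non-linear columns", {
  cfg <- sim_config(fs = 125, duration = 40, n_leads = 2, seed = 2,
                    class_probs = c(N = 0.8, S = 0.1, V = 0.1))
  sim <- synth_recording(cfg)
  segs <- segment_signal(bandpass_filter(sim$recording, filter_spec(fs = 125)),
                         segmentation_spec(10, 0.5, 125))
  segs <- encode_and_label(segs, sim$annotations)
  ft <- extract_feature_tensor(segs, T = 5)
  masked <- leadnet:::mask_feature_groups(ft$x, "time_freq", feature_names())
  nl <- c("apen", "sd1", "sd2")
  dn <- dimnames(ft$x)[[4]]
  zeroed <- c(match(nl, dn), match(paste0("m_", nl), dn))
  expect_true(all(masked[, , , zeroed] == 0))
  kept <- setdiff(seq_along(dn), zeroed)
  expect_identical(masked[, , , kept], ft$x[, , , kept])
})
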