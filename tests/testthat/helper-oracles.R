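# independent brute-force oracles used across tests

# double-loop ApEn oracle (Pincus definition, Chebyshev distance,
# self-matches included) -- deliberately naive
apen_oracle <- function(x, m, r) {
  phi <- function(m) {
    n <- length(x)
    nv <- n - m + 1
    logc <- numeric(nv)
    for (i in seq_len(nv)) {
      cnt <- 0
      for (j in seq_len(nv)) {
        dmax <- 0
        for (k in 0:(m - 1))
          dmax <- max(dmax, abs(x[i + k] - x[j + k]))
        if (dmax <= r) cnt <- cnt + 1
      }
      logc[i] <- log(cnt / nv)
    }
    mean(logc)
  }
  phi(m) - phi(m + 1)
}

# concordant-pair AUC oracle
auc_oracle <- function(scores_pos, scores_neg) {
  tot <- 0
  for (p in scores_pos) for (q in scores_neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(scores_pos) * length(scores_neg))
}

# brute-force window-start enumeration for sliding segmentation
enumerate_starts <- function(L, N, stride) {
  starts <- c()
  s <- 0
  while (s + N <= L) { starts <- c(starts, s); s <- s + stride }
  starts
}

# quick labelled separable feature tensor: class k has mean pattern k
separable_tensor <- function(n_per_class = 12, T = 4, L = 2, d = 6,
                             K = 4, noise = 0.1, seed = 1) {
  set.seed(seed)
  n <- n_per_class * K
  x <- array(stats::rnorm(n * T * L * d, sd = noise), c(n, T, L, d))
  y <- rep(0:(K - 1), each = n_per_class)
  for (k in 0:(K - 1)) {
    idx <- which(y == k)
    x[idx, , , ] <- x[idx, , , ] + k  # class-specific offset
  }
  list(x = x, y = y)
}

tiny_model_setup <- function(d_feat = 3, T = 2, n_leads = 2, d_model = 4,
                             heads = 2, seed = 1) {
  cfg <- model_config(d_feat = d_feat, T = T, n_leads = n_leads,
                      n_gnn_layers = 1, n_transformer_layers = 1,
                      d_model = d_model, heads = heads, dropout = 0.3)
  list(cfg = cfg, graph = build_lead_graph(n_leads, "full"),
       params = init_model_params(cfg, seed = seed))
}
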