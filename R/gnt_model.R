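#' Build the inter-lead graph
#'
#' Leads are nodes; edges carry the symmetric GCN normalization
#' c_vu = sqrt(deg(v) * deg(u)) with degrees counted including the
#' mandatory self-loop. Strategies: `"full"` (complete graph),
#' `"correlation"` (edge where the absolute Pearson correlation between
#' lead signals reaches `threshold`), `"identity"` (self-loops only, i.e.
#' no inter-lead mixing).
#'
#' @param n_leads Number of leads (>= 1).
#' @param strategy `"full"`, `"correlation"` or `"identity"`.
#' @param signals Samples x leads matrix, required for `"correlation"`.
#' @param threshold Absolute-correlation threshold (default 0.3).
#' @return A `lead_graph`: list with `n_nodes`, logical adjacency `adj`
#'   (self-loops TRUE), and `mix`, the normalized mixing matrix with
#'   entries 1/c_vu on edges.
#' @export
build_lead_graph <- function(n_leads, strategy = c("full", "correlation",
                                                   "identity"),
                             signals = NULL, threshold = 0.3) {
  strategy <- match.arg(strategy)
  if (n_leads < 1) stop("n_leads must be >= 1", call. = FALSE)
  adj <- switch(strategy,
    full = matrix(TRUE, n_leads, n_leads),
    identity = diag(n_leads) > 0,
    correlation = {
      if (is.null(signals)) stop("correlation strategy requires signals",
                                 call. = FALSE)
      if (ncol(signals) != n_leads)
        stop("signals must have one column per lead", call. = FALSE)
      r <- suppressWarnings(stats::cor(signals))
      r[!is.finite(r)] <- 0
      a <- abs(r) >= threshold
      diag(a) <- TRUE
      a | t(a)
    })
  deg <- rowSums(adj)
  c_vu <- sqrt(outer(deg, deg))
  mix <- ifelse(adj, 1 / c_vu, 0)
  structure(list(n_nodes = n_leads, adj = adj, mix = mix,
                 strategy = strategy), class = "lead_graph")
}

#' One graph-convolution layer over lead nodes
#'
#' h_v' = act( sum_{u in N(v)} (1/c_vu) W h_u + b ), the shared-weight GCN
#' update with the neighborhood including v itself through the self-loop.
#'
#' @param node_feats n_nodes x d_in matrix of node features.
#' @param graph A [build_lead_graph()] result.
#' @param W d_in x d_out weight matrix (shared across nodes).
#' @param b Length-d_out bias.
#' @param activation Function applied elementwise (default ReLU).
#' @return n_nodes x d_out matrix.
#' @export
graph_conv <- function(node_feats, graph, W, b = rep(0, ncol(W)),
                       activation = function(z) pmax(z, 0)) {
  node_feats <- as.matrix(node_feats)
  if (nrow(node_feats) != graph$n_nodes || ncol(node_feats) != nrow(W))
    stop("shape mismatch between node features, graph and W", call. = FALSE)
  activation(sweep(graph$mix %*% (node_feats %*% W), 2, b, "+"))
}

softmax_rows <- function(S) {
  m <- apply(S, 1, max)
  E <- exp(S - m)
  E / rowSums(E)
}

#' Scaled dot-product attention
#'
#' Attention(Q, K, V) = softmax(Q K^T / sqrt(d_k)) V. Weight rows sum to 1.
#'
#' @param Q n x d_k query matrix.
#' @param K n x d_k key matrix.
#' @param V n x d_v value matrix.
#' @return List with `output` (n x d_v) and `weights` (n x n).
#' @export
scaled_dot_attention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K) || nrow(K) != nrow(V))
    stop("dimension mismatch in attention inputs", call. = FALSE)
  if (ncol(Q) == 0) stop("d_k must be positive", call. = FALSE)
  A <- softmax_rows(Q %*% t(K) / sqrt(ncol(Q)))
  list(output = A %*% V, weights = A)
}

#' Sinusoidal positional encoding
#'
#' PE(pos, 2i) = sin(pos / 10000^(2i/d)), PE(pos, 2i+1) = cos(...), with
#' 0-based positions and column indices (standard transformer encoding).
#'
#' @param T Sequence length (>= 1).
#' @param d_model Even embedding dimension.
#' @return T x d_model matrix with entries in \[-1, 1\].
#' @export
positional_encoding <- function(T, d_model) {
  if (d_model %% 2 != 0) stop("d_model must be even", call. = FALSE)
  pos <- seq_len(T) - 1
  i <- seq_len(d_model / 2) - 1
  ang <- outer(pos, 1 / 10000^(2 * i / d_model))
  pe <- matrix(0, T, d_model)
  pe[, 2 * i + 1] <- sin(ang)
  pe[, 2 * i + 2] <- cos(ang)
  pe
}

#' Model configuration
#'
#' Full-size defaults follow the tuned configuration used throughout:
#' Adam with learning rate 1e-4, batch size 32, 3 GNN layers, 4
#' transformer layers, d_model 128, 8 heads, dropout 0.3, ReLU.
#'
#' @param d_feat Input feature channels per lead per sub-window.
#' @param T Sub-windows per segment (sequence length).
#' @param n_leads Lead count.
#' @param n_gnn_layers,n_transformer_layers Stack depths (0 allowed:
#'   0 transformer layers = temporal mean-pool only; 0 GNN layers feeds
#'   pooled raw features to the embedding).
#' @param d_model Embedding dimension (divisible by `heads`).
#' @param heads Attention head count.
#' @param dropout Dropout rate in train mode.
#' @param n_classes Output classes.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param ffn_mult Feed-forward inner-dim multiplier (4 standard).
#' @param d_hidden Classifier-head hidden width (default `d_model`).
#' @param attention `"softmax"` (default) or `"uniform"` (ablation:
#'   attention weights replaced by uniform averaging).
#' @return A `model_config` list.
#' @export
model_config <- function(d_feat, T, n_leads, n_gnn_layers = 3,
                         n_transformer_layers = 4, d_model = 128, heads = 8,
                         dropout = 0.3, n_classes = 4, lr = 1e-4,
                         batch_size = 32, ffn_mult = 4, d_hidden = NULL,
                         attention = c("softmax", "uniform")) {
  attention <- match.arg(attention)
  if (d_model %% heads != 0) stop("d_model must be divisible by heads",
                                  call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)",
                                        call. = FALSE)
  if (is.null(d_hidden)) d_hidden <- d_model
  structure(list(d_feat = d_feat, T = T, n_leads = n_leads,
                 n_gnn_layers = n_gnn_layers,
                 n_transformer_layers = n_transformer_layers,
                 d_model = d_model, heads = heads, dropout = dropout,
                 n_classes = n_classes, lr = lr, batch_size = batch_size,
                 ffn_mult = ffn_mult, d_hidden = d_hidden,
                 attention = attention),
            class = "model_config")
}

#' Scaled-down model configuration
#'
#' A compact variant for desk-scale experiments: d_model 32, one GNN and
#' one transformer layer, 4 heads, learning rate 1e-3 (a smaller model
#' trained for ~1e3 Adam steps needs a proportionally larger rate than the
#' full-size 1e-4 default).
#'
#' @inheritParams model_config
#' @param ... Overrides passed to [model_config()].
#' @return A `model_config`.
#' @export
small_model_config <- function(d_feat, T, n_leads, ...) {
  args <- utils::modifyList(
    list(d_feat = d_feat, T = T, n_leads = n_leads, n_gnn_layers = 1,
         n_transformer_layers = 1, d_model = 32, heads = 4, lr = 1e-3),
    list(...))
  do.call(model_config, args)
}

unif_init <- function(n_in, n_out, rng = TRUE) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out)
}

#' Initialize model parameters
#'
#' Fan-based scaled-uniform initialization for weights, zeros for biases,
#' ones/zeros for layer-norm gains/shifts; fully determined by `seed`.
#'
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return Flat named list of parameter arrays.
#' @export
init_model_params <- function(config, seed = 1) {
  set.seed(seed)
  cfg <- config
  p <- list()
  d_in <- cfg$d_feat
  for (l in seq_len(cfg$n_gnn_layers)) {
    p[[paste0("gnn", l, ".W")]] <- unif_init(d_in, cfg$d_model)
    p[[paste0("gnn", l, ".b")]] <- rep(0, cfg$d_model)
    d_in <- cfg$d_model
  }
  p[["embed.W"]] <- unif_init(d_in, cfg$d_model)
  p[["embed.b"]] <- rep(0, cfg$d_model)
  dm <- cfg$d_model; dff <- cfg$ffn_mult * dm
  for (l in seq_len(cfg$n_transformer_layers)) {
    pre <- paste0("tr", l, ".")
    for (nm in c("Wq", "Wk", "Wv", "Wo"))
      p[[paste0(pre, nm)]] <- unif_init(dm, dm)
    for (nm in c("bq", "bk", "bv", "bo"))
      p[[paste0(pre, nm)]] <- rep(0, dm)
    p[[paste0(pre, "ln1g")]] <- rep(1, dm)
    p[[paste0(pre, "ln1b")]] <- rep(0, dm)
    p[[paste0(pre, "W1")]] <- unif_init(dm, dff)
    p[[paste0(pre, "b1")]] <- rep(0, dff)
    p[[paste0(pre, "W2")]] <- unif_init(dff, dm)
    p[[paste0(pre, "b2")]] <- rep(0, dm)
    p[[paste0(pre, "ln2g")]] <- rep(1, dm)
    p[[paste0(pre, "ln2b")]] <- rep(0, dm)
  }
  p[["head.W"]] <- unif_init(dm, cfg$d_hidden)
  p[["head.b"]] <- rep(0, cfg$d_hidden)
  p[["out.W"]] <- unif_init(cfg$d_hidden, cfg$n_classes)
  p[["out.b"]] <- rep(0, cfg$n_classes)
  p
}

# lead mixing of a (B*T*L) x d matrix whose rows are ordered (b, t) fastest,
# lead slowest; returns the same layout with leads mixed by `mix`
mix_leads <- function(M, mix, BT, L) {
  d <- ncol(M)
  Z3 <- array(M, c(BT, L, d))
  Zp <- matrix(aperm(Z3, c(2, 1, 3)), nrow = L)
  Z3m <- aperm(array(mix %*% Zp, c(L, BT, d)), c(2, 1, 3))
  matrix(Z3m, nrow = BT * L, ncol = d)
}

ln_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(Y = sweep(sweep(xhat, 2, g, "*"), 2, b, "+"), xhat = xhat, inv = inv)
}

ln_bwd <- function(dY, cache, g) {
  dxhat <- sweep(dY, 2, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  list(dX = (dxhat - m1 - cache$xhat * m2) * cache$inv,
       dg = colSums(dY * cache$xhat), db = colSums(dY))
}

drop_mask <- function(nr, nc, p) {
  matrix(stats::rbinom(nr * nc, 1, 1 - p) / (1 - p), nr, nc)
}

# full forward pass; returns probs and (optionally) every intermediate
# needed for the manual backward pass
model_fwd <- function(x, graph, params, config, mode = "eval",
                      keep_cache = FALSE) {
  cfg <- config
  d <- dim(x)
  B <- d[1]; T <- d[2]; L <- d[3]; df <- d[4]
  if (T != cfg$T || L != cfg$n_leads || df != cfg$d_feat)
    stop("input tensor shape does not match model config", call. = FALSE)
  BT <- B * T
  train <- mode == "train" && cfg$dropout > 0
  p <- params
  cache <- list(B = B, T = T, L = L, train = train)

  # ---- GNN stack over leads, per (segment, sub-window) ----
  Hm <- matrix(x, nrow = BT * L, ncol = df)
  gnn_cache <- vector("list", cfg$n_gnn_layers)
  for (l in seq_len(cfg$n_gnn_layers)) {
    W <- p[[paste0("gnn", l, ".W")]]
    Z <- mix_leads(Hm %*% W, graph$mix, BT, L)
    pre <- sweep(Z, 2, p[[paste0("gnn", l, ".b")]], "+")
    gnn_cache[[l]] <- list(Hm = Hm, pre = pre)
    Hm <- pre * (pre > 0)
  }
  cache$gnn <- gnn_cache

  # ---- mean-pool over leads ----
  dg <- ncol(Hm)
  E0 <- matrix(0, BT, dg)
  for (l in seq_len(L)) E0 <- E0 + Hm[((l - 1) * BT + 1):(l * BT), ,
                                      drop = FALSE]
  E0 <- E0 / L
  cache$E0 <- E0

  # ---- linear embedding + positional encoding ----
  X <- sweep(E0 %*% p[["embed.W"]], 2, p[["embed.b"]], "+")
  pe <- positional_encoding(T, cfg$d_model)
  X <- X + pe[rep(seq_len(T), each = B), , drop = FALSE]
  if (train) {
    m0 <- drop_mask(nrow(X), ncol(X), cfg$dropout)
    X <- X * m0
    cache$m0 <- m0
  }

  # ---- transformer encoder stack ----
  dm <- cfg$d_model; h <- cfg$heads; dk <- dm / h
  tr_cache <- vector("list", cfg$n_transformer_layers)
  for (l in seq_len(cfg$n_transformer_layers)) {
    pre <- paste0("tr", l, ".")
    bc <- vector("list", B)
    Xnew <- X
    for (b in seq_len(B)) {
      rows <- b + B * (seq_len(T) - 1)
      Xb <- X[rows, , drop = FALSE]
      Q <- sweep(Xb %*% p[[paste0(pre, "Wq")]], 2, p[[paste0(pre, "bq")]], "+")
      K <- sweep(Xb %*% p[[paste0(pre, "Wk")]], 2, p[[paste0(pre, "bk")]], "+")
      V <- sweep(Xb %*% p[[paste0(pre, "Wv")]], 2, p[[paste0(pre, "bv")]], "+")
      O <- matrix(0, T, dm)
      As <- vector("list", h)
      for (hh in seq_len(h)) {
        cols <- ((hh - 1) * dk + 1):(hh * dk)
        A <- if (cfg$attention == "uniform") matrix(1 / T, T, T) else
          softmax_rows(Q[, cols, drop = FALSE] %*%
                         t(K[, cols, drop = FALSE]) / sqrt(dk))
        As[[hh]] <- A
        O[, cols] <- A %*% V[, cols, drop = FALSE]
      }
      O2 <- sweep(O %*% p[[paste0(pre, "Wo")]], 2, p[[paste0(pre, "bo")]], "+")
      m1 <- if (train) drop_mask(T, dm, cfg$dropout) else NULL
      O2d <- if (train) O2 * m1 else O2
      R1 <- Xb + O2d
      l1 <- ln_fwd(R1, p[[paste0(pre, "ln1g")]], p[[paste0(pre, "ln1b")]])
      Y <- l1$Y
      F1pre <- sweep(Y %*% p[[paste0(pre, "W1")]], 2, p[[paste0(pre, "b1")]], "+")
      F1 <- F1pre * (F1pre > 0)
      F2 <- sweep(F1 %*% p[[paste0(pre, "W2")]], 2, p[[paste0(pre, "b2")]], "+")
      m2 <- if (train) drop_mask(T, dm, cfg$dropout) else NULL
      F2d <- if (train) F2 * m2 else F2
      R2 <- Y + F2d
      l2 <- ln_fwd(R2, p[[paste0(pre, "ln2g")]], p[[paste0(pre, "ln2b")]])
      Xnew[rows, ] <- l2$Y
      bc[[b]] <- list(Xb = Xb, Q = Q, K = K, V = V, As = As, O = O, m1 = m1,
                      l1 = l1, Y = Y, F1pre = F1pre, F1 = F1, m2 = m2,
                      l2 = l2)
    }
    tr_cache[[l]] <- bc
    X <- Xnew
  }
  cache$tr <- tr_cache
  cache$Xfinal <- X

  # ---- mean-pool over time, classifier head ----
  hfinal <- matrix(0, B, dm)
  for (t in seq_len(T)) hfinal <- hfinal + X[(t - 1) * B + seq_len(B), ,
                                             drop = FALSE]
  hfinal <- hfinal / T
  Hpre <- sweep(hfinal %*% p[["head.W"]], 2, p[["head.b"]], "+")
  Hh <- Hpre * (Hpre > 0)
  m3 <- if (train) drop_mask(B, cfg$d_hidden, cfg$dropout) else NULL
  Hhd <- if (train) Hh * m3 else Hh
  logits <- sweep(Hhd %*% p[["out.W"]], 2, p[["out.b"]], "+")
  if (any(!is.finite(logits)))
    stop("non-finite logits in classifier head (check inputs/learning rate)",
         call. = FALSE)
  probs <- softmax_rows(logits)
  cache$hfinal <- hfinal; cache$Hpre <- Hpre; cache$Hh <- Hh
  cache$m3 <- m3; cache$Hhd <- Hhd
  list(probs = probs, cache = if (keep_cache) cache else NULL)
}

#' Forward pass of the hybrid lead-graph + transformer classifier
#'
#' Pipeline: per sub-window, GNN layers mix lead features over the lead
#' graph; lead mean-pool; linear embedding to d_model plus sinusoidal
#' positional encoding; transformer encoder blocks (multi-head attention,
#' add & layer-norm, position-wise feed-forward, add & layer-norm, dropout
#' in train mode); temporal mean-pool; ReLU fully connected layer; softmax.
#' Every output row is a probability distribution over the classes.
#'
#' @param x Input array, batch x T x leads x d_feat.
#' @param graph A [build_lead_graph()] result.
#' @param params Parameters from [init_model_params()].
#' @param config The matching [model_config()].
#' @param mode `"eval"` (default) or `"train"` (activates dropout).
#' @param seed Optional seed set before dropout draws, making train-mode
#'   forwards reproducible.
#' @return Batch x n_classes matrix of class probabilities.
#' @export
model_forward <- function(x, graph, params, config, mode = c("eval", "train"),
                          seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  model_fwd(x, graph, params, config, mode = mode)$probs
}

# backward pass: dlogits is B x K; returns flat named list of gradients
model_bwd <- function(dlogits, x, graph, params, config, cache) {
  cfg <- config
  B <- cache$B; T <- cache$T; L <- cache$L
  BT <- B * T
  dm <- cfg$d_model; h <- cfg$heads; dk <- dm / h
  p <- params
  g <- list()

  g[["out.W"]] <- t(cache$Hhd) %*% dlogits
  g[["out.b"]] <- colSums(dlogits)
  dHhd <- dlogits %*% t(p[["out.W"]])
  dHh <- if (cache$train) dHhd * cache$m3 else dHhd
  dHpre <- dHh * (cache$Hpre > 0)
  g[["head.W"]] <- t(cache$hfinal) %*% dHpre
  g[["head.b"]] <- colSums(dHpre)
  dhfinal <- dHpre %*% t(p[["head.W"]])

  dX <- matrix(0, BT, dm)
  for (t in seq_len(T)) dX[(t - 1) * B + seq_len(B), ] <- dhfinal / T

  for (l in rev(seq_len(cfg$n_transformer_layers))) {
    pre <- paste0("tr", l, ".")
    bc <- cache$tr[[l]]
    for (nm in c("Wq", "Wk", "Wv", "Wo", "W1", "W2"))
      g[[paste0(pre, nm)]] <- matrix(0, nrow(p[[paste0(pre, nm)]]),
                                     ncol(p[[paste0(pre, nm)]]))
    for (nm in c("bq", "bk", "bv", "bo", "b1", "b2", "ln1g", "ln1b",
                 "ln2g", "ln2b"))
      g[[paste0(pre, nm)]] <- rep(0, length(p[[paste0(pre, nm)]]))
    dXprev <- dX
    for (b in seq_len(B)) {
      rows <- b + B * (seq_len(T) - 1)
      cb <- bc[[b]]
      dXb_out <- dX[rows, , drop = FALSE]

      l2b <- ln_bwd(dXb_out, cb$l2, p[[paste0(pre, "ln2g")]])
      g[[paste0(pre, "ln2g")]] <- g[[paste0(pre, "ln2g")]] + l2b$dg
      g[[paste0(pre, "ln2b")]] <- g[[paste0(pre, "ln2b")]] + l2b$db
      dR2 <- l2b$dX
      dY <- dR2
      dF2 <- if (cache$train) dR2 * cb$m2 else dR2
      g[[paste0(pre, "W2")]] <- g[[paste0(pre, "W2")]] + t(cb$F1) %*% dF2
      g[[paste0(pre, "b2")]] <- g[[paste0(pre, "b2")]] + colSums(dF2)
      dF1 <- dF2 %*% t(p[[paste0(pre, "W2")]])
      dF1pre <- dF1 * (cb$F1pre > 0)
      g[[paste0(pre, "W1")]] <- g[[paste0(pre, "W1")]] + t(cb$Y) %*% dF1pre
      g[[paste0(pre, "b1")]] <- g[[paste0(pre, "b1")]] + colSums(dF1pre)
      dY <- dY + dF1pre %*% t(p[[paste0(pre, "W1")]])

      l1b <- ln_bwd(dY, cb$l1, p[[paste0(pre, "ln1g")]])
      g[[paste0(pre, "ln1g")]] <- g[[paste0(pre, "ln1g")]] + l1b$dg
      g[[paste0(pre, "ln1b")]] <- g[[paste0(pre, "ln1b")]] + l1b$db
      dR1 <- l1b$dX
      dXb <- dR1
      dO2 <- if (cache$train) dR1 * cb$m1 else dR1
      g[[paste0(pre, "Wo")]] <- g[[paste0(pre, "Wo")]] + t(cb$O) %*% dO2
      g[[paste0(pre, "bo")]] <- g[[paste0(pre, "bo")]] + colSums(dO2)
      dO <- dO2 %*% t(p[[paste0(pre, "Wo")]])

      dQ <- matrix(0, T, dm); dK <- matrix(0, T, dm); dV <- matrix(0, T, dm)
      for (hh in seq_len(h)) {
        cols <- ((hh - 1) * dk + 1):(hh * dk)
        A <- cb$As[[hh]]
        dOh <- dO[, cols, drop = FALSE]
        dV[, cols] <- t(A) %*% dOh
        if (cfg$attention == "softmax") {
          dA <- dOh %*% t(cb$V[, cols, drop = FALSE])
          dS <- A * (dA - rowSums(dA * A))
          dQ[, cols] <- dS %*% cb$K[, cols, drop = FALSE] / sqrt(dk)
          dK[, cols] <- t(dS) %*% cb$Q[, cols, drop = FALSE] / sqrt(dk)
        }
      }
      g[[paste0(pre, "Wq")]] <- g[[paste0(pre, "Wq")]] + t(cb$Xb) %*% dQ
      g[[paste0(pre, "bq")]] <- g[[paste0(pre, "bq")]] + colSums(dQ)
      g[[paste0(pre, "Wk")]] <- g[[paste0(pre, "Wk")]] + t(cb$Xb) %*% dK
      g[[paste0(pre, "bk")]] <- g[[paste0(pre, "bk")]] + colSums(dK)
      g[[paste0(pre, "Wv")]] <- g[[paste0(pre, "Wv")]] + t(cb$Xb) %*% dV
      g[[paste0(pre, "bv")]] <- g[[paste0(pre, "bv")]] + colSums(dV)
      dXb <- dXb + dQ %*% t(p[[paste0(pre, "Wq")]]) +
        dK %*% t(p[[paste0(pre, "Wk")]]) + dV %*% t(p[[paste0(pre, "Wv")]])
      dXprev[rows, ] <- dXb
    }
    dX <- dXprev
  }

  if (cache$train) dX <- dX * cache$m0
  g[["embed.W"]] <- t(cache$E0) %*% dX
  g[["embed.b"]] <- colSums(dX)
  dE0 <- dX %*% t(p[["embed.W"]])

  dg_dim <- ncol(dE0)
  dHm <- matrix(0, BT * L, dg_dim)
  for (l in seq_len(L)) dHm[((l - 1) * BT + 1):(l * BT), ] <- dE0 / L

  for (l in rev(seq_len(cfg$n_gnn_layers))) {
    gc <- cache$gnn[[l]]
    dpre <- dHm * (gc$pre > 0)
    g[[paste0("gnn", l, ".b")]] <- colSums(dpre)
    dZ <- mix_leads(dpre, graph$mix, BT, L)   # mix is symmetric
    g[[paste0("gnn", l, ".W")]] <- t(gc$Hm) %*% dZ
    dHm <- dZ %*% t(p[[paste0("gnn", l, ".W")]])
  }
  g
}

#' Cross-entropy loss (optionally class-weighted)
#'
#' Mean over the batch of -w_y * log p_y. Probabilities are clamped at
#' 1e-12 (with a warning) before the log. Doubling all class weights
#' doubles the loss: weights rescale, they are not normalized away.
#'
#' @param probs Batch x K matrix of class probabilities.
#' @param labels Integer class codes in \[0, K).
#' @param class_weights Optional length-K nonnegative weight vector
#'   (indexed by code order).
#' @return Scalar loss.
#' @export
cross_entropy_loss <- function(probs, labels, class_weights = NULL) {
  probs <- as.matrix(probs)
  K <- ncol(probs)
  if (any(labels < 0 | labels >= K)) stop("labels out of range", call. = FALSE)
  if (length(labels) != nrow(probs))
    stop("labels/probs length mismatch", call. = FALSE)
  w <- if (is.null(class_weights)) rep(1, K) else class_weights
  py <- probs[cbind(seq_len(nrow(probs)), labels + 1L)]
  if (any(py < 1e-12)) {
    warning("probabilities clamped at 1e-12 in cross-entropy")
    py <- pmax(py, 1e-12)
  }
  mean(-w[labels + 1L] * log(py))
}

ce_grad_logits <- function(probs, labels, class_weights = NULL) {
  B <- nrow(probs); K <- ncol(probs)
  w <- if (is.null(class_weights)) rep(1, K) else class_weights
  onehot <- matrix(0, B, K)
  onehot[cbind(seq_len(B), labels + 1L)] <- 1
  (probs - onehot) * w[labels + 1L] / B
}

#' Map class probabilities to a clinical decision
#'
#' Default: argmax (ties broken toward the lowest class index). With
#' per-class `thresholds`, an abnormal class is eligible only if its
#' probability reaches its threshold; among the eligible classes (N always
#' is) the most probable wins, so an under-threshold abnormal falls back
#' to N. `detected` flags any non-N decision.
#'
#' @param probs Probability vector over the classes.
#' @param label_map Label map (see [make_label_map()]); names give the
#'   class symbols in code order.
#' @param thresholds Optional named numeric vector of per-class thresholds
#'   in \[0, 1\] (classes not named get 0).
#' @return List with `label` (symbol), `detected` (logical), `confidence`
#'   (chosen class probability).
#' @export
decision_map <- function(probs, label_map = make_label_map(),
                         thresholds = NULL) {
  syms <- names(sort(label_map))
  stopifnot(length(probs) == length(syms))
  names(probs) <- syms
  thr <- stats::setNames(rep(0, length(syms)), syms)
  if (!is.null(thresholds)) {
    if (any(thresholds < 0 | thresholds > 1))
      stop("thresholds must be in [0, 1]", call. = FALSE)
    thr[names(thresholds)] <- thresholds
  }
  eligible <- syms == "N" | probs >= thr
  cand <- probs
  cand[!eligible] <- -Inf
  lab <- syms[which.max(cand)]
  list(label = lab, detected = lab != "N", confidence = unname(probs[lab]))
}
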