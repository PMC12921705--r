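# Message-passing layers, graph poolings and the optimizer used by the
# joint survival model. Everything is implemented with dense linear
# algebra and hand-derived backward passes; graphs at the working scale
# (tens to a few hundred patches) make dense per-graph N x N operators
# the simplest correct choice, and the same code path powers the
# edge-mask explainer which needs gradients with respect to the
# adjacency itself.

leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)

# --- exported, stateless layer/pooling operations (also the unit-test surface)

#' Graph convolution layer
#'
#' Symmetric-normalised neighbourhood aggregation
#' `Ahat %*% X %*% W + b` with `Ahat = D^{-1/2} (A + I) D^{-1/2}`
#' (self-loops added internally, so isolated nodes always have degree at
#' least 1), followed by an optional ReLU.
#'
#' @param features N x d node feature matrix.
#' @param edges E x 2 undirected edge list (1-based, no self-loops).
#' @param weights d x d' weight matrix.
#' @param bias optional length-d' bias.
#' @param activation apply ReLU (`TRUE` for hidden layers).
#' @return N x d' matrix.
#' @export
gcn_layer <- function(features, edges, weights, bias = NULL, activation = TRUE) {
  n <- nrow(features)
  ah <- norm_adjacency(adjacency_dense(n, edges))
  z <- ah %*% (features %*% weights)
  if (!is.null(bias)) z <- sweep(z, 2, bias, "+")
  if (activation) pmax(z, 0) else z
}

#' Graph attention layer
#'
#' Multi-head additive attention over each node's neighbourhood including
#' itself: per head, logits `e_ij = LeakyReLU(a_src . W h_i + a_dst . W h_j)`
#' are softmax-normalised over `j in N(i) u {i}` and used to average the
#' transformed neighbour features. Head outputs are concatenated
#' (`average = FALSE`, hidden layers) or averaged (`average = TRUE`).
#'
#' @param features N x d node feature matrix.
#' @param edges E x 2 undirected edge list.
#' @param weights list with `W` (d x heads*dh), `a_src`, `a_dst`
#'   (dh x heads) and optional `b`.
#' @param heads number of attention heads.
#' @param average average heads instead of concatenating.
#' @param activation apply ReLU.
#' @return N x (heads*dh) matrix (or N x dh if averaged).
#' @export
gat_layer <- function(features, edges, weights, heads = 4L, average = FALSE,
                      activation = TRUE) {
  n <- nrow(features)
  adj <- adjacency_dense(n, edges) > 0
  diag(adj) <- TRUE
  out <- gat_forward(features, adj, weights, heads)$out
  if (average) {
    dh <- ncol(out) / heads
    out <- Reduce(`+`, lapply(seq_len(heads), function(h)
      out[, ((h - 1) * dh + 1):(h * dh), drop = FALSE])) / heads
  }
  if (!is.null(weights$b) && !average) out <- sweep(out, 2, weights$b, "+")
  if (activation) pmax(out, 0) else out
}

#' Graph poolings
#'
#' Aggregate an N x d matrix of node embeddings into a single d-vector.
#' `pool_mean` and `pool_max` are element-wise; `pool_attention` is gated
#' attention (`score_i = w' tanh(V h_i)`, softmax-weighted sum);
#' `pool_kde` evaluates, per embedding dimension, a Gaussian kernel
#' density estimate of the node values at `grid_size` equally spaced
#' points spanning the dimension's range (a degenerate range collapses to
#' a delta at the constant), then linearly projects the flattened
#' d x grid density image back to d dimensions with the learned map
#' `proj`.
#'
#' @param node_embeds N x d matrix, N >= 1.
#' @param V,w gated-attention parameters (d x d matrix, length-d vector).
#' @param proj learned KDE projection, (d*grid_size) x d matrix.
#' @param grid_size number of KDE evaluation points per dimension.
#' @param bandwidth per-dimension KDE bandwidth; default Scott's rule
#'   (`sd * N^{-1/5}`) floored at 1e-3.
#' @return Length-d numeric vector.
#' @export
pool_mean <- function(node_embeds) {
  check_nonempty(node_embeds)
  colMeans(node_embeds)
}

#' @rdname pool_mean
#' @export
pool_max <- function(node_embeds) {
  check_nonempty(node_embeds)
  apply(node_embeds, 2, max)
}

#' @rdname pool_mean
#' @export
pool_attention <- function(node_embeds, V, w) {
  check_nonempty(node_embeds)
  attention_pool_forward(node_embeds, V, w)$g
}

#' @rdname pool_mean
#' @export
pool_kde <- function(node_embeds, proj, grid_size = 16L, bandwidth = NULL) {
  check_nonempty(node_embeds)
  kde_pool_forward(node_embeds, proj, grid_size, bandwidth)$g
}

check_nonempty <- function(x) {
  if (is.null(dim(x)) || nrow(x) < 1) gs_error("cannot pool an empty graph",
                                               "empty_graph_error")
}

#' Per-dimension Gaussian KDE densities on a grid
#'
#' The raw (unnormalised) mixture densities underlying [pool_kde()]:
#' `u_t = mean_i dnorm((g_t - v_i) / b) / b` per dimension. Exposed so the
#' density stage can be checked directly against a hand-summed Gaussian
#' mixture.
#'
#' @param values N x d matrix (or vector) of node values.
#' @param grid_size evaluation points per dimension.
#' @param bandwidth per-dimension bandwidth (recycled); default Scott's
#'   rule floored at 1e-3.
#' @return List with `grid` (grid_size x d) and `density` (grid_size x d).
#' @export
kde_density <- function(values, grid_size = 16L, bandwidth = NULL) {
  v <- as.matrix(values)
  fw <- kde_pool_forward(v, proj = NULL, grid_size, bandwidth)
  list(grid = fw$grid, density = matrix(fw$u, grid_size, ncol(v)))
}

# --- dense adjacency helpers ----------------------------------------------

adjacency_dense <- function(n, edges, weights = NULL) {
  a <- matrix(0, n, n)
  if (length(edges)) {
    w <- if (is.null(weights)) 1 else weights
    a[edges] <- w
    a[edges[, c(2, 1), drop = FALSE]] <- w
  }
  a
}

# Ahat = D^{-1/2} (A + I) D^{-1/2}; returns the operator plus pieces the
# explainer's adjacency gradient needs
norm_adjacency <- function(a, pieces = FALSE) {
  m <- a
  diag(m) <- diag(m) + 1
  d <- rowSums(m)
  inv <- 1 / sqrt(d)
  ah <- m * outer(inv, inv)
  if (pieces) list(ah = ah, m = m, d = d) else ah
}

# --- internal forward/backward blocks -------------------------------------

gcn_forward_block <- function(ah, H, W, b, act) {
  M <- H %*% W
  Z <- ah %*% M
  Z <- sweep(Z, 2, b, "+")
  out <- if (act) pmax(Z, 0) else Z
  list(out = out, H = H, M = M, Z = Z, act = act)
}

# multi-head GAT forward on a dense neighbourhood mask (incl. self).
# Wm, if given, is a dense edge-mask matrix (1 on the diagonal) applied
# multiplicatively to the softmax-normalised attention coefficients
# without renormalisation (message masking).
gat_forward <- function(H, adj, weights, heads, Wm = NULL) {
  n <- nrow(H)
  dh <- ncol(weights$W) / heads
  out <- matrix(0, n, ncol(weights$W))
  hc <- vector("list", heads)
  for (h in seq_len(heads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    M <- H %*% weights$W[, idx, drop = FALSE]
    sv <- drop(M %*% weights$a_src[, h])
    tv <- drop(M %*% weights$a_dst[, h])
    Epre <- matrix(sv, n, n) + matrix(tv, n, n, byrow = TRUE)
    E <- leaky_relu(Epre)
    E[!adj] <- -Inf
    E <- E - apply(E, 1, max)
    P <- exp(E)
    P <- P / rowSums(P)
    Pm <- if (is.null(Wm)) P else P * Wm
    out[, idx] <- Pm %*% M
    hc[[h]] <- list(M = M, P = P, Pm = Pm, Epre = Epre, idx = idx)
  }
  list(out = out, heads = hc, H = H)
}

gat_backward <- function(cache, adj, weights, heads, dout, Wm = NULL,
                         want_mask_grad = FALSE) {
  H <- cache$H
  n <- nrow(H)
  dW <- matrix(0, nrow(weights$W), ncol(weights$W))
  da_src <- matrix(0, nrow(weights$a_src), heads)
  da_dst <- matrix(0, nrow(weights$a_dst), heads)
  dH <- matrix(0, n, ncol(H))
  dWm <- if (want_mask_grad) matrix(0, n, n) else NULL
  for (h in seq_len(heads)) {
    hc <- cache$heads[[h]]
    dOh <- dout[, hc$idx, drop = FALSE]
    P <- hc$P; M <- hc$M
    dPm <- dOh %*% t(M)
    dM <- t(hc$Pm) %*% dOh
    if (want_mask_grad) dWm <- dWm + dPm * P
    dP <- if (is.null(Wm)) dPm else dPm * Wm
    dE <- P * (dP - rowSums(P * dP))    # softmax backward, zero off-mask
    dEpre <- dE * ifelse(hc$Epre > 0, 1, 0.2)
    ds <- rowSums(dEpre)
    dt <- colSums(dEpre)
    dM <- dM + outer(ds, weights$a_src[, h]) + outer(dt, weights$a_dst[, h])
    da_src[, h] <- drop(crossprod(M, ds))
    da_dst[, h] <- drop(crossprod(M, dt))
    dW[, hc$idx] <- crossprod(H, dM)
    dH <- dH + dM %*% t(weights$W[, hc$idx, drop = FALSE])
  }
  list(dW = dW, da_src = da_src, da_dst = da_dst, dH = dH, dWm = dWm)
}

attention_pool_forward <- function(H, V, w) {
  a <- tanh(H %*% V)
  u <- drop(a %*% w)
  u <- u - max(u)
  al <- exp(u) / sum(exp(u))
  list(g = drop(crossprod(H, al)), a = a, al = al, H = H)
}

attention_pool_backward <- function(cache, V, w, dg) {
  H <- cache$H; a <- cache$a; al <- cache$al
  dal <- drop(H %*% dg)
  dH <- tcrossprod(al, dg)              # N x d: al_i * dg
  du <- al * (dal - sum(al * dal))
  dpre <- (du %o% w) * (1 - a^2)        # N x d
  dV <- crossprod(H, dpre)
  dw <- drop(crossprod(a, du))
  dH <- dH + dpre %*% t(V)
  list(dH = dH, dV = dV, dw = dw)
}

kde_pool_forward <- function(H, proj, grid_size, bandwidth = NULL) {
  n <- nrow(H); D <- ncol(H); G <- grid_size
  imin <- max.col(-t(H), ties.method = "first")
  imax <- max.col(t(H), ties.method = "first")
  lo <- H[cbind(imin, seq_len(D))]
  hi <- H[cbind(imax, seq_len(D))]
  span <- hi - lo
  degen <- span < 1e-12
  scott <- is.null(bandwidth)
  if (scott) {
    sdv <- if (n > 1) {
      mu <- colMeans(H)
      sqrt(pmax(colSums(H * H) - n * mu^2, 0) / (n - 1))
    } else rep(0, D)
    bw <- pmax(sdv * n^(-1 / 5), 1e-3)
    floored <- sdv * n^(-1 / 5) <= 1e-3
  } else {
    bw <- rep(bandwidth, length.out = D)
    floored <- rep(TRUE, D)       # fixed bandwidth: no gradient through bw
  }
  grid <- matrix(lo, G, D, byrow = TRUE) +
    outer(seq(0, 1, length.out = G), span)
  Grep <- matrix(as.vector(grid), n, G * D, byrow = TRUE)
  Vrep <- H[, rep(seq_len(D), each = G), drop = FALSE]
  Brep <- rep(bw, each = G)
  Z <- (Grep - Vrep) / matrix(Brep, n, G * D, byrow = TRUE)
  Phi <- dnorm(Z)
  u <- colMeans(Phi) / Brep
  if (any(degen)) {
    # degenerate span: delta at the constant
    u[rep(degen, each = G)] <- rep(c(1, numeric(G - 1)), sum(degen))
  }
  g <- if (is.null(proj)) NULL else drop(u %*% proj)
  list(g = g, u = u, Z = Z, Phi = Phi, bw = bw, grid = grid, H = H,
       degen = degen, imin = imin, imax = imax, floored = floored,
       n = n, D = D, G = G)
}

# full gradient: direct kernel term plus the chains through the
# data-dependent grid endpoints (min/max nodes) and the Scott bandwidth
kde_pool_backward <- function(cache, proj, dg) {
  G <- cache$G; D <- cache$D; n <- cache$n
  dproj <- outer(cache$u, dg)
  du <- drop(proj %*% dg)
  live <- !rep(cache$degen, each = G)
  du[!live] <- 0
  Brep <- rep(cache$bw, each = G)
  ZPhi <- cache$Z * cache$Phi
  # direct: du/dv_i = z_ti phi(z_ti) / (n b^2)
  colscale <- du / (n * Brep^2)
  dV <- ZPhi * matrix(colscale, n, G * D, byrow = TRUE)
  dH <- t(rowsum(t(dV), rep(seq_len(D), each = G)))
  # grid chain: du/dg_t = -sum_i z phi / (n b^2)
  A <- colSums(ZPhi)
  dgg <- du * (-A) / (n * Brep^2)
  f <- rep(seq(0, 1, length.out = G), D)
  dlo <- colSums(matrix(dgg * (1 - f), G, D))
  dhi <- colSums(matrix(dgg * f, G, D))
  for (j in which(!cache$degen)) {
    dH[cache$imin[j], j] <- dH[cache$imin[j], j] + dlo[j]
    dH[cache$imax[j], j] <- dH[cache$imax[j], j] + dhi[j]
  }
  # bandwidth chain (Scott's rule): du/db = -u/b + sum_i z^2 phi / (n b^2)
  if (n > 1) {
    B <- colSums(cache$Z * ZPhi)
    dub <- du * (-cache$u / Brep + B / (n * Brep^2))
    db <- colSums(matrix(dub, G, D))
    live_bw <- which(!cache$floored & !cache$degen)
    if (length(live_bw)) {
      Hl <- cache$H[, live_bw, drop = FALSE]
      Hc <- Hl - matrix(colMeans(Hl), n, length(live_bw), byrow = TRUE)
      sdv <- cache$bw[live_bw] / n^(-1 / 5)
      sc <- db[live_bw] * n^(-1 / 5) / ((n - 1) * sdv)
      dH[, live_bw] <- dH[, live_bw] + Hc * matrix(sc, n, length(live_bw),
                                                   byrow = TRUE)
    }
  }
  list(dH = dH, dproj = dproj)
}

# --- parameter initialisation and the full model pass ----------------------

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

init_params <- function(bcfg, input_dim) {
  dims <- c(input_dim, bcfg$hidden_dims)
  p <- list()
  for (l in seq_along(bcfg$hidden_dims)) {
    if (bcfg$arch == "gcn") {
      p[[paste0("W", l)]] <- glorot(dims[l], dims[l + 1])
      p[[paste0("b", l)]] <- numeric(dims[l + 1])
    } else {
      dh <- dims[l + 1] %/% bcfg$gat_heads
      p[[paste0("W", l)]] <- glorot(dims[l], dh * bcfg$gat_heads)
      p[[paste0("asrc", l)]] <- matrix(runif(dh * bcfg$gat_heads, -0.1, 0.1),
                                       dh, bcfg$gat_heads)
      p[[paste0("adst", l)]] <- matrix(runif(dh * bcfg$gat_heads, -0.1, 0.1),
                                       dh, bcfg$gat_heads)
      p[[paste0("b", l)]] <- numeric(dh * bcfg$gat_heads)
    }
  }
  last <- dims[length(dims)]
  p$Wn <- glorot(last, bcfg$embed_dim)
  p$bn <- numeric(bcfg$embed_dim)
  if (bcfg$pooling == "attention") {
    p$Va <- glorot(bcfg$embed_dim, bcfg$embed_dim)
    p$wa <- runif(bcfg$embed_dim, -0.1, 0.1)
  } else if (bcfg$pooling == "kde") {
    p$Pk <- glorot(bcfg$embed_dim * bcfg$kde_grid, bcfg$embed_dim)
  }
  p$beta <- numeric(bcfg$embed_dim)
  p
}

# precompute fixed per-graph operators
prep_graph <- function(graph) {
  n <- nrow(graph$features)
  a <- adjacency_dense(n, graph$edges)
  adj <- a > 0
  diag(adj) <- TRUE
  list(X = graph$features, edges = graph$edges, n = n,
       norm = norm_adjacency(a, pieces = TRUE), adj = adj)
}

# full forward pass for one graph. edge_weights (explainer) soft-masks
# the per-edge messages with the normalisation held fixed: the
# aggregation operator entries (or attention coefficients) are
# multiplied by the mask without recomputing degrees or softmax, so a
# fully masked edge really removes its message. Dropout masks must be
# supplied (train).
model_forward <- function(params, bcfg, gp, dropmasks = NULL, edge_weights = NULL) {
  nl <- length(bcfg$hidden_dims)
  norm <- gp$norm
  Wm <- NULL
  ah <- norm$ah
  if (!is.null(edge_weights) && length(gp$edges)) {
    Wm <- matrix(1, gp$n, gp$n)
    Wm[gp$edges] <- edge_weights
    Wm[gp$edges[, c(2, 1), drop = FALSE]] <- edge_weights
    ah <- norm$ah * Wm
  }
  H <- gp$X
  layers <- vector("list", nl)
  for (l in seq_len(nl)) {
    if (bcfg$arch == "gcn") {
      cc <- gcn_forward_block(ah, H, params[[paste0("W", l)]],
                              params[[paste0("b", l)]], act = TRUE)
      attr(cc, "W") <- params[[paste0("W", l)]]
    } else {
      wts <- list(W = params[[paste0("W", l)]],
                  a_src = params[[paste0("asrc", l)]],
                  a_dst = params[[paste0("adst", l)]])
      fw <- gat_forward(H, gp$adj, wts, bcfg$gat_heads, Wm = Wm)
      z <- sweep(fw$out, 2, params[[paste0("b", l)]], "+")
      cc <- list(gat = fw, Z = z, out = pmax(z, 0))
    }
    H <- cc$out
    if (!is.null(dropmasks)) {
      H <- H * dropmasks[[l]]
      cc$mask <- dropmasks[[l]]
    }
    cc$Hout <- H
    layers[[l]] <- cc
  }
  Hn <- sweep(H %*% params$Wn, 2, params$bn, "+")
  pool <- switch(bcfg$pooling,
    mean = list(g = colMeans(Hn)),
    max = {
      amax <- apply(Hn, 2, which.max)
      list(g = Hn[cbind(amax, seq_len(ncol(Hn)))], amax = amax)
    },
    attention = attention_pool_forward(Hn, params$Va, params$wa),
    kde = kde_pool_forward(Hn, params$Pk, bcfg$kde_grid, bcfg$kde_bandwidth)
  )
  risk <- sum(pool$g * params$beta)
  list(risk = risk, g = pool$g, layers = layers, Hn = Hn, Hlast = H,
       pool = pool, norm = norm, ah = ah, Wm = Wm)
}

# backward pass; returns parameter gradients (same names as params) and,
# if requested, the gradient with respect to the per-edge mask weights
model_backward <- function(params, bcfg, gp, fw, drisk, want_edge_grad = FALSE,
                           edge_weights = NULL) {
  nl <- length(bcfg$hidden_dims)
  gr <- list(beta = drisk * fw$g)
  dg <- drisk * params$beta
  n <- gp$n
  pool <- fw$pool
  dHn <- switch(bcfg$pooling,
    mean = matrix(dg, n, length(dg), byrow = TRUE) / n,
    max = {
      m <- matrix(0, n, length(dg))
      m[cbind(pool$amax, seq_along(dg))] <- dg
      m
    },
    attention = {
      bk <- attention_pool_backward(pool, params$Va, params$wa, dg)
      gr$Va <- bk$dV; gr$wa <- bk$dw
      bk$dH
    },
    kde = {
      bk <- kde_pool_backward(pool, params$Pk, dg)
      gr$Pk <- bk$dproj
      bk$dH
    })
  gr$Wn <- crossprod(fw$Hlast, dHn)
  gr$bn <- colSums(dHn)
  dH <- dHn %*% t(params$Wn)
  dah <- if (want_edge_grad) matrix(0, n, n) else NULL
  dWm <- if (want_edge_grad) matrix(0, n, n) else NULL
  for (l in rev(seq_len(nl))) {
    cc <- fw$layers[[l]]
    if (!is.null(cc$mask)) dH <- dH * cc$mask
    if (bcfg$arch == "gcn") {
      dZ <- dH * (cc$Z > 0)
      gr[[paste0("b", l)]] <- colSums(dZ)
      dM <- fw$ah %*% dZ
      gr[[paste0("W", l)]] <- crossprod(cc$H, dM)
      dH <- dM %*% t(attr(cc, "W"))
      if (want_edge_grad) dah <- dah + dZ %*% t(cc$M)
    } else {
      dZ <- dH * (cc$Z > 0)
      gr[[paste0("b", l)]] <- colSums(dZ)
      wts <- list(W = params[[paste0("W", l)]],
                  a_src = params[[paste0("asrc", l)]],
                  a_dst = params[[paste0("adst", l)]])
      bk <- gat_backward(cc$gat, gp$adj, wts, bcfg$gat_heads, dZ,
                         Wm = fw$Wm, want_mask_grad = want_edge_grad)
      gr[[paste0("W", l)]] <- bk$dW
      gr[[paste0("asrc", l)]] <- bk$da_src
      gr[[paste0("adst", l)]] <- bk$da_dst
      dH <- bk$dH
      if (want_edge_grad) dWm <- dWm + bk$dWm
    }
  }
  if (want_edge_grad && length(gp$edges)) {
    e <- gp$edges
    if (bcfg$arch == "gcn") {
      # message masking: d(ah * Wm)_ij / d w_e = ah_ij (normalisation fixed)
      dmask <- dah * gp$norm$ah
      gr$edge <- dmask[e] + dmask[e[, c(2, 1), drop = FALSE]]
    } else {
      gr$edge <- dWm[e] + dWm[e[, c(2, 1), drop = FALSE]]
    }
  }
  gr
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0 && !startsWith(nm, "b")) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
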