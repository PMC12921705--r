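test_that("graph convolution matches the dense normalised-adjacency oracle", {
  # 3-node path graph, hand-set weights
  X <- rbind(c(1, 0), c(0, 1), c(2, -1))
  edges <- rbind(c(1L, 2L), c(2L, 3L))
  W <- rbind(c(0.5, -1), c(0.25, 2))
  A <- matrix(0, 3, 3)
  A[cbind(edges[, 1], edges[, 2])] <- 1
  A <- A + t(A); diag(A) <- 1
  d <- rowSums(A)
  ahat <- A / sqrt(outer(d, d))
  expect_equal(gcn_layer(X, edges, W, activation = FALSE), ahat %*% X %*% W)
  expect_equal(gcn_layer(X, edges, W), pmax(ahat %*% X %*% W, 0))
})

test_that("graph convolution handles degenerate graphs via self-loops", {
  # single node: Ahat = 1, identity weights -> ReLU(input)
  X <- matrix(c(2, -3), 1, 2)
  expect_equal(gcn_layer(X, matrix(integer(0), 0, 2), diag(2)),
               pmax(X, 0))
  # two connected nodes with equal features get equal outputs
  X2 <- rbind(c(1, 2), c(1, 2))
  out <- gcn_layer(X2, rbind(c(1L, 2L)), matrix(rnorm(4), 2, 2))
  expect_equal(out[1, ], out[2, ])
})

test_that("graph attention reduces to neighbourhood mean for constant logits", {
  set.seed(19)
  X <- matrix(rnorm(8), 4, 2)
  edges <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L))
  W <- diag(2)
  wts <- list(W = W, a_src = matrix(0, 2, 1), a_dst = matrix(0, 2, 1))
  out <- gat_layer(X, edges, wts, heads = 1, activation = FALSE)
  # zero attention vectors -> uniform weights over N(i) u {i}
  expect_equal(out[1, ], colMeans(X[c(1, 2), ]))
  expect_equal(out[2, ], colMeans(X[1:3, ]))
  # single node: self-attention weight 1
  single <- gat_layer(X[1, , drop = FALSE], matrix(integer(0), 0, 2), wts,
                      heads = 1, activation = FALSE)
  expect_equal(single[1, ], X[1, ])
})

test_that("graph attention star matches a dense softmax oracle", {
  X <- rbind(c(1, 0), c(0, 1), c(1, 1))     # star: 1-2, 1-3
  edges <- rbind(c(1L, 2L), c(1L, 3L))
  W <- rbind(c(0.8, -0.3), c(0.1, 0.6))
  a_s <- matrix(c(0.5, -0.2), 2, 1)
  a_d <- matrix(c(0.3, 0.4), 2, 1)
  out <- gat_layer(X, edges, list(W = W, a_src = a_s, a_dst = a_d),
                   heads = 1, activation = FALSE)
  M <- X %*% W
  s <- drop(M %*% a_s); t <- drop(M %*% a_d)
  lk <- function(x) ifelse(x > 0, x, 0.2 * x)
  e1 <- lk(s[1] + t[1:3])                  # node 1 attends {1,2,3}
  a1 <- exp(e1 - max(e1)); a1 <- a1 / sum(a1)
  expect_equal(out[1, ], drop(a1 %*% M))
  e2 <- lk(s[2] + t[c(1, 2)])              # node 2 attends {1,2}
  a2 <- exp(e2 - max(e2)); a2 <- a2 / sum(a2)
  expect_equal(out[2, ], drop(a2 %*% M[c(1, 2), ]))
})

test_that("mean and max pooling match column-wise oracles", {
  set.seed(30)
  H <- matrix(rnorm(640), 10, 64)
  expect_equal(pool_mean(H), colMeans(H))
  expect_equal(pool_max(H), apply(H, 2, max))
  one <- H[3, , drop = FALSE]
  expect_equal(pool_mean(one), H[3, ])
  expect_equal(pool_max(one), H[3, ])
  expect_equal(pool_mean(rbind(H[1, ], -H[1, ])), numeric(64))
})

test_that("gated attention pooling is a softmax convex combination", {
  set.seed(31)
  V <- matrix(rnorm(16), 4, 4); w <- rnorm(4)
  # identical embeddings: output equals the shared embedding
  H <- matrix(rep(c(1, -2, 0.5, 3), each = 5), 5, 4)
  expect_equal(pool_attention(H, V, w), c(1, -2, 0.5, 3))
  # hand-computed combination
  H2 <- matrix(rnorm(12), 3, 4)
  sc <- drop(tanh(H2 %*% V) %*% w)
  al <- exp(sc - max(sc)); al <- al / sum(al)
  expect_equal(pool_attention(H2, V, w), drop(al %*% H2))
  # forcing one score to dominate recovers that node's embedding
  sc2 <- sc; sc2[2] <- sc2[2] + 1e4
  expect_equal(drop((exp(sc2 - max(sc2)) / sum(exp(sc2 - max(sc2)))) %*% H2),
               H2[2, ])
})

test_that("KDE pooling densities match a hand-summed Gaussian mixture", {
  # 5 nodes, 2 dims, grid 4, unit bandwidth
  H <- cbind(c(0, 1, 2, 3, 4), c(-1, 0, 0, 0, 1))
  kd <- kde_density(H, grid_size = 4, bandwidth = 1)
  for (j in 1:2) {
    grid <- seq(min(H[, j]), max(H[, j]), length.out = 4)
    for (t in 1:4) {
      expect_equal(kd$density[t, j], mean(dnorm(grid[t] - H[, j])),
                   tolerance = 1e-12)
    }
  }
  # projection stage: linear in the flattened density image
  proj <- matrix(rnorm(8 * 2), 8, 2)
  expect_equal(pool_kde(H, proj, grid_size = 4, bandwidth = 1),
               drop(as.vector(kd$density) %*% proj))
})

test_that("KDE pooling of identical nodes equals the single-node case", {
  proj <- matrix(rnorm(4 * 3 * 3), 12, 3)
  one <- matrix(c(2, -1, 0.5), 1, 3)
  rep5 <- one[rep(1, 5), ]
  expect_equal(pool_kde(one, proj, grid_size = 4),
               pool_kde(rep5, proj, grid_size = 4))
})

test_that("pooled embeddings are invariant to node permutation", {
  set.seed(55)
  g <- build_knn_graph(matrix(rnorm(20 * 6), 20, 6),
                       matrix(runif(40), 20, 2), k = 3)
  for (pool in c("mean", "max", "attention", "kde")) {
    bcfg <- tiny_backbone(pooling = pool)
    set.seed(77)
    params <- gnnsurv:::init_params(bcfg, 6)
    gp <- gnnsurv:::prep_graph(g)
    g0 <- gnnsurv:::model_forward(params, bcfg, gp)$g
    perm <- sample(20)
    inv <- order(perm)
    g2 <- g
    g2$features <- g$features[perm, ]
    g2$coords <- g$coords[perm, ]
    e <- matrix(inv[g$edges], ncol = 2)
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    g2$edges <- e[order(e[, 1], e[, 2]), ]
    gp2 <- gnnsurv:::prep_graph(g2)
    g1 <- gnnsurv:::model_forward(params, bcfg, gp2)$g
    expect_equal(g1, g0, tolerance = 1e-5)
  }
})

test_that("model gradients match finite differences for every arch/pooling", {
  set.seed(7)
  n <- 7; d <- 6
  g <- build_knn_graph(matrix(rnorm(n * d), n, d),
                       matrix(runif(n * 2), n, 2), k = 2)
  gp <- gnnsurv:::prep_graph(g)
  for (arch in c("gcn", "gat")) {
    for (pool in c("mean", "attention", "kde")) {
      bcfg <- tiny_backbone(arch = arch, pooling = pool)
      set.seed(11)
      params <- gnnsurv:::init_params(bcfg, d)
      params$beta <- rnorm(8)
      fw <- gnnsurv:::model_forward(params, bcfg, gp)
      gr <- gnnsurv:::model_backward(params, bcfg, gp, fw, 1.0)
      for (nm in names(params)) {
        idx <- seq_along(params[[nm]])
        if (length(idx) > 6) idx <- sample(idx, 6)
        for (i in idx) {
          h <- 1e-5
          pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
          r1 <- gnnsurv:::model_forward(pp, bcfg, gp)$risk
          pp[[nm]][i] <- pp[[nm]][i] - 2 * h
          r2 <- gnnsurv:::model_forward(pp, bcfg, gp)$risk
          fd <- (r1 - r2) / (2 * h)
          expect_lt(abs(fd - gr[[nm]][i]) / max(1e-4, abs(fd) + abs(gr[[nm]][i])),
                    1e-3)
        }
      }
    }
  }
})

test_that("empty graphs cannot be pooled", {
  expect_error(pool_mean(matrix(numeric(0), 0, 4)), class = "empty_graph_error")
  expect_error(pool_max(matrix(numeric(0), 0, 4)), class = "empty_graph_error")
})
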