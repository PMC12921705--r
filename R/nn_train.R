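# Batched full-batch trainer. All graphs are stacked into one node
# matrix so every dense transform (the dominant cost: 512 -> 256 -> 128
# -> 64 maps) is a single BLAS call per epoch, while the per-graph
# operators (normalised adjacency, attention, pooling) run block-wise on
# the small per-graph slices. Produces exactly the same model family as
# the per-graph path in nn.R (which remains the reference implementation
# for inference, explanation and the gradient tests).

# KDE pooling evaluated jointly for all graphs: one dnorm call over the
# stacked rows instead of per-graph temporaries. Same mathematics as
# kde_pool_forward/kde_pool_backward.
kde_batch_forward <- function(Hn, rows, grp, ngv, proj, G, bandwidth) {
  ng <- length(rows); D <- ncol(Hn); N <- nrow(Hn)
  f <- seq(0, 1, length.out = G)
  LO <- HI <- BW <- matrix(0, ng, D)
  IMIN <- IMAX <- matrix(0L, ng, D)
  DEGEN <- FLOORED <- matrix(FALSE, ng, D)
  for (g in seq_len(ng)) {
    Hg <- Hn[rows[[g]], , drop = FALSE]
    im <- max.col(-t(Hg), ties.method = "first")
    ix <- max.col(t(Hg), ties.method = "first")
    IMIN[g, ] <- rows[[g]][im]
    IMAX[g, ] <- rows[[g]][ix]
    LO[g, ] <- Hg[cbind(im, seq_len(D))]
    HI[g, ] <- Hg[cbind(ix, seq_len(D))]
    DEGEN[g, ] <- (HI[g, ] - LO[g, ]) < 1e-12
    n_g <- ngv[g]
    if (is.null(bandwidth)) {
      sdv <- if (n_g > 1) {
        mu <- colMeans(Hg)
        sqrt(pmax(colSums(Hg * Hg) - n_g * mu^2, 0) / (n_g - 1))
      } else rep(0, D)
      BW[g, ] <- pmax(sdv * n_g^(-1 / 5), 1e-3)
      FLOORED[g, ] <- sdv * n_g^(-1 / 5) <= 1e-3
    } else {
      BW[g, ] <- rep(bandwidth, length.out = D)
      FLOORED[g, ] <- TRUE
    }
  }
  bl <- rep(seq_len(D), each = G)            # column block -> dimension
  SPAN <- HI - LO
  cc <- .kde_batch_u_cpp(Hn, grp, ngv, LO, SPAN, BW, DEGEN, G)
  U <- cc$U
  BWrep <- BW[, bl, drop = FALSE]
  Ngrep <- matrix(ngv, ng, G * D)
  DEGrep <- DEGEN[, bl, drop = FALSE]
  Frep <- matrix(rep(f, D), ng, G * D, byrow = TRUE)
  list(G_embed = U %*% proj, U = U, A = cc$A, B2 = cc$B2,
       LO = LO, SPAN = SPAN, BWrep = BWrep, Ngrep = Ngrep,
       DEGrep = DEGrep, DEGEN = DEGEN, FLOORED = FLOORED,
       IMIN = IMIN, IMAX = IMAX, BW = BW, Frep = Frep, bl = bl, G = G, D = D)
}

kde_batch_backward <- function(cache, Hn, rows, grp, ngv, proj, DG) {
  G <- cache$G; D <- cache$D; bl <- cache$bl
  ng <- length(rows)
  dPk <- crossprod(cache$U, DG)
  dU <- tcrossprod(DG, proj)                 # ng x G*D
  dU[cache$DEGrep] <- 0
  inv_nb2 <- 1 / (cache$Ngrep * cache$BWrep^2)
  # direct kernel term, computed in C without large temporaries
  dH <- .kde_batch_dh_cpp(Hn, grp, ngv, cache$LO, cache$SPAN, cache$BW,
                          cache$DEGEN, G, dU)
  # grid-endpoint chain (A, B2 are per-graph moment sums from the forward)
  scl <- 1 / (matrix(ngv, ng, G * D) * cache$BWrep)
  dgg <- dU * (-cache$A * scl) / cache$BWrep
  blocksum <- function(x) t(rowsum(t(x), bl))
  dlo <- blocksum(dgg * (1 - cache$Frep))
  dhi <- blocksum(dgg * cache$Frep)
  live <- !cache$DEGEN
  for (g in seq_len(ng)) {
    lj <- which(live[g, ])
    if (!length(lj)) next
    i1 <- cbind(cache$IMIN[g, lj], lj)
    dH[i1] <- dH[i1] + dlo[g, lj]
    i2 <- cbind(cache$IMAX[g, lj], lj)
    dH[i2] <- dH[i2] + dhi[g, lj]
  }
  # Scott bandwidth chain
  dub <- dU * (-cache$U / cache$BWrep + cache$B2 * scl / cache$BWrep)
  db <- blocksum(dub)
  for (g in seq_len(ng)) {
    n_g <- ngv[g]
    if (n_g <= 1) next
    lj <- which(!cache$FLOORED[g, ] & live[g, ])
    if (!length(lj)) next
    Hg <- Hn[rows[[g]], lj, drop = FALSE]
    Hc <- Hg - matrix(colMeans(Hg), n_g, length(lj), byrow = TRUE)
    sdv <- cache$BW[g, lj] / n_g^(-1 / 5)
    sc <- db[g, lj] * n_g^(-1 / 5) / ((n_g - 1) * sdv)
    dH[rows[[g]], lj] <- dH[rows[[g]], lj] +
      Hc * matrix(sc, n_g, length(lj), byrow = TRUE)
  }
  list(dH = dH, dPk = dPk)
}

train_model <- function(params, bcfg, gps, times, events, tcfg, verbose = FALSE) {
  ng <- length(gps)
  rows <- vector("list", ng)
  off <- 0L
  for (i in seq_len(ng)) {
    rows[[i]] <- off + seq_len(gps[[i]]$n)
    off <- off + gps[[i]]$n
  }
  Xall <- do.call(rbind, lapply(gps, function(gp) gp$X))
  grp <- rep(seq_len(ng), vapply(gps, function(gp) gp$n, integer(1)))
  ngv <- vapply(gps, function(gp) gp$n, numeric(1))
  nl <- length(bcfg$hidden_dims)
  p <- bcfg$dropout
  state <- adam_init(params)
  loss_tr <- numeric(tcfg$epochs)

  agg <- function(M) {
    out <- M
    for (i in seq_len(ng)) {
      out[rows[[i]], ] <- gps[[i]]$norm$ah %*% M[rows[[i]], , drop = FALSE]
    }
    out
  }

  for (ep in seq_len(tcfg$epochs)) {
    # ---- forward
    H <- Xall
    caches <- vector("list", nl)
    for (l in seq_len(nl)) {
      cc <- list(H = H)
      if (bcfg$arch == "gcn") {
        M <- H %*% params[[paste0("W", l)]]
        Z <- agg(M)
        Z <- Z + rep(params[[paste0("b", l)]], each = nrow(Z))
        cc$Z <- Z
        H <- pmax(Z, 0)
      } else {
        W <- params[[paste0("W", l)]]
        Mall <- H %*% W
        heads <- bcfg$gat_heads
        dh <- ncol(W) / heads
        out <- matrix(0, nrow(Mall), ncol(Mall))
        att <- vector("list", ng)
        for (i in seq_len(ng)) {
          att[[i]] <- vector("list", heads)
          ri <- rows[[i]]
          for (hh in seq_len(heads)) {
            idx <- ((hh - 1) * dh + 1):(hh * dh)
            M <- Mall[ri, idx, drop = FALSE]
            sv <- drop(M %*% params[[paste0("asrc", l)]][, hh])
            tv <- drop(M %*% params[[paste0("adst", l)]][, hh])
            nn <- length(ri)
            Epre <- matrix(sv, nn, nn) + matrix(tv, nn, nn, byrow = TRUE)
            E <- leaky_relu(Epre)
            E[!gps[[i]]$adj] <- -Inf
            E <- E - apply(E, 1, max)
            P <- exp(E); P <- P / rowSums(P)
            out[ri, idx] <- P %*% M
            att[[i]][[hh]] <- list(P = P, Epre = Epre)
          }
        }
        Z <- out + rep(params[[paste0("b", l)]], each = nrow(out))
        cc$Mall <- Mall; cc$att <- att; cc$Z <- Z
        H <- pmax(Z, 0)
      }
      if (p > 0) {
        mask <- matrix(rbinom(length(H), 1, 1 - p), nrow(H), ncol(H)) / (1 - p)
        H <- H * mask
        cc$mask <- mask
      }
      cc$Hout <- H
      caches[[l]] <- cc
    }
    Hn <- H %*% params$Wn
    Hn <- Hn + rep(params$bn, each = nrow(Hn))
    pools <- NULL
    kdec <- NULL
    if (bcfg$pooling == "kde") {
      kdec <- kde_batch_forward(Hn, rows, grp, ngv, params$Pk,
                                bcfg$kde_grid, bcfg$kde_bandwidth)
      Gmat <- kdec$G_embed
    } else {
      pools <- vector("list", ng)
      Gmat <- matrix(0, ng, bcfg$embed_dim)
      for (i in seq_len(ng)) {
        Hni <- Hn[rows[[i]], , drop = FALSE]
        pools[[i]] <- switch(bcfg$pooling,
          mean = list(g = colMeans(Hni)),
          max = {
            am <- apply(Hni, 2, which.max)
            list(g = Hni[cbind(am, seq_len(ncol(Hni)))], amax = am)
          },
          attention = attention_pool_forward(Hni, params$Va, params$wa))
        Gmat[i, ] <- pools[[i]]$g
      }
    }
    risks <- drop(Gmat %*% params$beta)
    loss <- cox_partial_nll(risks, times, events, return_gradient = TRUE)
    if (!is.finite(loss)) {
      gs_error(sprintf("training diverged at epoch %d (loss %s); try a lower learning rate",
                       ep, format(as.numeric(loss))), "training_error")
    }
    loss_tr[ep] <- as.numeric(loss)
    dr <- attr(loss, "gradient")

    # ---- backward
    grads <- list(beta = drop(crossprod(Gmat, dr)))
    DG <- tcrossprod(dr, params$beta)        # ng x embed: per-graph dg
    if (bcfg$pooling == "kde") {
      bk <- kde_batch_backward(kdec, Hn, rows, grp, ngv, params$Pk, DG)
      dHn <- bk$dH
      grads$Pk <- bk$dPk
    } else {
      dHn <- matrix(0, nrow(Hn), ncol(Hn))
      dVa <- if (bcfg$pooling == "attention") params$Va * 0 else NULL
      dwa <- if (bcfg$pooling == "attention") params$wa * 0 else NULL
      for (i in seq_len(ng)) {
        dg <- DG[i, ]
        po <- pools[[i]]
        ni <- length(rows[[i]])
        dHn[rows[[i]], ] <- switch(bcfg$pooling,
          mean = matrix(dg, ni, length(dg), byrow = TRUE) / ni,
          max = {
            m <- matrix(0, ni, length(dg))
            m[cbind(po$amax, seq_along(dg))] <- dg
            m
          },
          attention = {
            bk <- attention_pool_backward(po, params$Va, params$wa, dg)
            dVa <- dVa + bk$dV; dwa <- dwa + bk$dw
            bk$dH
          })
      }
      if (bcfg$pooling == "attention") { grads$Va <- dVa; grads$wa <- dwa }
    }
    grads$Wn <- crossprod(caches[[nl]]$Hout, dHn)
    grads$bn <- colSums(dHn)
    dH <- tcrossprod(dHn, params$Wn)
    for (l in rev(seq_len(nl))) {
      cc <- caches[[l]]
      if (!is.null(cc$mask)) dH <- dH * cc$mask
      dZ <- dH * (cc$Z > 0)
      grads[[paste0("b", l)]] <- colSums(dZ)
      if (bcfg$arch == "gcn") {
        dM <- agg(dZ)                     # Ahat symmetric
        grads[[paste0("W", l)]] <- crossprod(cc$H, dM)
        if (l > 1) dH <- tcrossprod(dM, params[[paste0("W", l)]])
      } else {
        W <- params[[paste0("W", l)]]
        heads <- bcfg$gat_heads
        dh_ <- ncol(W) / heads
        dMall <- matrix(0, nrow(dZ), ncol(dZ))
        das <- params[[paste0("asrc", l)]] * 0
        dad <- params[[paste0("adst", l)]] * 0
        for (i in seq_len(ng)) {
          ri <- rows[[i]]
          for (hh in seq_len(heads)) {
            idx <- ((hh - 1) * dh_ + 1):(hh * dh_)
            M <- cc$Mall[ri, idx, drop = FALSE]
            a <- cc$att[[i]][[hh]]
            dOh <- dZ[ri, idx, drop = FALSE]
            dP <- tcrossprod(dOh, M)
            dM <- crossprod(a$P, dOh)
            dE <- a$P * (dP - rowSums(a$P * dP))
            dEpre <- dE * ifelse(a$Epre > 0, 1, 0.2)
            ds <- rowSums(dEpre); dt <- colSums(dEpre)
            dM <- dM + outer(ds, params[[paste0("asrc", l)]][, hh]) +
              outer(dt, params[[paste0("adst", l)]][, hh])
            das[, hh] <- das[, hh] + drop(crossprod(M, ds))
            dad[, hh] <- dad[, hh] + drop(crossprod(M, dt))
            dMall[ri, idx] <- dM
          }
        }
        grads[[paste0("W", l)]] <- crossprod(cc$H, dMall)
        grads[[paste0("asrc", l)]] <- das
        grads[[paste0("adst", l)]] <- dad
        if (l > 1) dH <- tcrossprod(dMall, W)
      }
    }
    upd <- adam_step(params, grads, state, tcfg$learning_rate,
                     weight_decay = tcfg$weight_decay)
    params <- upd$params
    state <- upd$state
    if (verbose && (ep %% 20 == 0 || ep == 1)) {
      message(sprintf("epoch %4d  loss %.5f", ep, loss_tr[ep]))
    }
  }
  list(params = params, loss_trajectory = loss_tr)
}
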