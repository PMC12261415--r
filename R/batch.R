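# Batched training path. A minibatch is encoded as one disjoint-union
# graph per entity kind (block-diagonal adjacency), which turns the many
# small per-sample matrix products into a few large ones while running the
# exact same layer code. Pooling becomes a segmented softmax over each
# sample's node range. The per-sample path in model.R computes identical
# quantities and serves as its oracle in the tests.

# Assemble the disjoint union of one entity kind across a batch.
union_graphs <- function(samples, kind) {
  gs <- lapply(samples, function(s) s$graphs[[kind]])
  ns <- vapply(gs, `[[`, integer(1), "n")
  offs <- cumsum(c(0L, ns[-length(ns)]))
  H <- do.call(rbind, lapply(gs, `[[`, "features"))
  X <- do.call(rbind, lapply(gs, `[[`, "coords"))
  dir_i <- unlist(lapply(seq_along(gs), function(b) gs[[b]]$dir$i + offs[b]))
  dir_j <- unlist(lapply(seq_along(gs), function(b) gs[[b]]$dir$j + offs[b]))
  attr <- do.call(rbind, lapply(gs, function(g) g$dir$attr))
  gid <- rep(seq_along(gs), ns)
  list(H = H, X = X, dir = list(i = dir_i, j = dir_j, attr = attr),
       gid = gid, ns = ns, B = length(gs))
}

encode_union <- function(un, params, config, with_cache = FALSE) {
  H <- un$H; X <- un$X
  caches <- list()
  for (l in seq_along(params$layers)) {
    out <- egnn_layer_fwd(H, X, un$dir, params$layers[[l]], config,
                          with_cache = with_cache)
    H <- out$H; X <- out$X
    if (with_cache) caches[[l]] <- out$cache
  }
  res <- list(H = H, X = X)
  if (with_cache) res$caches <- caches
  res
}

encode_union_bwd <- function(dH, dX, enc_out, un, params, config) {
  L <- length(params$layers)
  layer_grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    b <- egnn_layer_bwd(dH, dX, enc_out$caches[[l]], params$layers[[l]], config)
    dH <- b$dH; dX <- b$dX
    layer_grads[[l]] <- b$grads
  }
  list(grads = list(layers = layer_grads))
}

# Segmented mutual-attention pooling over a union graph.
# F_attr: B x d' matrix of per-sample attribute vectors.
pool_batch_fwd <- function(H, F_attr, gid, B, params, mean_pool = FALSE) {
  if (mean_pool) {
    ninv <- 1 / tabulate(gid, nbins = B)
    Z <- rowsum(H, gid) * ninv + F_attr
    return(list(Z = Z, w = ninv[gid],
                cache = list(H = H, F_attr = F_attr, gid = gid, B = B,
                             ninv = ninv, mean_pool = TRUE)))
  }
  da <- ncol(params$WQ)
  Q <- H %*% params$WQ
  tq <- tanh(Q)
  K <- F_attr %*% params$WK
  tk <- tanh(K)
  logit <- drop(tq %*% params$a[seq_len(da)]) +
    drop(tk %*% params$a[da + seq_len(da)])[gid]
  mx <- vapply(split(logit, gid), max, numeric(1))
  e <- exp(logit - mx[gid])
  denom <- rowsum(e, gid)
  w <- e / denom[gid]
  Z <- rowsum(w * H, gid) + F_attr
  list(Z = Z, w = w,
       cache = list(H = H, F_attr = F_attr, gid = gid, B = B, tq = tq,
                    tk = tk, w = w, mean_pool = FALSE))
}

pool_batch_bwd <- function(dZ, cache, params) {
  gid <- cache$gid
  H <- cache$H
  if (isTRUE(cache$mean_pool)) {
    dH <- (dZ * cache$ninv)[gid, , drop = FALSE]
    return(list(dH = dH, dF = dZ, grads = tree_zero(params)))
  }
  w <- cache$w
  da <- ncol(params$WQ)
  a1 <- params$a[seq_len(da)]
  a2 <- params$a[da + seq_len(da)]
  dF <- dZ
  dZn <- dZ[gid, , drop = FALSE]
  dH <- w * dZn
  dw <- rowSums(H * dZn)
  swdw <- rowsum(w * dw, gid)
  dlogit <- w * (dw - swdw[gid])
  ga1 <- drop(t(cache$tq) %*% dlogit)
  s_g <- rowsum(dlogit, gid)                  # per-graph logit-shift grad (~0)
  ga2 <- drop(t(cache$tk) %*% s_g)
  dQ <- (1 - cache$tq^2) * outer(dlogit, a1)
  gWQ <- t(H) %*% dQ
  dH <- dH + dQ %*% t(params$WQ)
  dK <- (1 - cache$tk^2) * outer(drop(s_g), a2)
  gWK <- t(cache$F_attr) %*% dK
  dF <- dF + dK %*% t(params$WK)
  list(dH = dH, dF = dF,
       grads = list(WQ = gWQ, WK = gWK, a = c(ga1, ga2)))
}

# Full batched forward. Returns per-sample probabilities and (optionally)
# the caches needed for the batched backward.
batch_forward <- function(samples, params, config, with_cache = FALSE) {
  B <- length(samples)
  mean_pool <- !isTRUE(config$use_attention_pooling)
  uns <- list(); encs <- list(); pools <- list(); F_attrs <- list()
  D <- do.call(rbind, lapply(samples, `[[`, "desc_std"))
  FP <- do.call(rbind, lapply(samples, `[[`, "fp"))
  for (kind in GRAPH_KINDS) {
    un <- union_graphs(samples, kind)
    enc <- encode_union(un, params$enc[[kind]], config, with_cache = with_cache)
    F_attr <- switch(kind,
      PROTAC = cbind(linear_fwd(D, params$attr_P$desc),
                     linear_fwd(FP, params$attr_P$fp)),
      POI = matrix(params$f_T, B, length(params$f_T), byrow = TRUE),
      E3 = matrix(params$f_E, B, length(params$f_E), byrow = TRUE))
    pool <- pool_batch_fwd(enc$H, F_attr, un$gid, B, params$pool[[kind]],
                           mean_pool = mean_pool)
    uns[[kind]] <- un; encs[[kind]] <- enc; pools[[kind]] <- pool
    F_attrs[[kind]] <- F_attr
  }
  Z <- cbind(pools$PROTAC$Z, pools$POI$Z, pools$E3$Z)
  fh <- mlp2_fwd(Z, params$head)
  logits <- fh$out
  mx <- pmax(logits[, 1], logits[, 2])
  e1 <- exp(logits[, 1] - mx); e2 <- exp(logits[, 2] - mx)
  prob_high <- unname(e2 / (e1 + e2))
  res <- list(prob_high = prob_high, logits = logits, Z = Z,
              weights = lapply(pools, `[[`, "w"))
  if (with_cache)
    res$cache <- list(uns = uns, encs = encs, pools = pools, head = fh$cache,
                      D = D, FP = FP, B = B)
  res
}

# Batched backward: class-weighted cross-entropy summed over the batch,
# gradients divided by the batch size (matching the per-sample loop).
batch_backward <- function(fwd, y, params, config, class_weight) {
  cache <- fwd$cache
  B <- cache$B
  p_high <- fwd$prob_high
  p_true <- ifelse(y == 1, p_high, 1 - p_high)
  loss <- -sum(class_weight * log(pmax(p_true, 1e-12)))
  # dlogits rows: cw * (softmax - onehot), pre-scaled by 1/B
  P <- cbind(1 - p_high, p_high)
  Yh <- cbind(1 - y, y)
  dlogits <- (class_weight / B) * (P - Yh)
  bh <- mlp2_bwd(dlogits, cache$head, params$head)
  dZ <- bh$dX
  d <- ncol(dZ) / 3
  grads <- list(enc = list(), pool = list(), attr_P = NULL,
                f_T = NULL, f_E = NULL, head = bh$grads)
  for (kind in GRAPH_KINDS) {
    cols <- switch(kind, PROTAC = seq_len(d), POI = d + seq_len(d),
                   E3 = 2 * d + seq_len(d))
    pb <- pool_batch_bwd(dZ[, cols, drop = FALSE], cache$pools[[kind]]$cache,
                         params$pool[[kind]])
    grads$pool[[kind]] <- pb$grads
    eb <- encode_union_bwd(pb$dH, matrix(0, nrow(pb$dH), 3),
                           cache$encs[[kind]], cache$uns[[kind]],
                           params$enc[[kind]], config)
    grads$enc[[kind]] <- eb$grads
    if (kind == "PROTAC") {
      half <- ncol(params$attr_P$desc$W)
      dFd <- pb$dF[, seq_len(half), drop = FALSE]
      dFf <- pb$dF[, half + seq_len(ncol(pb$dF) - half), drop = FALSE]
      grads$attr_P <- list(
        desc = list(W = t(cache$D) %*% dFd, b = colSums(dFd)),
        fp = list(W = t(cache$FP) %*% dFf, b = colSums(dFf))
      )
    } else if (kind == "POI") {
      grads$f_T <- colSums(pb$dF)
    } else {
      grads$f_E <- colSums(pb$dF)
    }
  }
  list(loss = loss, grads = grads)
}

# Batched prediction in chunks (keeps union sizes bounded).
batch_predict <- function(samples, params, config, chunk = 100L) {
  out <- numeric(length(samples))
  idx <- split(seq_along(samples), ceiling(seq_along(samples) / chunk))
  for (b in idx) {
    out[b] <- batch_forward(samples[b], params, config)$prob_high
  }
  out
}
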