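# E(3)-equivariant graph encoder. Each layer computes edge messages from
# invariant quantities (edge attributes, endpoint features, squared
# distance), updates coordinates along stabilized difference directions
# scaled by a learned per-edge gate, and updates node features from the
# summed incoming messages. Feature outputs are E(3)-invariant; coordinate
# outputs are E(3)-equivariant, and check_equivariance() verifies both
# numerically.

#' Initialize encoder parameters for one entity kind
#'
#' @param d_in input feature width (length of `feature_layout("atom")`).
#' @param d_hidden node embedding width d'.
#' @param n_layers number of message-passing layers L.
#' @param d_edge edge-attribute width.
#' @return parameter list with per-layer `phi_e` (edge message), `phi_x`
#'   (coordinate gate, zero-initialized output layer) and `phi_h` (node
#'   update) perceptrons. The first layer consumes raw atom features
#'   (width `d_in`); later layers operate at width `d_hidden`, so a
#'   zero-layer encoder is the identity.
#' @export
init_encoder_params <- function(d_in, d_hidden, n_layers,
                                d_edge = length(EDGE_ATTR_NAMES)) {
  layers <- lapply(seq_len(n_layers), function(l) {
    dh_in <- if (l == 1) d_in else d_hidden
    list(
      phi_e = init_mlp2(d_edge + 2 * dh_in + 1, d_hidden, d_hidden,
                        act1 = "silu", act2 = "silu"),
      phi_x = init_mlp2(d_hidden, d_hidden, 1, act1 = "silu", act2 = "none",
                        gain_out = 0),
      phi_h = init_mlp2(dh_in + d_hidden, d_hidden, d_hidden,
                        act1 = "silu", act2 = "none")
    )
  })
  list(layers = layers)
}

# Aggregate per-edge rows into per-node rows (sum over incoming edges).
aggregate_by_node <- function(x, idx, n) {
  out <- matrix(0, n, ncol(x))
  if (length(idx)) {
    tmp <- rowsum(x, idx)
    out[as.integer(rownames(tmp)), ] <- tmp
  }
  out
}

# One encoder layer. H: n x d', X: n x 3; dir: directed edge expansion.
egnn_layer_fwd <- function(H, X, dir, lp, config, with_cache = FALSE) {
  n <- nrow(H)
  eps <- config$eps
  use_geom <- config$use_equivariant %||% TRUE
  d_msg <- length(lp$phi_e$l2$b)
  if (!length(dir$i)) {
    # no edges: messages are empty; every node keeps coords and aggregates 0
    u <- cbind(H, matrix(0, n, d_msg))
    fh <- mlp2_fwd(u, lp$phi_h)
    res <- list(H = fh$out, X = X)
    if (with_cache)
      res$cache <- list(empty = TRUE, fh = fh$cache, n = n, d_in = ncol(H))
    return(res)
  }
  i <- dir$i; j <- dir$j
  v <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
  d2 <- rowSums(v^2)
  dn <- sqrt(d2)
  eattr <- dir$attr
  if (!use_geom) {
    # non-geometric ablation: distances zeroed out of the message input,
    # no coordinate update
    d2_in <- numeric(length(i))
    eattr[, "distance"] <- 0
  } else d2_in <- d2
  e_in <- cbind(eattr, H[i, , drop = FALSE], H[j, , drop = FALSE], d2_in)
  fe <- mlp2_fwd(e_in, lp$phi_e)
  m <- fe$out
  if (use_geom) {
    fx <- mlp2_fwd(m, lp$phi_x)
    s <- drop(fx$out)
    r <- v / (dn + eps)
    contrib <- r * s
    delta <- aggregate_by_node(contrib, i, n)
    if (isTRUE(config$normalize_coord_update)) {
      ni <- tabulate(i, nbins = n)
      coef <- ifelse(ni > 0, 1 / pmax(ni, 1), 0)
      delta <- delta * coef
    }
    X_new <- X + delta
  } else {
    fx <- NULL; s <- NULL; r <- NULL
    X_new <- X
  }
  mi <- aggregate_by_node(m, i, n)
  u <- cbind(H, mi)
  fh <- mlp2_fwd(u, lp$phi_h)
  res <- list(H = fh$out, X = X_new)
  if (with_cache) {
    res$cache <- list(empty = FALSE, i = i, j = j, v = v, d2 = d2, dn = dn,
                      fe = fe$cache, fx = if (use_geom) fx$cache else NULL,
                      s = s, r = r, fh = fh$cache, n = n, use_geom = use_geom,
                      d_in = ncol(H))
  }
  res
}

egnn_layer_bwd <- function(dH_out, dX_out, cache, lp, config) {
  eps <- config$eps
  n <- cache$n
  d_in <- cache$d_in
  bh <- mlp2_bwd(dH_out, cache$fh, lp$phi_h)
  dU <- bh$dX
  dH <- dU[, seq_len(d_in), drop = FALSE]
  dMi <- dU[, d_in + seq_len(ncol(dU) - d_in), drop = FALSE]
  grads <- list(phi_e = NULL, phi_x = NULL, phi_h = bh$grads)
  if (isTRUE(cache$empty)) {
    grads$phi_e <- tree_zero(lp$phi_e)
    grads$phi_x <- tree_zero(lp$phi_x)
    return(list(dH = dH, dX = dX_out, grads = grads))
  }
  i <- cache$i; j <- cache$j
  dm <- dMi[i, , drop = FALSE]              # message path via feature update
  dX <- dX_out                              # identity term of the coordinate update
  dv <- matrix(0, length(i), 3)
  if (cache$use_geom) {
    dDelta <- dX_out
    if (isTRUE(config$normalize_coord_update)) {
      ni <- tabulate(i, nbins = n)
      coef <- ifelse(ni > 0, 1 / pmax(ni, 1), 0)
      dDelta <- dDelta * coef
    }
    dcontrib <- dDelta[i, , drop = FALSE]
    ds <- rowSums(dcontrib * cache$r)
    dr <- dcontrib * cache$s
    t_ <- cache$dn + eps
    rs <- rowSums(dr * cache$v)
    dv_r <- dr / t_ - cache$v * (rs / (cache$dn * t_^2))
    dv_r[cache$dn == 0, ] <- 0
    dv <- dv + dv_r
    bx <- mlp2_bwd(matrix(ds, ncol = 1), cache$fx, lp$phi_x)
    dm <- dm + bx$dX
    grads$phi_x <- bx$grads
  } else {
    grads$phi_x <- tree_zero(lp$phi_x)
  }
  be <- mlp2_bwd(dm, cache$fe, lp$phi_e)
  grads$phi_e <- be$grads
  d_edge <- ncol(cache$fe$X) - 2 * d_in - 1
  dHi <- be$dX[, d_edge + seq_len(d_in), drop = FALSE]
  dHj <- be$dX[, d_edge + d_in + seq_len(d_in), drop = FALSE]
  dd2 <- be$dX[, d_edge + 2 * d_in + 1]
  if (cache$use_geom) dv <- dv + 2 * cache$v * dd2
  dH <- dH + aggregate_by_node(dHi, i, n) + aggregate_by_node(dHj, j, n)
  dX <- dX + aggregate_by_node(dv, i, n) - aggregate_by_node(dv, j, n)
  list(dH = dH, dX = dX, grads = grads)
}

#' Encode a molecule graph with the equivariant encoder
#'
#' Applies `n_layers` equivariant message-passing layers to the graph's
#' atom features and coordinates. With zero layers both are returned
#' unchanged. Deterministic given parameters and input.
#'
#' @param graph a featurized `molecule_graph`.
#' @param params encoder parameters from [init_encoder_params()].
#' @param config a [pdg_config()] (uses `eps`, `normalize_coord_update`,
#'   `use_equivariant`).
#' @param with_cache keep intermediate states for backpropagation.
#' @return list with `H` (n x d' node embeddings), `X` (final coordinates),
#'   and per-layer `snapshots` of both.
#' @export
encode_graph <- function(graph, params, config = pdg_config(),
                         with_cache = FALSE) {
  if (is.null(graph$features))
    stop("graph has no features; run atom_features() first")
  if (length(params$layers) &&
      ncol(graph$features) != nrow(params$layers[[1]]$phi_h$l1$W) -
        length(params$layers[[1]]$phi_e$l2$b))
    stop("configuration error: graph feature width ", ncol(graph$features),
         " does not match encoder input width")
  H <- graph$features
  X <- graph$coords
  dir <- graph$dir %||% graph_directed(graph)
  snapshots <- list(list(H = H, X = X))
  caches <- list()
  for (l in seq_along(params$layers)) {
    out <- egnn_layer_fwd(H, X, dir, params$layers[[l]], config,
                          with_cache = with_cache)
    H <- out$H; X <- out$X
    snapshots[[l + 1]] <- list(H = H, X = X)
    if (with_cache) caches[[l]] <- out$cache
  }
  res <- list(H = H, X = X, snapshots = snapshots)
  if (with_cache) res$caches <- caches
  res
}

encode_bwd <- function(dH, dX, enc_out, graph, params, config) {
  L <- length(params$layers)
  layer_grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    b <- egnn_layer_bwd(dH, dX, enc_out$caches[[l]], params$layers[[l]], config)
    dH <- b$dH; dX <- b$dX
    layer_grads[[l]] <- b$grads
  }
  list(grads = list(layers = layer_grads), dH0 = dH, dX0 = dX)
}

#' Random Euclidean transform
#'
#' Draws a uniformly random orthogonal 3x3 matrix (optionally forcing a
#' reflection, det = -1) and a random translation.
#'
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @param reflection force `det(M) = -1` (default: random sign).
#' @param translation_sd spread of the translation components.
#' @return list with `rotation` (3x3 orthogonal) and `translation` (3-vector).
#' @export
random_transform <- function(seed = NULL, reflection = NULL,
                             translation_sd = 5) {
  if (!is.null(seed)) set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  M <- qr.Q(qr_)
  M <- M %*% diag(sign(diag(qr.R(qr_))))
  want_reflect <- if (is.null(reflection)) stats::runif(1) < 0.5 else reflection
  if ((det(M) < 0) != want_reflect) M[, 1] <- -M[, 1]
  list(rotation = M, translation = stats::rnorm(3, 0, translation_sd))
}

apply_transform <- function(X, tr) {
  sweep(X %*% t(tr$rotation), 2, tr$translation, "+")
}

#' Check the E(3)-equivariance contract of the encoder
#'
#' Encodes the graph as-is and with coordinates transformed by
#' `rotation %*% x + translation`, then verifies that (a) feature
#' embeddings are invariant and (b) final coordinates are equivariant
#' (transform of output equals output of transform), both within `tol`.
#'
#' @param graph featurized `molecule_graph`.
#' @param params encoder parameters.
#' @param transform list with orthogonal `rotation` and `translation`
#'   (see [random_transform()]).
#' @param tol tolerance for both maxima (default 1e-8).
#' @param config encoder configuration.
#' @return list with `max_feature_dev`, `max_coord_dev`, the worst node for
#'   each, and `pass`.
#' @export
check_equivariance <- function(graph, params, transform, tol = 1e-8,
                               config = pdg_config()) {
  M <- transform$rotation
  if (max(abs(crossprod(M) - diag(3))) > 1e-6)
    stop("transform$rotation is not orthogonal")
  base <- encode_graph(graph, params, config)
  g2 <- graph
  g2$coords <- apply_transform(graph$coords, transform)
  moved <- encode_graph(g2, params, config)
  feat_dev <- abs(moved$H - base$H)
  coord_dev <- abs(moved$X - apply_transform(base$X, transform))
  max_feat <- max(feat_dev)
  max_coord <- max(coord_dev)
  res <- list(
    max_feature_dev = max_feat,
    max_coord_dev = max_coord,
    worst_feature_node = which.max(apply(feat_dev, 1, max)),
    worst_coord_node = which.max(apply(coord_dev, 1, max)),
    tol = tol,
    pass = max_feat <= tol && max_coord <= tol
  )
  if (!res$pass)
    warning(sprintf(
      "equivariance violation: feature dev %.3g (node %d), coord dev %.3g (node %d) exceed tol %g",
      max_feat, res$worst_feature_node, max_coord, res$worst_coord_node, tol))
  res
}
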