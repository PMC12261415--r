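# Mutual attention pooling, ternary fusion, the classification head, and
# the per-sample forward/backward pass of the full model.
#
# Pooling: node queries q_i = WQ h_i,
# a key k = WK f from the attribute vector, logits a . tanh(q_i || k),
# softmax over nodes, and z = sum_i w_i h_i + f. Because the key enters
# every node's logit through the same additive constant, the softmax
# weights are unchanged by the key (a shift-invariance of softmax); the
# attribute vector still shapes z through the additive term. Implemented
# in exactly this form; gradients through the key channel are exact zeros
# in consequence.

#' Initialize mutual-attention pooling parameters
#'
#' @param d_hidden node embedding width d'.
#' @param d_attr attribute vector width (equals d').
#' @param d_attn attention projection width.
#' @return list with `WQ` (d' x da), `WK` (df x da) and attention vector
#'   `a` (length 2 da).
#' @export
init_pool_params <- function(d_hidden, d_attr, d_attn) {
  list(
    WQ = matrix(stats::runif(d_hidden * d_attn, -1, 1) / sqrt(d_hidden),
                d_hidden, d_attn),
    WK = matrix(stats::runif(d_attr * d_attn, -1, 1) / sqrt(d_attr),
                d_attr, d_attn),
    a = stats::runif(2 * d_attn, -1, 1) / sqrt(2 * d_attn)
  )
}

init_attr_params <- function(k_desc, nbits, d_hidden) {
  half <- d_hidden %/% 2
  list(desc = init_linear(k_desc, half),
       fp = init_linear(nbits, d_hidden - half))
}

#' Pool node embeddings into a graph embedding by mutual attention
#'
#' @param H n x d' node embedding matrix.
#' @param f attribute vector of length d' (the fused PROTAC attribute
#'   vector, or a learned free vector for protein graphs).
#' @param params pooling parameters from [init_pool_params()].
#' @param mean_pool use the ablation fallback `z = mean(H) + f` with
#'   uniform weights.
#' @return list with `z` (graph embedding, length d'), `weights`
#'   (nonnegative, summing to one), and the per-node attention logits.
#' @export
mutual_attention_pool <- function(H, f, params, mean_pool = FALSE) {
  n <- nrow(H)
  if (mean_pool) {
    w <- rep(1 / n, n)
    return(list(z = colMeans(H) + f, weights = w, logits = rep(0, n),
                cache = list(H = H, f = f)))
  }
  da <- ncol(params$WQ)
  Q <- H %*% params$WQ
  k <- drop(f %*% params$WK)
  tq <- tanh(Q)
  tk <- tanh(k)
  logits <- drop(tq %*% params$a[seq_len(da)]) + sum(params$a[da + seq_len(da)] * tk)
  w <- softmax_vec(logits)
  z <- drop(t(H) %*% w) + f
  list(z = z, weights = w, logits = logits,
       cache = list(Q = Q, k = k, tq = tq, tk = tk, w = w, H = H, f = f))
}

pool_bwd <- function(dz, pooled, params, mean_pool = FALSE) {
  cache <- pooled$cache
  H <- cache$H
  if (mean_pool) {
    n <- nrow(H)
    dH <- matrix(rep(dz / n, each = n), n)
    return(list(dH = dH, df = dz, grads = tree_zero(params)))
  }
  w <- cache$w
  da <- ncol(params$WQ)
  a1 <- params$a[seq_len(da)]
  a2 <- params$a[da + seq_len(da)]
  df <- dz                                   # additive + f term
  dH <- outer(w, dz)                         # z = sum_i w_i h_i
  dw <- drop(H %*% dz)
  dlogit <- w * (dw - sum(w * dw))           # softmax backward
  ga1 <- drop(t(cache$tq) %*% dlogit)
  ga2 <- sum(dlogit) * cache$tk              # key channel: exact zero since sum(dlogit) = 0
  dQ <- (1 - cache$tq^2) * outer(dlogit, a1)
  gWQ <- t(H) %*% dQ
  dH <- dH + dQ %*% t(params$WQ)
  dk <- sum(dlogit) * (a2 * (1 - cache$tk^2))
  gWK <- outer(cache$f, dk)
  df <- df + drop(params$WK %*% dk)
  list(dH = dH, df = df,
       grads = list(WQ = gWQ, WK = gWK, a = c(ga1, ga2)))
}

#' Fuse the three graph embeddings and classify
#'
#' Concatenates the PROTAC, POI and E3 embeddings and applies a two-layer
#' perceptron head giving logits over {low, high} and the probability of
#' high degradation activity.
#'
#' @param zP,zT,zE graph embeddings of equal length d'.
#' @param head_params head perceptron (a `mlp2` parameter list of input
#'   width 3 d').
#' @return list with `z` (the ternary embedding), `logits` (length 2,
#'   ordered low, high) and `prob_high`.
#' @export
fuse_and_classify <- function(zP, zT, zE, head_params) {
  if (length(unique(c(length(zP), length(zT), length(zE)))) != 1)
    stop("configuration error: embedding sizes differ")
  z <- c(zP, zT, zE)
  if (length(z) != nrow(head_params$l1$W))
    stop("configuration error: head input width ", nrow(head_params$l1$W),
         " does not match embedding length ", length(z))
  fh <- mlp2_fwd(matrix(z, 1), head_params)
  logits <- drop(fh$out)
  p <- softmax_vec(logits)
  list(z = z, logits = logits, prob_high = p[2], prob = p, cache = fh$cache)
}

#' Map node attention weights onto graph edges
#'
#' Annotates each edge (i, j) with the mean of its endpoint attention
#' weights, (w_i + w_j) / 2, for visualization of which regions of the
#' molecule drive the pooled representation.
#'
#' @param graph a `molecule_graph`.
#' @param weights per-node attention weights (length = node count).
#' @return tibble with columns `i`, `j`, `kind` and `attention`.
#' @export
edge_attention_map <- function(graph, weights) {
  if (length(weights) != graph$n)
    stop("weights length must equal the node count")
  e <- graph$edges
  tibble::tibble(
    i = e$i, j = e$j, kind = e$kind,
    attention = (weights[e$i] + weights[e$j]) / 2
  )
}

# ---- full model -------------------------------------------------------------

#' Initialize the full model parameter set
#'
#' Separate equivariant encoders and pooling blocks per entity kind
#' (PROTAC / POI / E3), the two one-layer attribute perceptrons for the
#' PROTAC (selected descriptors and Morgan fingerprint), learned free
#' attribute vectors for the two proteins, and the classification head.
#'
#' @param config a [pdg_config()].
#' @param k_desc number of selected descriptors feeding the attribute MLP.
#' @param d_in atom feature width.
#' @param seed RNG seed for initialization.
#' @return nested parameter list.
#' @export
init_model_params <- function(config = pdg_config(),
                              k_desc = config$k_select,
                              d_in = length(feature_layout("atom")),
                              seed = 1L) {
  set.seed(seed)
  d <- config$hidden_dim
  enc <- lapply(stats::setNames(GRAPH_KINDS, GRAPH_KINDS), function(kind)
    init_encoder_params(d_in, d, config$n_layers))
  pool <- lapply(stats::setNames(GRAPH_KINDS, GRAPH_KINDS), function(kind)
    init_pool_params(d, d, config$attn_dim))
  list(
    enc = enc,
    pool = pool,
    attr_P = init_attr_params(k_desc, config$fp_bits, d),
    f_T = stats::rnorm(d, 0, 1 / sqrt(d)),
    f_E = stats::rnorm(d, 0, 1 / sqrt(d)),
    head = init_mlp2(3 * d, d, 2, act1 = "silu", act2 = "none")
  )
}

# Forward pass for one ternary sample. `sample` carries featurized graphs
# and the standardized descriptor / fingerprint vectors.
model_forward <- function(sample, params, config, with_cache = FALSE) {
  mean_pool <- !isTRUE(config$use_attention_pooling)
  enc_out <- list(); pooled <- list(); fvec <- list()
  for (kind in GRAPH_KINDS) {
    enc_out[[kind]] <- encode_graph(sample$graphs[[kind]], params$enc[[kind]],
                                    config, with_cache = with_cache)
    fvec[[kind]] <- switch(kind,
      PROTAC = build_attribute_vector(sample$desc_std, sample$fp, params$attr_P),
      POI = params$f_T,
      E3 = params$f_E)
    pooled[[kind]] <- mutual_attention_pool(enc_out[[kind]]$H, fvec[[kind]],
                                            params$pool[[kind]],
                                            mean_pool = mean_pool)
  }
  out <- fuse_and_classify(pooled$PROTAC$z, pooled$POI$z, pooled$E3$z,
                           params$head)
  res <- list(prob_high = out$prob_high, logits = out$logits, z = out$z,
              weights = lapply(pooled, `[[`, "weights"))
  if (with_cache)
    res$cache <- list(enc_out = enc_out, pooled = pooled, fvec = fvec,
                      head = out$cache, mean_pool = mean_pool)
  res
}

# Backward pass: class-weighted cross-entropy on the two logits.
# y in {0 (low), 1 (high)}; returns gradients mirroring params and the loss.
model_backward <- function(sample, fwd, y, params, config, class_weight = 1) {
  p <- softmax_vec(fwd$logits)
  loss <- -class_weight * log(max(p[y + 1], 1e-12))
  dlogits <- class_weight * (p - c(1 - y, y))
  bh <- mlp2_bwd(matrix(dlogits, 1), fwd$cache$head, params$head)
  dz <- drop(bh$dX)
  d <- length(dz) / 3
  dz_kind <- list(PROTAC = dz[seq_len(d)], POI = dz[d + seq_len(d)],
                  E3 = dz[2 * d + seq_len(d)])
  grads <- list(enc = list(), pool = list(), attr_P = NULL,
                f_T = NULL, f_E = NULL, head = bh$grads)
  for (kind in GRAPH_KINDS) {
    pb <- pool_bwd(dz_kind[[kind]], fwd$cache$pooled[[kind]],
                   params$pool[[kind]], mean_pool = fwd$cache$mean_pool)
    grads$pool[[kind]] <- pb$grads
    eb <- encode_bwd(pb$dH, matrix(0, nrow(pb$dH), 3),
                     fwd$cache$enc_out[[kind]],
                     sample$graphs[[kind]], params$enc[[kind]], config)
    grads$enc[[kind]] <- eb$grads
    if (kind == "PROTAC") {
      half <- ncol(params$attr_P$desc$W)
      dfd <- pb$df[seq_len(half)]
      dff <- pb$df[half + seq_len(length(pb$df) - half)]
      grads$attr_P <- list(
        desc = list(W = outer(sample$desc_std, dfd), b = dfd),
        fp = list(W = outer(sample$fp, dff), b = dff)
      )
    } else if (kind == "POI") {
      grads$f_T <- pb$df
    } else {
      grads$f_E <- pb$df
    }
  }
  list(loss = loss, grads = grads)
}
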