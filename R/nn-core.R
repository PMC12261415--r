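# Minimal dense neural-network primitives with hand-written reverse-mode
# gradients. Parameters are nested lists whose leaves are numeric matrices
# or vectors; gradients mirror that structure exactly, which lets the Adam
# update walk both trees in lockstep.

silu <- function(x) x / (1 + exp(-x))

dsilu <- function(x) {
  s <- 1 / (1 + exp(-x))
  s * (1 + x * (1 - s))
}

# Uniform fan-in initialization; gain 0 zeroes the weights (used for the
# final layer of the coordinate gate so initial coordinate updates vanish).
init_linear <- function(n_in, n_out, gain = 1) {
  a <- gain / sqrt(n_in)
  list(
    W = matrix(stats::runif(n_in * n_out, -a, a), n_in, n_out),
    b = numeric(n_out)
  )
}

linear_fwd <- function(X, lin) {
  out <- X %*% lin$W
  out + matrix(lin$b, nrow(out), length(lin$b), byrow = TRUE)
}

# Two-layer perceptron. act2 = "none" gives a linear output layer.
init_mlp2 <- function(n_in, n_hidden, n_out, act1 = "silu", act2 = "none",
                      gain_out = 1) {
  list(
    l1 = init_linear(n_in, n_hidden),
    l2 = init_linear(n_hidden, n_out, gain = gain_out),
    act1 = act1, act2 = act2
  )
}

# silu forward caches the sigmoid so the backward pass avoids a second exp
act_fwd <- function(z, act) {
  if (act == "silu") {
    s <- 1 / (1 + exp(-z))
    list(out = z * s, s = s)
  } else list(out = z, s = NULL)
}

act_bwd <- function(d, z, s, act) {
  if (act == "silu") d * (s * (1 + z * (1 - s))) else d
}

mlp2_fwd <- function(X, p) {
  z1 <- linear_fwd(X, p$l1)
  f1 <- act_fwd(z1, p$act1)
  z2 <- linear_fwd(f1$out, p$l2)
  f2 <- act_fwd(z2, p$act2)
  list(out = f2$out, cache = list(X = X, z1 = z1, a1 = f1$out, s1 = f1$s,
                                  z2 = z2, s2 = f2$s))
}

mlp2_bwd <- function(dOut, cache, p) {
  dz2 <- act_bwd(dOut, cache$z2, cache$s2, p$act2)
  gW2 <- crossprod(cache$a1, dz2)
  gb2 <- colSums(dz2)
  da1 <- tcrossprod(dz2, p$l2$W)
  dz1 <- act_bwd(da1, cache$z1, cache$s1, p$act1)
  gW1 <- crossprod(cache$X, dz1)
  gb1 <- colSums(dz1)
  dX <- tcrossprod(dz1, p$l1$W)
  # grads mirror the parameter tree exactly (activation tags included) so
  # tree_map2 can walk params and grads in lockstep
  list(
    dX = dX,
    grads = list(l1 = list(W = gW1, b = gb1), l2 = list(W = gW2, b = gb2),
                 act1 = p$act1, act2 = p$act2)
  )
}

# ---- parameter-tree helpers -------------------------------------------------

is_leaf <- function(x) is.numeric(x)

tree_map <- function(f, tree) {
  if (is_leaf(tree)) return(f(tree))
  if (is.list(tree)) return(lapply(tree, tree_map, f = f))
  tree
}

tree_map2 <- function(f, a, b) {
  if (is_leaf(a)) return(f(a, b))
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- tree_map2(f, a[[nm]], b[[nm]])
    return(out)
  }
  a
}

tree_zero <- function(tree) tree_map(function(x) x * 0, tree)

tree_add <- function(a, b) tree_map2(`+`, a, b)

tree_scale <- function(tree, s) tree_map(function(x) x * s, tree)

tree_max_abs <- function(tree) {
  m <- 0
  walk <- function(t) {
    if (is_leaf(t)) m <<- max(m, max(abs(t))) else if (is.list(t)) lapply(t, walk)
    invisible(NULL)
  }
  walk(tree)
  m
}

# Flatten/unflatten for finite-difference gradient checks.
tree_flatten <- function(tree) {
  out <- numeric(0)
  walk <- function(t) {
    if (is_leaf(t)) out <<- c(out, as.numeric(t)) else if (is.list(t)) lapply(t, walk)
    invisible(NULL)
  }
  walk(tree)
  out
}

tree_unflatten <- function(tree, vec) {
  idx <- 0
  fill <- function(t) {
    if (is_leaf(t)) {
      n <- length(t)
      val <- vec[(idx + 1):(idx + n)]
      idx <<- idx + n
      if (is.matrix(t)) return(matrix(val, nrow(t), ncol(t)))
      return(val)
    }
    if (is.list(t)) return(lapply(t, fill))
    t
  }
  fill(tree)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}
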