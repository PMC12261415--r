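# Equivariant encoder: message/coordinate/feature update formulas against
# naive loop oracles, the E(3)-equivariance contract, structural
# properties, and the analytic gradients against finite differences.

test_that("edge messages depend on coordinates only through the squared distance", {
  cfg <- tiny_config()
  d_in <- length(feature_layout("atom"))
  enc <- active_encoder(d_in, cfg, seed = 3)
  lp <- enc$layers[[1]]
  set.seed(10)
  for (rep in 1:10) {
    hi <- stats::rnorm(d_in); hj <- stats::rnorm(d_in)
    aij <- c(1, 0, 0, 0, 0, 0, stats::runif(1, 1, 3))
    xi <- stats::rnorm(3); xj <- stats::rnorm(3)
    d2 <- sum((xi - xj)^2)
    m_ref <- mlp2_ref(matrix(c(aij, hi, hj, d2), 1), lp$phi_e)
    # translating both endpoints leaves the message unchanged
    b <- stats::rnorm(3, 0, 10)
    d2_shift <- sum(((xi + b) - (xj + b))^2)
    expect_equal(d2_shift, d2, tolerance = 1e-9)
    m_shift <- mlp2_ref(matrix(c(aij, hi, hj, d2_shift), 1), lp$phi_e)
    expect_equal(m_shift, m_ref, tolerance = 1e-9)
  }
  # coincident endpoints: squared distance 0 is a valid input
  hi <- stats::rnorm(d_in)
  m0 <- mlp2_ref(matrix(c(rep(0, 7), hi, hi, 0), 1), lp$phi_e)
  expect_true(all(is.finite(m0)))
})

test_that("one encoder layer matches the naive double-loop oracle", {
  cfg <- tiny_config(n_layers = 1L)
  for (seed in c(4, 8, 15)) {
    g <- random_molecule(6, seed = seed)$graph
    d_in <- ncol(g$features)
    enc <- active_encoder(d_in, cfg, seed = seed)
    out <- encode_graph(g, enc, cfg)
    dir <- protacdeg:::graph_directed(g)
    ref <- naive_egnn_layer(g$features, g$coords, dir$i, dir$j, dir$attr,
                            enc$layers[[1]], eps = cfg$eps)
    expect_equal(out$H, ref$H, tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(out$X, ref$X, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("the normalized coordinate-update variant divides by the neighbour count", {
  cfg <- tiny_config(n_layers = 1L, normalize_coord_update = TRUE)
  g <- random_molecule(6, seed = 21)$graph
  enc <- active_encoder(ncol(g$features), cfg, seed = 2)
  out <- encode_graph(g, enc, cfg)
  dir <- protacdeg:::graph_directed(g)
  ref <- naive_egnn_layer(g$features, g$coords, dir$i, dir$j, dir$attr,
                          enc$layers[[1]], eps = cfg$eps, normalize = TRUE)
  expect_equal(out$X, ref$X, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("isolated nodes keep their coordinates; zeroed messages reduce the feature update", {
  cfg <- tiny_config(n_layers = 1L)
  # a graph with an isolated node (no edges at all)
  g <- molecule_graph("PROTAC", elements = c("C", "N"),
                      coords = rbind(c(0, 0, 0), c(3, 0, 0)),
                      edges = data.frame(i = integer(0), j = integer(0),
                                         kind = character(0),
                                         order = character(0)))
  g$features <- atom_features(g)
  enc <- active_encoder(ncol(g$features), cfg, seed = 5)
  out <- encode_graph(g, enc, cfg)
  expect_equal(out$X, g$coords, ignore_attr = TRUE)
  # with phi_e zeroed the aggregated message is zero: h' = phi_h(h || 0)
  g2 <- random_molecule(5, seed = 3)$graph
  enc2 <- active_encoder(ncol(g2$features), cfg, seed = 6)
  enc2$layers[[1]]$phi_e$l1$W[] <- 0
  enc2$layers[[1]]$phi_e$l1$b[] <- 0
  enc2$layers[[1]]$phi_e$l2$W[] <- 0
  enc2$layers[[1]]$phi_e$l2$b[] <- 0
  out2 <- encode_graph(g2, enc2, cfg)
  for (i in seq_len(g2$n)) {
    expected <- mlp2_ref(matrix(c(g2$features[i, ], rep(0, cfg$hidden_dim)), 1),
                         enc2$layers[[1]]$phi_h)
    expect_equal(out2$H[i, ], expected, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("two symmetric nodes receive equal and opposite coordinate updates", {
  cfg <- tiny_config(n_layers = 1L)
  g <- molecule_graph("PROTAC", elements = c("C", "C"),
                      coords = rbind(c(-1, 0, 0), c(1, 0, 0)),
                      edges = data.frame(i = 1L, j = 2L, kind = "bond",
                                         order = "single"))
  g$features <- atom_features(g)
  enc <- active_encoder(ncol(g$features), cfg, seed = 9)
  out <- encode_graph(g, enc, cfg)
  delta <- out$X - g$coords
  expect_equal(delta[1, ], -delta[2, ], tolerance = 1e-12)
  expect_equal(colMeans(out$X), colMeans(g$coords), tolerance = 1e-12)
})

test_that("encoding is the identity at zero layers and composes across layers", {
  cfg0 <- tiny_config(n_layers = 0L)
  g <- random_molecule(5, seed = 13)$graph
  out0 <- encode_graph(g, list(layers = list()), cfg0)
  expect_identical(out0$H, g$features)
  expect_identical(out0$X, g$coords)
  # L = 2 equals applying the two single layers in sequence via the oracle
  cfg2 <- tiny_config(n_layers = 2L)
  enc <- active_encoder(ncol(g$features), cfg2, seed = 14)
  out2 <- encode_graph(g, enc, cfg2)
  dir <- protacdeg:::graph_directed(g)
  s1 <- naive_egnn_layer(g$features, g$coords, dir$i, dir$j, dir$attr,
                         enc$layers[[1]], eps = cfg2$eps)
  s2 <- naive_egnn_layer(s1$H, s1$X, dir$i, dir$j, dir$attr,
                         enc$layers[[2]], eps = cfg2$eps)
  expect_equal(out2$H, s2$H, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(out2$X, s2$X, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("permuting node order permutes encoder outputs identically", {
  cfg <- tiny_config()
  g <- random_molecule(7, seed = 19)$graph
  enc <- active_encoder(ncol(g$features), cfg, seed = 20)
  out <- encode_graph(g, enc, cfg)
  set.seed(1)
  perm <- sample.int(g$n)
  inv <- order(perm)
  e <- g$edges
  g2 <- molecule_graph("PROTAC", g$elements[perm], g$coords[perm, ],
                       data.frame(i = inv[e$i], j = inv[e$j],
                                  kind = e$kind, order = e$order))
  g2$features <- g$features[perm, ]
  out2 <- encode_graph(g2, enc, cfg)
  expect_equal(out2$H, out$H[perm, ], tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(out2$X, out$X[perm, ], tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("feature invariance and coordinate equivariance hold under random E(3) transforms", {
  cfg <- tiny_config()
  set.seed(99)
  for (rep in 1:20) {
    g <- random_molecule(sample(4:9, 1), seed = 1000 + rep)$graph
    enc <- active_encoder(ncol(g$features), cfg, seed = 2000 + rep)
    tr <- random_transform()           # random rotation or reflection
    res <- check_equivariance(g, enc, tr, tol = 1e-8, config = cfg)
    expect_true(res$pass)
  }
  # the identity transform gives exactly zero deviation
  g <- random_molecule(6, seed = 3)$graph
  enc <- active_encoder(ncol(g$features), cfg, seed = 4)
  res0 <- check_equivariance(g, enc,
                             list(rotation = diag(3), translation = rep(0, 3)),
                             config = cfg)
  expect_identical(res0$max_feature_dev, 0)
  expect_identical(res0$max_coord_dev, 0)
  # a non-orthogonal transform is rejected
  expect_error(check_equivariance(g, enc,
                                  list(rotation = diag(3) * 2,
                                       translation = rep(0, 3)), config = cfg),
               "orthogonal")
})

test_that("one-layer outputs are local: nodes away from a cut edge set are unaffected", {
  cfg <- tiny_config(n_layers = 1L)
  g <- random_molecule(9, seed = 44)$graph
  enc <- active_encoder(ncol(g$features), cfg, seed = 45)
  v <- 1L
  e <- g$edges
  nbrs <- unique(c(e$j[e$i == v], e$i[e$j == v]))
  keep <- e$i != v & e$j != v
  g2 <- molecule_graph("PROTAC", g$elements, g$coords, e[keep, ])
  g2$features <- g$features
  out <- encode_graph(g, enc, cfg)
  out2 <- encode_graph(g2, enc, cfg)
  untouched <- setdiff(seq_len(g$n), c(v, nbrs))
  expect_gt(length(untouched), 0)
  expect_equal(out2$H[untouched, ], out$H[untouched, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(out2$X[untouched, ], out$X[untouched, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("encoding is deterministic: repeated runs are bit-identical", {
  cfg <- tiny_config()
  g <- random_molecule(8, seed = 55)$graph
  enc <- active_encoder(ncol(g$features), cfg, seed = 56)
  o1 <- encode_graph(g, enc, cfg)
  o2 <- encode_graph(g, enc, cfg)
  expect_identical(o1$H, o2$H)
  expect_identical(o1$X, o2$X)
})

test_that("analytic model gradients match central finite differences", {
  cfg <- tiny_config(hidden_dim = 6L, attn_dim = 3L, fp_bits = 10L)
  sample <- make_tiny_sample(seed = 11, cfg = cfg)
  sample$desc_std <- sample$desc_std[1:4]
  sample$fp <- as.numeric(stats::runif(10) < 0.3)
  params <- active_model_params(cfg, k_desc = 4L, seed = 7)
  loss_fn <- function(p) {
    fwd <- protacdeg:::model_forward(sample, p, cfg, with_cache = TRUE)
    protacdeg:::model_backward(sample, fwd, 1L, p, cfg,
                               class_weight = 1.3)$loss
  }
  fwd <- protacdeg:::model_forward(sample, params, cfg, with_cache = TRUE)
  bwd <- protacdeg:::model_backward(sample, fwd, 1L, params, cfg,
                                    class_weight = 1.3)
  ga <- protacdeg:::tree_flatten(bwd$grads)
  v0 <- protacdeg:::tree_flatten(params)
  set.seed(123)
  idx <- sample(seq_along(v0), 150)
  h <- 1e-5
  gn <- vapply(idx, function(i) {
    vp <- v0; vp[i] <- vp[i] + h
    vm <- v0; vm[i] <- vm[i] - h
    (loss_fn(protacdeg:::tree_unflatten(params, vp)) -
       loss_fn(protacdeg:::tree_unflatten(params, vm))) / (2 * h)
  }, numeric(1))
  rel <- abs(gn - ga[idx]) / pmax(1e-6, abs(gn) + abs(ga[idx]))
  expect_lt(max(rel), 1e-4)
})

test_that("the batched union path reproduces the per-sample forward and backward", {
  cfg <- tiny_config()
  samples <- lapply(1:5, make_tiny_sample, cfg = cfg)
  y <- c(1, 0, 1, 0, 1)
  cw <- seq(0.6, 1.4, length.out = 5)
  params <- active_model_params(cfg, seed = 8)
  loss_ref <- 0; g_ref <- NULL; probs <- numeric(5)
  for (i in 1:5) {
    fwd <- protacdeg:::model_forward(samples[[i]], params, cfg,
                                     with_cache = TRUE)
    probs[i] <- fwd$prob_high
    bwd <- protacdeg:::model_backward(samples[[i]], fwd, y[i], params, cfg,
                                      class_weight = cw[i])
    loss_ref <- loss_ref + bwd$loss
    g_ref <- if (is.null(g_ref)) bwd$grads else
      protacdeg:::tree_add(g_ref, bwd$grads)
  }
  g_ref <- protacdeg:::tree_scale(g_ref, 1 / 5)
  bf <- protacdeg:::batch_forward(samples, params, cfg, with_cache = TRUE)
  bb <- protacdeg:::batch_backward(bf, y, params, cfg, class_weight = cw)
  expect_equal(bf$prob_high, probs, tolerance = 1e-12)
  expect_equal(bb$loss, loss_ref, tolerance = 1e-10)
  diff <- protacdeg:::tree_map2(function(a, b) max(abs(a - b)), g_ref,
                                bb$grads)
  expect_lt(protacdeg:::tree_max_abs(diff), 1e-10)
})
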