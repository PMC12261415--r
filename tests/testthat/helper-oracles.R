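# Independent oracle implementations used to cross-check the package code.
# Everything here is written against the formulas directly (explicit loops,
# no shared code with the implementation paths under test).

silu_ref <- function(x) x / (1 + exp(-x))

# Evaluate a two-layer perceptron exactly as a formula (no shared code).
mlp2_ref <- function(x, p) {
  z1 <- as.numeric(x %*% p$l1$W) + p$l1$b
  a1 <- if (p$act1 == "silu") silu_ref(z1) else z1
  z2 <- as.numeric(a1 %*% p$l2$W) + p$l2$b
  if (p$act2 == "silu") silu_ref(z2) else z2
}

# Naive double-loop evaluation of one equivariant message-passing layer:
# messages from edge attributes, endpoint features and squared distance;
# coordinate update along stabilized unit differences; feature update from
# the plain neighbour sum.
naive_egnn_layer <- function(H, X, edges_i, edges_j, eattr, lp,
                             eps = 1e-8, normalize = FALSE) {
  n <- nrow(H)
  d_msg <- length(lp$phi_e$l2$b)
  msgs <- matrix(0, n, d_msg)
  X_new <- X
  for (i in seq_len(n)) {
    nbr <- which(edges_i == i)
    delta <- c(0, 0, 0)
    for (k in nbr) {
      j <- edges_j[k]
      v <- X[i, ] - X[j, ]
      d2 <- sum(v^2)
      m_ij <- mlp2_ref(matrix(c(eattr[k, ], H[i, ], H[j, ], d2), 1), lp$phi_e)
      msgs[i, ] <- msgs[i, ] + m_ij
      s <- mlp2_ref(matrix(m_ij, 1), lp$phi_x)
      delta <- delta + v / (sqrt(d2) + eps) * s
    }
    if (normalize && length(nbr)) delta <- delta / length(nbr)
    X_new[i, ] <- X[i, ] + delta
  }
  H_new <- t(vapply(seq_len(n), function(i)
    mlp2_ref(matrix(c(H[i, ], msgs[i, ]), 1), lp$phi_h),
    numeric(length(lp$phi_h$l2$b))))
  list(H = H_new, X = X_new, messages = msgs)
}

# Direct evaluation of the mutual-attention pooling equations.
naive_pool <- function(H, f, pp) {
  da <- ncol(pp$WQ)
  n <- nrow(H)
  logits <- numeric(n)
  k <- as.numeric(f %*% pp$WK)
  for (i in seq_len(n)) {
    qi <- as.numeric(H[i, ] %*% pp$WQ)
    logits[i] <- sum(pp$a * tanh(c(qi, k)))
  }
  w <- exp(logits - max(logits)); w <- w / sum(w)
  z <- f
  for (i in seq_len(n)) z <- z + w[i] * H[i, ]
  list(z = z, w = w)
}

# Loop evaluation of the prototype update equations (soft assignment over
# samples by exponentiated cosine, additive update, renormalization).
naive_prototype_update <- function(protos, Z) {
  R <- nrow(protos)
  for (r in seq_len(R)) {
    u <- protos[r, ]
    sims <- numeric(nrow(Z))
    for (i in seq_len(nrow(Z)))
      sims[i] <- sum(Z[i, ] * u) / (sqrt(sum(Z[i, ]^2)) * sqrt(sum(u^2)))
    e <- exp(sims - max(sims)); w <- e / sum(e)
    u_new <- u
    for (i in seq_len(nrow(Z))) u_new <- u_new + w[i] * Z[i, ]
    protos[r, ] <- u_new / sqrt(sum(u_new^2))
  }
  protos
}

# Minimal independent mol2 reader: section scan with strsplit, no bio3d.
ref_read_mol2 <- function(path) {
  lines <- readLines(path)
  a0 <- grep("^@<TRIPOS>ATOM", lines)
  b0 <- grep("^@<TRIPOS>BOND", lines)
  sec_end <- function(start) {
    nxt <- grep("^@<TRIPOS>", lines)
    nxt <- nxt[nxt > start]
    if (length(nxt)) nxt[1] - 1 else length(lines)
  }
  atom_lines <- lines[(a0 + 1):sec_end(a0)]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  toks <- strsplit(trimws(atom_lines), "[ \t]+")
  atoms <- data.frame(
    id = vapply(toks, function(t) as.integer(t[1]), 1L),
    name = vapply(toks, `[`, "", 2),
    x = vapply(toks, function(t) as.numeric(t[3]), 1),
    y = vapply(toks, function(t) as.numeric(t[4]), 1),
    z = vapply(toks, function(t) as.numeric(t[5]), 1),
    type = vapply(toks, `[`, "", 6)
  )
  bond_lines <- lines[(b0 + 1):sec_end(b0)]
  bond_lines <- bond_lines[nzchar(trimws(bond_lines))]
  btoks <- strsplit(trimws(bond_lines), "[ \t]+")
  bonds <- data.frame(
    i = vapply(btoks, function(t) as.integer(t[2]), 1L),
    j = vapply(btoks, function(t) as.integer(t[3]), 1L),
    type = vapply(btoks, `[`, "", 4)
  )
  list(atoms = atoms, bonds = bonds)
}

# Independent fixed-column PDB coordinate reader (columns 31-54).
ref_read_pdb_coords <- function(path) {
  lines <- readLines(path)
  rec <- lines[grepl("^(ATOM|HETATM)", lines)]
  cbind(as.numeric(substr(rec, 31, 38)),
        as.numeric(substr(rec, 39, 46)),
        as.numeric(substr(rec, 47, 54)))
}

# Brute-force pocket selection: all-pairs distance scan, whole residues.
ref_pocket <- function(receptor, ligand, cutoff) {
  keep <- logical(0)
  for (rid in unique(receptor$residue_id)) {
    atoms <- receptor[receptor$residue_id == rid, ]
    hit <- FALSE
    for (a in seq_len(nrow(atoms))) for (b in seq_len(nrow(ligand))) {
      d <- sqrt((atoms$x[a] - ligand$x[b])^2 + (atoms$y[a] - ligand$y[b])^2 +
                  (atoms$z[a] - ligand$z[b])^2)
      if (d <= cutoff) hit <- TRUE
    }
    if (hit) keep <- c(keep, rid)
  }
  receptor[receptor$residue_id %in% keep, ]
}

# ---- shared fixtures --------------------------------------------------------

tiny_config <- function(...) {
  pdg_config(hidden_dim = 8L, n_layers = 2L, attn_dim = 4L, fp_bits = 32L,
             k_select = 4L, ...)
}

# Compact study configuration used by training-based checks.
study_config <- function(...) {
  pdg_config(hidden_dim = 32L, n_layers = 2L, attn_dim = 16L, fp_bits = 256L,
             ...)
}

make_pocket_graph <- function(kind = "POI", seed = 1L, n_residues = 3L) {
  pk <- random_pocket(n_residues, seed = seed, fraction_within = 1)
  poc <- extract_pocket(pk$receptor_atoms, pk$ligand_atoms, 5)
  build_protein_graph(poc, kind)
}

# A single in-memory ternary sample with random attribute inputs.
make_tiny_sample <- function(seed = 1L, cfg = tiny_config()) {
  set.seed(seed)
  list(
    entry_id = sprintf("T%03d", seed),
    graphs = list(PROTAC = random_molecule(6, seed = seed)$graph,
                  POI = make_pocket_graph("POI", seed + 100),
                  E3 = make_pocket_graph("E3", seed + 200)),
    desc_std = stats::rnorm(cfg$k_select),
    fp = as.numeric(stats::runif(cfg$fp_bits) < 0.3)
  )
}

# Encoder params with active (non-degenerate) coordinate gates.
active_encoder <- function(d_in, cfg, seed = 1L, scale = 0.3) {
  set.seed(seed)
  enc <- init_encoder_params(d_in, cfg$hidden_dim, cfg$n_layers)
  for (l in seq_along(enc$layers)) {
    W <- enc$layers[[l]]$phi_x$l2$W
    enc$layers[[l]]$phi_x$l2$W <- matrix(stats::rnorm(length(W), 0, scale),
                                         nrow(W))
  }
  enc
}

# Model params with active coordinate gates throughout.
active_model_params <- function(cfg, k_desc = cfg$k_select, seed = 1L) {
  params <- init_model_params(cfg, k_desc = k_desc, seed = seed)
  for (kind in c("PROTAC", "POI", "E3")) {
    for (l in seq_along(params$enc[[kind]]$layers)) {
      W <- params$enc[[kind]]$layers[[l]]$phi_x$l2$W
      params$enc[[kind]]$layers[[l]]$phi_x$l2$W <-
        matrix(stats::rnorm(length(W), 0, 0.3), nrow(W))
    }
  }
  params
}

# Lazily built shared datasets for training-based tests (built once per run).
.shared <- new.env()
shared_dataset <- function() {
  if (is.null(.shared$ds)) {
    .shared$ds <- planted_signal_dataset(80, seed = 424, config = study_config())
  }
  .shared$ds
}

shared_dataset_semi <- function() {
  if (is.null(.shared$ds_semi)) {
    .shared$ds_semi <- planted_signal_dataset(90, seed = 777,
                                              unlabeled_frac = 0.5,
                                              config = study_config())
  }
  .shared$ds_semi
}
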