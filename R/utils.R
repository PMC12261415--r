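#' @keywords internal
"_PACKAGE"

#' Default configuration
#'
#' Central configuration for graph construction, featurization, the
#' equivariant encoder, pooling, training, and pseudolabeling. Any entry can
#' be overridden by name; unknown names are rejected so typos fail loudly.
#'
#' @param ... named overrides of the defaults listed below.
#'
#' @details Key entries (units in parentheses):
#' \describe{
#'   \item{pocket_cutoff}{ligand-to-residue distance defining the binding
#'     pocket (Angstrom, default 5).}
#'   \item{inter_cutoff}{heavy-atom distance for inter-residue edges
#'     (Angstrom, default 4.5).}
#'   \item{intra_cutoff}{heavy-atom distance for intra-residue covalent
#'     edges (Angstrom, default 1.9).}
#'   \item{hidden_dim}{node embedding width d' (default 128).}
#'   \item{n_layers}{equivariant message-passing layers L (default 3).}
#'   \item{attn_dim}{attention projection width (default 64).}
#'   \item{fp_bits, fp_radius}{Morgan fingerprint length and radius.}
#'   \item{k_select}{descriptors kept by two-step feature selection.}
#'   \item{normalize_coord_update}{divide the coordinate update by the
#'     neighbour count (default FALSE: plain sum).}
#'   \item{lr, batch_size, max_epochs, patience, val_frac}{optimizer
#'     settings for supervised training.}
#'   \item{prototypes, epoch_window, pseudo_k}{memory-bank size R, number
#'     of recorded pretraining epochs T, and pseudolabel count K
#'     (NULL: K defaults to the labeled-set size).}
#' }
#' @return a named list of class `pdg_config`.
#' @export
pdg_config <- function(...) {
  cfg <- list(
    # graph construction
    pocket_cutoff = 5.0,
    inter_cutoff = 4.5,
    intra_cutoff = 1.9,
    keep_hydrogens = FALSE,
    # featurization
    fp_radius = 2L,
    fp_bits = 2048L,
    k_select = 6L,
    chi2_keep = 9L,
    gbdt_nrounds = 100L,
    gbdt_depth = 3L,
    gbdt_eta = 0.1,
    # encoder
    hidden_dim = 128L,
    n_layers = 3L,
    attn_dim = 64L,
    eps = 1e-8,
    normalize_coord_update = FALSE,
    # ablation switches
    use_feature_selection = TRUE,
    use_attention_pooling = TRUE,
    use_equivariant = TRUE,
    # training
    lr = 1e-3,
    batch_size = 50L,
    max_epochs = 200L,
    patience = 20L,
    min_epochs = 50L,
    val_frac = 0.1,
    threshold = 0.5,
    # pseudolabeling
    prototypes = 4L,
    epoch_window = 10L,
    pretrain_epochs = 60L,
    pseudo_k = NULL,
    invert_disagreement = FALSE
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "pdg_config")
}

#' Read a configuration from YAML
#'
#' @param path YAML file whose top-level keys override [pdg_config()] defaults.
#' @return a `pdg_config` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pdg_config, vals)
}

# 32-bit FNV-1a over a character string, exact in double arithmetic.
# Used for fingerprint environment hashing and config hashes.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b)
    h <- mulmod32(h, 16777619)
  }
  h
}

xor32 <- function(a, b) {
  # bitwXor works on 32-bit signed ints; route through [0, 2^32)
  ai <- a %% 4294967296; bi <- b %% 4294967296
  hi <- bitwXor(ai %/% 65536, bi %/% 65536)
  lo <- bitwXor(ai %% 65536, bi %% 65536)
  hi * 65536 + lo
}

mulmod32 <- function(a, p) {
  a <- a %% 4294967296
  lo <- a %% 65536
  hi <- a %/% 65536
  (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
}

# Short hex hash of an R object's canonical JSON form (config provenance).
config_hash <- function(x) {
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  h <- fnv1a32(as.character(js))
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

pairwise_dist <- function(a, b = a) {
  # a: n x 3, b: m x 3 -> n x m Euclidean distances
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
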