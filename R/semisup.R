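# Memory-enhanced pseudolabeling. After pretraining on the labeled set,
# per-epoch predictions over a trailing window are recorded for every
# unlabeled training entry. Each candidate is scored by (a) the
# disagreement score: the entropy of its epoch-prediction distribution
# (higher = stronger candidate, as specified; a config flag inverts the
# convention), and (b) the memory score: maximum cosine similarity between
# its latent embedding and a bank of prototypes summarizing the labeled
# latent space. The top-K by the combined score enter retraining with
# their majority-vote labels.

#' Disagreement score of epoch predictions
#'
#' The entropy (natural log) of the relative class frequencies across the
#' recorded epochs: 0 when every epoch agrees, ln 2 for a 50/50 split over
#' two classes.
#'
#' @param epoch_labels vector of per-epoch predicted classes (any atomic
#'   type; at least one epoch).
#' @return nonnegative entropy.
#' @export
disagreement_score <- function(epoch_labels) {
  stopifnot(length(epoch_labels) >= 1)
  p <- table(epoch_labels) / length(epoch_labels)
  p <- p[p > 0]
  -sum(p * log(p))
}

cosine_sim <- function(a, b) {
  sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

#' Initialize a memory bank with k-means++ seeding
#'
#' Prototypes are drawn from the labeled embeddings by the k-means++
#' rule (first uniformly, then proportional to squared distance from the
#' nearest chosen prototype) and normalized to unit length.
#'
#' @param embeddings matrix of labeled latent embeddings (rows = samples).
#' @param R number of prototypes.
#' @param seed RNG seed.
#' @return a `memory_bank`: list with `prototypes` (R x d) and `R`.
#' @export
init_memory_bank <- function(embeddings, R = 4L, seed = 1L) {
  stopifnot(R >= 1, nrow(embeddings) >= 1)
  set.seed(seed)
  n <- nrow(embeddings)
  centers <- integer(R)
  centers[1] <- sample.int(n, 1)
  if (R > 1) for (r in 2:R) {
    d2 <- apply(embeddings, 1, function(z)
      min(vapply(centers[seq_len(r - 1)], function(c_)
        sum((z - embeddings[c_, ])^2), numeric(1))))
    if (all(d2 == 0)) centers[r] <- sample.int(n, 1)
    else centers[r] <- sample.int(n, 1, prob = d2 / sum(d2))
  }
  protos <- embeddings[centers, , drop = FALSE]
  nrm <- sqrt(rowSums(protos^2))
  nrm[nrm == 0] <- 1
  structure(list(prototypes = protos / nrm, R = R), class = "memory_bank")
}

#' Update memory prototypes from labeled embeddings
#'
#' One accumulation step: per prototype, soft assignment weights over the
#' labeled samples (softmax across samples of the cosine similarity), an
#' additive update by the weighted embedding sum, and renormalization to
#' unit length (the raw accumulation is unbounded otherwise).
#'
#' @param bank a `memory_bank`.
#' @param embeddings labeled latent embeddings (rows = samples); zero-norm
#'   rows are excluded with a warning.
#' @return the updated `memory_bank`.
#' @export
update_prototypes <- function(bank, embeddings) {
  nrm <- sqrt(rowSums(embeddings^2))
  if (any(nrm == 0)) {
    warning(sum(nrm == 0), " zero-norm embedding(s) excluded from the ",
            "prototype update (cosine undefined)")
    embeddings <- embeddings[nrm > 0, , drop = FALSE]
    if (!nrow(embeddings)) return(bank)
  }
  for (r in seq_len(bank$R)) {
    u <- bank$prototypes[r, ]
    cs <- apply(embeddings, 1, cosine_sim, b = u)
    w <- softmax_vec(cs)
    u_new <- u + drop(crossprod(embeddings, w))
    bank$prototypes[r, ] <- u_new / sqrt(sum(u_new^2))
  }
  bank
}

#' Memory score of an unlabeled embedding
#'
#' Maximum cosine similarity between the embedding and the bank's
#' prototypes; lies in [-1, 1].
#'
#' @param z latent embedding (nonzero).
#' @param bank a `memory_bank`.
#' @return the score.
#' @export
memory_score <- function(z, bank) {
  if (sqrt(sum(z^2)) == 0) stop("zero-norm embedding: cosine undefined")
  max(apply(bank$prototypes, 1, cosine_sim, b = z))
}

#' Select the top-K pseudolabel candidates
#'
#' Ranks records by the combined score `s = (s_dis + s_mem) / 2` (exact
#' arithmetic on the stored scores) and returns the K highest with their
#' majority-vote labels (ties broken by the latest epoch's prediction).
#' Ordering is stable: equal scores resolve by entry id.
#'
#' @param records tibble with `entry_id`, `s_dis`, `s_mem` and a list
#'   column `epoch_labels` (0/1 per recorded epoch).
#' @param K number to select; 0 selects nothing; K above the pool size
#'   selects everything with a warning.
#' @return tibble with `entry_id`, `pseudolabel` (0/1) and `s`, in
#'   selection order.
#' @export
select_pseudolabels <- function(records, K) {
  if (K == 0 || !nrow(records)) {
    return(tibble::tibble(entry_id = character(0), pseudolabel = integer(0),
                          s = numeric(0)))
  }
  if (K > nrow(records)) {
    warning("K = ", K, " exceeds the ", nrow(records),
            " available records; selecting all")
    K <- nrow(records)
  }
  s <- (records$s_dis + records$s_mem) / 2
  ord <- order(-s, records$entry_id)
  pick <- ord[seq_len(K)]
  lab <- vapply(records$epoch_labels[pick], function(m) {
    tab <- table(m)
    if (length(tab) > 1 && tab[1] == tab[2]) return(as.integer(m[length(m)]))
    as.integer(names(tab)[which.max(tab)])
  }, integer(1))
  tibble::tibble(entry_id = records$entry_id[pick], pseudolabel = lab, s = s[pick])
}

#' Memory-enhanced semisupervised training loop
#'
#' (1) pretrains the model on the labeled training entries; (2) over the
#' trailing window of pretraining epochs, records predictions and latent
#' embeddings for the unlabeled pool and labeled embeddings for the
#' memory bank; (3) scores every unlabeled entry by disagreement and
#' memory similarity and selects the top K; (4) retrains from scratch on
#' the labeled entries plus the pseudolabeled selection. Test entries are
#' never scored or selected: the unlabeled pool contains only entries with
#' no activity annotation, and the split holds labeled entries only. With
#' `K = 0` or an empty unlabeled pool the result is bit-identical to
#' [train_supervised()] under the same seed.
#'
#' @param dataset a `pdg_dataset`.
#' @param split a `split_manifest`; its `train_ids` form the labeled set.
#' @param config a [pdg_config()].
#' @param seed RNG seed (shared by pretraining and retraining).
#' @param K pseudolabel count; `NULL` uses `config$pseudo_k`, and if that
#'   is also `NULL`, the labeled-set size.
#' @return list with `model` (the retrained `pdg_model`), `audit`
#'   (per-candidate score tibble), `pretrain_history`, `bank`, and
#'   `scored_ids` (instrumentation: every id that was scored).
#' @export
semisupervised_loop <- function(dataset, split, config = pdg_config(),
                                seed = 1L, K = NULL) {
  sl_ids <- split$train_ids
  if (!length(sl_ids)) stop("labeled training set is empty")
  su_ids <- dataset$manifest$entry_id[dataset$manifest$label == "unlabeled"]
  K <- K %||% config$pseudo_k %||% length(sl_ids)
  empty_audit <- tibble::tibble(entry_id = character(0), s_dis = numeric(0),
                                s_mem = numeric(0), s = numeric(0),
                                selected = logical(0),
                                pseudolabel = integer(0))
  if (K == 0 || !length(su_ids)) {
    model <- train_supervised(dataset, sl_ids, config, seed = seed)
    return(list(model = model, audit = empty_audit,
                pretrain_history = NULL, bank = NULL,
                scored_ids = character(0)))
  }

  # ---- pretraining with recording ------------------------------------------
  y_sl <- sample_labels(dataset, sl_ids)
  desc_tab <- dataset$descriptors[match(sl_ids, dataset_ids(dataset)), ,
                                  drop = FALSE]
  if (isTRUE(config$use_feature_selection) && length(unique(y_sl)) > 1) {
    mask <- select_features(desc_tab, y_sl, k = config$k_select,
                            chi2_keep = config$chi2_keep, seed = seed,
                            nrounds = config$gbdt_nrounds,
                            max_depth = config$gbdt_depth,
                            eta = config$gbdt_eta)$mask
  } else {
    mask <- stats::setNames(rep(TRUE, ncol(desc_tab)), colnames(desc_tab))
  }
  std <- standardize_descriptors(as.matrix(desc_tab)[, mask, drop = FALSE])
  sl_samples <- prepare_features(subset_samples(dataset, sl_ids), mask,
                                 std$stats)
  su_samples <- prepare_features(subset_samples(dataset, su_ids), mask,
                                 std$stats)

  pre_cfg <- config
  pre_cfg$max_epochs <- config$pretrain_epochs
  pre_cfg$val_frac <- 0
  window <- min(config$epoch_window, pre_cfg$max_epochs)
  params <- init_model_params(pre_cfg, k_desc = sum(mask), seed = seed)
  pre <- fit_loop(sl_samples, y_sl, params, pre_cfg, seed,
                  record_samples = c(sl_samples, su_samples),
                  record_window = window)

  n_sl <- length(sl_samples)
  # labeled embeddings per recorded epoch; unlabeled predictions/embeddings
  sl_emb <- lapply(pre$records, function(r)
    r$Z[seq_len(n_sl), , drop = FALSE])
  su_pred <- lapply(pre$records, function(r)
    as.integer(r$prob_high[n_sl + seq_along(su_samples)] >= config$threshold))
  su_emb_final <- pre$records[[length(pre$records)]]$Z[
    n_sl + seq_along(su_samples), , drop = FALSE]

  # ---- memory bank ----------------------------------------------------------
  bank <- init_memory_bank(sl_emb[[length(sl_emb)]],
                           R = config$prototypes, seed = seed)
  for (t in seq_along(sl_emb)) bank <- update_prototypes(bank, sl_emb[[t]])

  # ---- scoring --------------------------------------------------------------
  epoch_mat <- do.call(cbind, su_pred)      # |Su| x window
  s_dis <- apply(epoch_mat, 1, disagreement_score)
  if (isTRUE(config$invert_disagreement)) s_dis <- log(2) - s_dis
  s_mem <- vapply(seq_along(su_ids), function(k)
    memory_score(su_emb_final[k, ], bank), numeric(1))
  records <- tibble::tibble(
    entry_id = su_ids,
    s_dis = s_dis,
    s_mem = s_mem,
    epoch_labels = lapply(seq_along(su_ids), function(k) epoch_mat[k, ])
  )
  sel <- select_pseudolabels(records, K)

  audit <- tibble::tibble(
    entry_id = records$entry_id,
    epoch_labels = vapply(records$epoch_labels, paste, character(1),
                          collapse = ""),
    s_dis = records$s_dis,
    s_mem = records$s_mem,
    s = (records$s_dis + records$s_mem) / 2,
    selected = records$entry_id %in% sel$entry_id,
    pseudolabel = sel$pseudolabel[match(records$entry_id, sel$entry_id)]
  )

  # ---- retraining from scratch ---------------------------------------------
  all_ids <- c(sl_ids, sel$entry_id)
  labels <- stats::setNames(c(y_sl, sel$pseudolabel), all_ids)
  model <- train_supervised(dataset, all_ids, config, seed = seed,
                            labels = labels)
  list(model = model, audit = audit, pretrain_history = pre$history,
       bank = bank, scored_ids = records$entry_id)
}

#' Write the pseudolabel audit CSV
#'
#' @param audit the audit tibble from [semisupervised_loop()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pseudolabel_audit <- function(audit, path) {
  utils::write.csv(audit, path, row.names = FALSE, na = "")
  invisible(path)
}
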