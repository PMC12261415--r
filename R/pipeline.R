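# Dataset-level operations: the DC50/Dmax labeling rule, leakage-aware
# 80/20 splitting with canonical-SMILES duplicate exclusion, evaluation
# metrics, supervised training with Adam and early stopping, prediction,
# and the ablation switches.

#' Assign a degradation-activity label from DC50/Dmax annotations
#'
#' A PROTAC has low degradation activity iff DC50 >= 100 nM and
#' Dmax < 80%; otherwise it is high. With a single annotation present the
#' conjunction degenerates to the available clause (only DC50: low iff
#' >= 100 nM; only Dmax: low iff < 80%). With neither, the entry is
#' unlabeled.
#'
#' @param dc50 half-maximal degradation concentration in nM, or `NA`.
#' @param dmax maximum degradation percentage in [0, 100], or `NA`.
#' @return `"high"`, `"low"` or `"unlabeled"`.
#' @export
assign_activity_label <- function(dc50, dmax) {
  if (!is.na(dc50) && dc50 < 0)
    stop("validation error: negative dc50 (", dc50, ")")
  if (!is.na(dmax) && (dmax < 0 || dmax > 100))
    stop("validation error: dmax outside [0, 100] (", dmax, ")")
  if (is.na(dc50) && is.na(dmax)) return("unlabeled")
  low <- (is.na(dc50) || dc50 >= 100) && (is.na(dmax) || dmax < 80)
  if (low) "low" else "high"
}

#' Leakage-aware random train/test split
#'
#' Randomly splits the labeled records 80/20 (by `ratio`), then moves any
#' test record sharing both the target protein and the canonical PROTAC
#' SMILES with a training record into `excluded_ids`. Deterministic given
#' `seed`.
#'
#' @param records tibble with columns `entry_id`, `smiles`, `poi_id` and
#'   `label` (`"high"`/`"low"`/`"unlabeled"`); unlabeled records are
#'   ignored.
#' @param ratio training fraction (default 0.8).
#' @param seed RNG seed.
#' @param canonicalize canonicalize SMILES before duplicate matching
#'   (default TRUE; disable for inputs already canonical).
#' @return list of class `split_manifest`: `train_ids`, `test_ids`,
#'   `excluded_ids`, `seed`.
#' @export
make_split <- function(records, ratio = 0.8, seed = 1L, canonicalize = TRUE) {
  labeled <- records[records$label %in% c("high", "low"), , drop = FALSE]
  if (nrow(labeled) < 2) stop("need at least 2 labeled records to split")
  set.seed(seed)
  n <- nrow(labeled)
  perm <- sample.int(n)
  n_train <- floor(ratio * n)
  train_idx <- perm[seq_len(n_train)]
  test_idx <- perm[-seq_len(n_train)]
  smi <- if (canonicalize) canonical_smiles(labeled$smiles) else labeled$smiles
  key <- paste(labeled$poi_id, smi, sep = "|")
  leaky <- key[test_idx] %in% key[train_idx]
  split <- structure(list(
    train_ids = labeled$entry_id[train_idx],
    test_ids = labeled$entry_id[test_idx[!leaky]],
    excluded_ids = labeled$entry_id[test_idx[leaky]],
    seed = seed
  ), class = "split_manifest")
  if (!length(split$test_ids))
    stop("split error: all test records excluded as duplicates; try another seed")
  split
}

#' Classification metrics: accuracy, AUROC, F1
#'
#' Accuracy at the decision threshold, AUROC by the rank (Mann-Whitney)
#' method with half credit for ties, and F1 on the high class.
#'
#' @param prob predicted probability of the high class.
#' @param labels true labels, 0/1 (1 = high).
#' @param threshold decision threshold (default 0.5).
#' @return list with `accuracy`, `auroc`, `f1`, `n`.
#' @export
evaluate_predictions <- function(prob, labels, threshold = 0.5) {
  stopifnot(length(prob) == length(labels))
  y <- as.integer(labels)
  if (length(unique(y)) < 2)
    stop("AUROC undefined: labels contain a single class")
  pred <- as.integer(prob >= threshold)
  acc <- mean(pred == y)
  r <- rank(prob)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  auroc <- (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  list(accuracy = acc, auroc = auroc, f1 = f1, n = length(y))
}

# ---- training ---------------------------------------------------------------

# Label vector (0/1) for a set of samples, from the manifest.
sample_labels <- function(ds, ids) {
  lab <- ds$manifest$label[match(ids, ds$manifest$entry_id)]
  ifelse(lab == "high", 1L, ifelse(lab == "low", 0L, NA_integer_))
}

dataset_ids <- function(ds) vapply(ds$samples, `[[`, character(1), "entry_id")

subset_samples <- function(ds, ids) {
  ds$samples[match(ids, dataset_ids(ds))]
}

# Attach standardized selected descriptors to samples (training statistics
# only; stats and mask travel with the fitted model).
prepare_features <- function(samples, mask, stats) {
  lapply(samples, function(s) {
    s$desc_std <- as.numeric((s$desc[mask] - stats$center) / stats$scale)
    s
  })
}

# Core minibatch-Adam loop over the batched forward/backward. Returns
# params, history, and optionally recorded per-epoch predictions and
# latent embeddings for `record_samples`. Early stopping on validation
# AUROC activates after `min_epochs` (a short warm-up guards against
# restoring a noise-favoured early checkpoint from a small validation set).
fit_loop <- function(train_samples, train_y, params, config, seed,
                     val_samples = NULL, val_y = NULL,
                     record_samples = NULL, record_window = 0L,
                     log_path = NULL) {
  set.seed(seed + 1L)
  n <- length(train_samples)
  n_pos <- sum(train_y == 1); n_neg <- sum(train_y == 0)
  w_pos <- n / (2 * max(n_pos, 1)); w_neg <- n / (2 * max(n_neg, 1))
  cw <- ifelse(train_y == 1, w_pos, w_neg)
  opt <- adam_init(params)
  history <- list()
  best <- list(auroc = -Inf, params = params, epoch = 0L)
  records <- list()
  n_epochs <- config$max_epochs
  since_best <- 0L
  for (epoch in seq_len(n_epochs)) {
    perm <- sample.int(n)
    batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
    ep_loss <- 0
    for (b in batches) {
      fwd <- batch_forward(train_samples[b], params, config, with_cache = TRUE)
      bwd <- batch_backward(fwd, train_y[b], params, config,
                            class_weight = cw[b])
      ep_loss <- ep_loss + bwd$loss
      if (!is.finite(bwd$loss) || !is.finite(tree_max_abs(bwd$grads)))
        stop("NaN loss/gradient at epoch ", epoch, "; aborting")
      step <- adam_step(params, bwd$grads, opt, lr = config$lr)
      params <- step$params; opt <- step$state
    }
    ep <- list(epoch = epoch, loss = ep_loss / n)
    if (length(val_samples)) {
      vp <- batch_predict(val_samples, params, config)
      if (length(unique(val_y)) > 1) {
        ep$val_auroc <- evaluate_predictions(vp, val_y)$auroc
      } else ep$val_auroc <- NA_real_
      if (epoch >= config$min_epochs) {
        if (!is.na(ep$val_auroc) && ep$val_auroc > best$auroc + 1e-12) {
          best <- list(auroc = ep$val_auroc, params = params, epoch = epoch)
          since_best <- 0L
        } else since_best <- since_best + 1L
      }
    }
    history[[epoch]] <- ep
    if (!is.null(log_path))
      cat(jsonlite::toJSON(ep, auto_unbox = TRUE, digits = 6), "\n",
          file = log_path, append = TRUE)
    if (record_window > 0 && epoch > n_epochs - record_window) {
      fw <- batch_forward(record_samples, params, config)
      records[[length(records) + 1]] <-
        list(epoch = epoch, prob_high = fw$prob_high, Z = fw$Z)
    }
    if (length(val_samples) && since_best >= config$patience) break
  }
  if (length(val_samples) && is.finite(best$auroc)) {
    params <- best$params
  }
  hist_df <- tibble::tibble(
    epoch = vapply(history, `[[`, numeric(1), "epoch"),
    loss = vapply(history, `[[`, numeric(1), "loss"),
    val_auroc = vapply(history, function(h) h$val_auroc %||% NA_real_,
                       numeric(1))
  )
  list(params = params, history = hist_df, records = records,
       best_epoch = if (is.finite(best$auroc)) best$epoch else nrow(hist_df))
}

#' Train the supervised model
#'
#' Runs feature selection and descriptor standardization on the training
#' split, initializes all parameters from `seed`, and minimizes
#' class-weighted cross-entropy with Adam (inverse-frequency class
#' weights). A validation carve-out from the training set drives early
#' stopping on validation AUROC. Two runs with the same seed, data and
#' configuration are bit-identical.
#'
#' @param dataset a `pdg_dataset`.
#' @param train_ids entry ids to train on (labeled). Defaults to all
#'   labeled entries.
#' @param config a [pdg_config()].
#' @param seed RNG seed controlling initialization, the validation
#'   carve-out and batch order.
#' @param labels optional named 0/1 vector overriding manifest labels
#'   (used by the pseudolabel retraining step).
#' @param log_path optional JSONL file receiving per-epoch metrics.
#' @return a `pdg_model`: parameters, config, selection mask and
#'   standardization statistics, training history, and a config hash.
#' @export
train_supervised <- function(dataset, train_ids = NULL,
                             config = pdg_config(), seed = 1L,
                             labels = NULL, log_path = NULL) {
  ids_all <- dataset_ids(dataset)
  if (is.null(train_ids)) {
    lab <- dataset$manifest$label
    train_ids <- dataset$manifest$entry_id[lab %in% c("high", "low")]
  }
  if (!length(train_ids)) stop("empty labeled training set")
  y <- if (is.null(labels)) sample_labels(dataset, train_ids) else
    unname(labels[train_ids])
  if (any(is.na(y))) stop("unlabeled entries in the training set")

  # feature selection + standardization on training data only
  desc_tab <- dataset$descriptors[match(train_ids, ids_all), , drop = FALSE]
  if (isTRUE(config$use_feature_selection) &&
      length(unique(y)) > 1) {
    sel <- select_features(desc_tab, y, k = config$k_select,
                           chi2_keep = config$chi2_keep, seed = seed,
                           nrounds = config$gbdt_nrounds,
                           max_depth = config$gbdt_depth,
                           eta = config$gbdt_eta)
    mask <- sel$mask
    sel_report <- sel$report
  } else {
    mask <- stats::setNames(rep(TRUE, ncol(desc_tab)), colnames(desc_tab))
    sel_report <- NULL
  }
  std <- standardize_descriptors(as.matrix(desc_tab)[, mask, drop = FALSE])

  train_samples <- prepare_features(subset_samples(dataset, train_ids),
                                    mask, std$stats)
  # validation carve-out
  set.seed(seed)
  n <- length(train_samples)
  n_val <- floor(config$val_frac * n)
  val_idx <- if (n_val >= 2) sample.int(n, n_val) else integer(0)
  fit_idx <- setdiff(seq_len(n), val_idx)

  params <- init_model_params(config, k_desc = sum(mask), seed = seed)
  fit <- fit_loop(train_samples[fit_idx], y[fit_idx], params, config, seed,
                  val_samples = train_samples[val_idx], val_y = y[val_idx],
                  log_path = log_path)
  structure(list(
    params = fit$params,
    config = config,
    mask = mask,
    desc_stats = std$stats,
    selection_report = sel_report,
    history = fit$history,
    best_epoch = fit$best_epoch,
    train_ids = train_ids,
    seed = seed,
    config_hash = config_hash(unclass(config))
  ), class = "pdg_model")
}

#' @export
print.pdg_model <- function(x, ...) {
  cat(sprintf("<pdg_model: d'=%d, L=%d, %d epochs trained, config %s>\n",
              x$config$hidden_dim, x$config$n_layers, nrow(x$history),
              x$config_hash))
  invisible(x)
}

#' Predict degradation probabilities
#'
#' @param object a fitted `pdg_model`.
#' @param dataset a `pdg_dataset`.
#' @param ids entry ids to score (default: all).
#' @param ... unused.
#' @return tibble with `entry_id`, `prob_high` and `pred` (at the
#'   configured threshold).
#' @export
predict.pdg_model <- function(object, dataset, ids = NULL, ...) {
  ids <- ids %||% dataset_ids(dataset)
  samples <- prepare_features(subset_samples(dataset, ids), object$mask,
                              object$desc_stats)
  prob <- batch_predict(samples, object$params, object$config)
  tibble::tibble(
    entry_id = ids,
    prob_high = prob,
    pred = ifelse(prob >= object$config$threshold, "high", "low")
  )
}

#' Evaluate a model on a held-out id set
#'
#' @param model a `pdg_model`.
#' @param dataset a `pdg_dataset`.
#' @param ids held-out entry ids (labeled).
#' @return a one-row tibble with accuracy, AUROC and F1.
#' @export
evaluate_model <- function(model, dataset, ids) {
  pr <- predict(model, dataset, ids)
  y <- sample_labels(dataset, ids)
  m <- evaluate_predictions(pr$prob_high, y, model$config$threshold)
  tibble::tibble(accuracy = m$accuracy, auroc = m$auroc, f1 = m$f1, n = m$n)
}

#' Ablation study over the model's switchable components
#'
#' Each toggle substitutes its documented fallback: `feature_selection`
#' off uses all descriptors; `attention_pooling` off uses mean pooling;
#' `equivariant_encoder` off removes all coordinate dependence from the
#' encoder; `label_enrichment` off sets the pseudolabel count K to 0.
#'
#' @param dataset a `pdg_dataset`.
#' @param split a `split_manifest`.
#' @param toggles character vector of components to disable (may be empty).
#' @param config base configuration.
#' @param seed RNG seed shared by all variants.
#' @param semi run the semisupervised loop (required for the
#'   `label_enrichment` toggle to matter).
#' @return tibble with one row per variant (full model first) and the
#'   test metrics.
#' @export
ablation_run <- function(dataset, split, toggles = character(0),
                         config = pdg_config(), seed = 1L, semi = FALSE) {
  known <- c("feature_selection", "attention_pooling",
             "equivariant_encoder", "label_enrichment")
  bad <- setdiff(toggles, known)
  if (length(bad)) stop("unknown toggle(s): ", paste(bad, collapse = ", "))
  variants <- c(list(full = character(0)),
                stats::setNames(lapply(toggles, identity), toggles))
  out <- lapply(names(variants), function(vn) {
    off <- variants[[vn]]
    cfg <- config
    if ("feature_selection" %in% off) cfg$use_feature_selection <- FALSE
    if ("attention_pooling" %in% off) cfg$use_attention_pooling <- FALSE
    if ("equivariant_encoder" %in% off) cfg$use_equivariant <- FALSE
    k_override <- if ("label_enrichment" %in% off) 0L else NULL
    model <- if (semi) {
      semisupervised_loop(dataset, split, config = cfg, seed = seed,
                          K = k_override)$model
    } else {
      train_supervised(dataset, split$train_ids, cfg, seed = seed)
    }
    cbind(tibble::tibble(variant = vn),
          evaluate_model(model, dataset, split$test_ids))
  })
  do.call(rbind, out)
}
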