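# Text checkpointing (JSON with an embedded config hash) and the
# edge-attention export used for interpretability.

#' Save / load a fitted model checkpoint
#'
#' The checkpoint is a single JSON file holding every parameter tensor,
#' the configuration (with its hash), the descriptor selection mask and
#' standardization statistics. Loading verifies the embedded hash.
#'
#' @param model a `pdg_model`.
#' @param path checkpoint file.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  obj <- list(
    params = model$params,
    config = unclass(model$config),
    config_hash = model$config_hash,
    mask = as.list(model$mask),
    desc_stats = model$desc_stats,
    seed = model$seed,
    best_epoch = model$best_epoch
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

# Rebuild numeric leaves from the un-simplified JSON tree against the
# template parameter tree (JSON stores matrices row-major).
restore_tree <- function(template, loaded) {
  if (is_leaf(template)) {
    v <- as.numeric(unlist(loaded))
    if (is.matrix(template))
      return(matrix(v, nrow(template), ncol(template), byrow = TRUE))
    return(v)
  }
  if (is.list(template)) {
    out <- template
    for (k in seq_along(template)) {
      nm <- names(template)[k]
      src <- if (!is.null(nm) && nm %in% names(loaded)) loaded[[nm]]
        else loaded[[k]]
      out[[k]] <- restore_tree(template[[k]], src)
    }
    return(out)
  }
  template
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg_vals <- lapply(obj$config, function(v) if (is.list(v)) unlist(v) else v)
  config <- do.call(pdg_config, cfg_vals)
  if (config_hash(unclass(config)) != obj$config_hash)
    warning("checkpoint config hash mismatch; file may have been edited")
  mask <- unlist(obj$mask)
  if (!is.logical(mask)) mask <- as.logical(mask)
  template <- init_model_params(config, k_desc = sum(mask), seed = 1L)
  params <- restore_tree(template, obj$params)
  structure(list(
    params = params,
    config = config,
    mask = mask,
    desc_stats = list(center = unlist(obj$desc_stats$center),
                      scale = unlist(obj$desc_stats$scale)),
    history = NULL,
    best_epoch = obj$best_epoch,
    seed = obj$seed,
    config_hash = unlist(obj$config_hash)
  ), class = "pdg_model")
}

#' Export edge-attention annotations for a sample
#'
#' Writes the per-edge attention map as CSV and, for the PROTAC graph, an
#' annotated mol2 copy carrying each atom's attention weight in the charge
#' field so external viewers can color by it.
#'
#' @param model a fitted `pdg_model`.
#' @param dataset a `pdg_dataset`.
#' @param entry_id the entry to explain.
#' @param dir output directory.
#' @return tibble of per-graph edge attention maps, invisibly; files
#'   `<entry>_attention_<kind>.csv` and `<entry>_attention.mol2` in `dir`.
#' @export
export_attention <- function(model, dataset, entry_id, dir = ".") {
  s <- prepare_features(subset_samples(dataset, entry_id), model$mask,
                        model$desc_stats)[[1]]
  fwd <- model_forward(s, model$params, model$config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  maps <- list()
  for (kind in GRAPH_KINDS) {
    am <- edge_attention_map(s$graphs[[kind]], fwd$weights[[kind]])
    utils::write.csv(am, file.path(dir, sprintf("%s_attention_%s.csv",
                                                entry_id, kind)),
                     row.names = FALSE)
    maps[[kind]] <- am
  }
  g <- s$graphs$PROTAC
  lines <- render_mol2_charges(g, fwd$weights$PROTAC,
                               name = paste0(entry_id, "_attention"))
  writeLines(lines, file.path(dir, paste0(entry_id, "_attention.mol2")))
  invisible(maps)
}

render_mol2_charges <- function(g, charges, name = "mol") {
  e <- g$edges
  order_code <- c(single = "1", double = "2", triple = "3", aromatic = "ar")
  lines <- c(
    "@<TRIPOS>MOLECULE", name,
    sprintf("%d %d 0 0 0", g$n, nrow(e)),
    "SMALL", "USER_CHARGES", "", "@<TRIPOS>ATOM",
    sprintf("%7d %-4s %10.4f %10.4f %10.4f %-5s %3d LIG %8.4f",
            seq_len(g$n), paste0(g$elements, seq_len(g$n)),
            g$coords[, 1], g$coords[, 2], g$coords[, 3],
            g$elements, 1L, charges),
    "@<TRIPOS>BOND"
  )
  if (nrow(e))
    lines <- c(lines, sprintf("%6d %5d %5d %s", seq_len(nrow(e)), e$i, e$j,
                              order_code[e$order]))
  lines
}
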