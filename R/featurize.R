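# Per-atom input features, PROTAC chemical descriptors, two-step feature
# selection, Morgan fingerprints, and the fused attribute vector.

ELEMENT_CLASSES <- c("C", "N", "O", "S", "P", "halogen", "other")

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

#' Documented atom-feature layout
#'
#' @param which `"atom"` for node features, `"edge"` for edge attributes.
#' @return character vector naming each feature position.
#' @export
feature_layout <- function(which = c("atom", "edge")) {
  which <- match.arg(which)
  if (which == "edge") return(EDGE_ATTR_NAMES)
  c(paste0("elem_", ELEMENT_CLASSES), "degree", "aromatic", "in_ring",
    paste0("res_", AA3), "res_other")
}

classify_element <- function(el) {
  out <- ifelse(el %in% c("C", "N", "O", "S", "P"), el,
                ifelse(el %in% HALOGENS, "halogen", "other"))
  unknown <- !(el %in% c("C", "N", "O", "S", "P", HALOGENS)) &
    !grepl("^[A-Z][a-z]?$", el)
  if (any(unknown))
    warning("unknown element symbol(s) mapped to 'other': ",
            paste(unique(el[unknown]), collapse = ", "))
  out
}

# Atoms inside a cycle of the covalent graph = members of its 2-core
# (iteratively prune degree-1 vertices; whatever survives lies on a cycle).
ring_membership <- function(n, ei, ej) {
  deg <- tabulate(c(ei, ej), nbins = n)
  alive <- rep(TRUE, n)
  repeat {
    leaf <- which(alive & deg == 1)
    if (!length(leaf)) break
    alive[leaf] <- FALSE
    for (k in seq_along(ei)) {
      if ((ei[k] %in% leaf && alive[ej[k]]) ) deg[ej[k]] <- deg[ej[k]] - 1
      if ((ej[k] %in% leaf && alive[ei[k]]) ) deg[ei[k]] <- deg[ei[k]] - 1
    }
    deg[leaf] <- 0
  }
  alive & deg >= 2
}

#' Per-atom input features
#'
#' Deterministic feature vector per atom: element-class one-hot
#' (C,N,O,S,P,halogen,other), graph degree, aromatic flag (atom on an
#' aromatic bond), in-ring flag (atom in the 2-core of the covalent graph),
#' and a residue-type one-hot (20 standard amino acids + other) that is all
#' zero for small-molecule atoms. The ordering is fixed and documented by
#' [feature_layout()].
#'
#' @param graph a `molecule_graph` providing the atom's context.
#' @param index optional single atom index; default returns the full
#'   n x d feature matrix.
#' @return feature matrix (or single row when `index` is given).
#' @export
atom_features <- function(graph, index = NULL) {
  layout <- feature_layout("atom")
  n <- graph$n
  F <- matrix(0, n, length(layout), dimnames = list(NULL, layout))
  cls <- classify_element(graph$elements)
  F[cbind(seq_len(n), match(paste0("elem_", cls), layout))] <- 1
  e <- graph$edges
  F[, "degree"] <- tabulate(c(e$i, e$j), nbins = n)
  if (nrow(e)) {
    arom_edges <- e$kind == "bond" & !is.na(e$order) & e$order == "aromatic"
    F[unique(c(e$i[arom_edges], e$j[arom_edges])), "aromatic"] <- 1
    cov <- e$kind %in% c("bond", "intra_residue")
    F[ring_membership(n, e$i[cov], e$j[cov]), "in_ring"] <- 1
  }
  rid <- graph$residue_name
  prot <- !is.na(rid)
  if (any(prot)) {
    res_col <- ifelse(rid %in% AA3, paste0("res_", rid), "res_other")
    F[cbind(which(prot), match(res_col[prot], layout))] <- 1
  }
  if (!is.null(index)) return(F[index, ])
  F
}

DESCRIPTOR_NAMES <- c("HBDC", "HBAC", "RBC", "TPSA", "MW", "cLogP",
                      "RingCount", "AromaticRingCount", "HeavyAtomCount",
                      "FormalCharge", "FracCSP3")

# MDL ctab charge codes -> formal charge
MDL_CHARGE <- c("0" = 0, "1" = 3, "2" = 2, "3" = 1, "4" = 0, "5" = -1,
                "6" = -2, "7" = -3)

smiles_to_sdf <- function(smiles) {
  # single-atom molecules trigger a spurious zero-bond validity warning
  tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)),
           error = function(e) stop("unparsable SMILES '", smiles, "': ",
                                    conditionMessage(e), call. = FALSE))
}

# Heavy-atom bond graph of a single ChemmineR SDF molecule.
sdf_graph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  el <- gsub("_.*$", "", rownames(ab))
  chg <- if ("C6" %in% colnames(ab))
    unname(MDL_CHARGE[as.character(ab[, "C6"])]) else numeric(nrow(ab))
  chg[is.na(chg)] <- 0
  bi <- bj <- integer(0); bo <- integer(0)
  # zero-bond molecules yield a placeholder all-zero bond row without C3
  if (!is.null(bb) && nrow(bb) && "C3" %in% colnames(bb)) {
    real <- bb[, "C1"] > 0 & bb[, "C2"] > 0
    bi <- as.integer(bb[real, "C1"]); bj <- as.integer(bb[real, "C2"])
    bo <- as.integer(bb[real, "C3"])
  }
  heavy <- el != "H"
  map <- cumsum(heavy)
  keep <- heavy[bi] & heavy[bj]
  list(element = el[heavy], charge = chg[heavy],
       i = map[bi[keep]], j = map[bj[keep]], order = bo[keep])
}

# Aromatic perception for descriptor/fingerprint purposes: ring atoms
# reported aromatic by ChemmineR's ring perception.
sdf_aromatic_atoms <- function(sdf, n) {
  arom <- rep(FALSE, n)
  r <- tryCatch(ChemmineR::rings(sdf, type = "all", arom = TRUE),
                error = function(e) NULL)
  if (!is.null(r) && length(r$RINGS)) {
    for (k in seq_along(r$RINGS)) {
      if (isTRUE(r$AROMATIC[[k]])) {
        idx <- as.integer(gsub("^[A-Za-z]+_", "", r$RINGS[[k]]))
        arom[idx] <- TRUE
      }
    }
  }
  arom
}

obabel_descriptors <- function(smiles) {
  smi_file <- tempfile(fileext = ".smi")
  on.exit(unlink(smi_file))
  writeLines(smiles, smi_file)
  out <- suppressWarnings(system2(
    "obabel", c(smi_file, "-osmi", "--append", shQuote("HBD HBA1 rotors TPSA MW logP")),
    stdout = TRUE, stderr = FALSE))
  out <- out[nzchar(out)]
  if (length(out) != length(smiles))
    stop("descriptor error: obabel returned ", length(out), " records for ",
         length(smiles), " SMILES inputs")
  parts <- strsplit(trimws(out), "[ \t]+")
  vals <- t(vapply(parts, function(p) as.numeric(utils::tail(p, 6)), numeric(6)))
  colnames(vals) <- c("HBDC", "HBAC", "RBC", "TPSA", "MW", "cLogP")
  vals
}

#' Compute the 11 candidate chemical descriptors for SMILES inputs
#'
#' Hydrogen-bond donor and acceptor counts, rotatable-bond count, TPSA,
#' molecular weight and cLogP are computed by Open Babel; ring count
#' (cyclomatic number), aromatic ring count, heavy-atom count, net formal
#' charge and the fraction of sp3 carbons are derived from the parsed
#' molecular graph.
#'
#' @param smiles character vector of SMILES strings.
#' @return a tibble with one row per molecule and the 11 descriptor
#'   columns named in `protacdeg:::DESCRIPTOR_NAMES`.
#' @export
compute_descriptors <- function(smiles) {
  stopifnot(length(smiles) >= 1)
  ob <- obabel_descriptors(smiles)
  if (any(!is.finite(ob)))
    stop("descriptor error: unparsable SMILES among inputs: ",
         paste(smiles[!stats::complete.cases(ob)], collapse = ", "))
  graph_desc <- matrix(0, length(smiles), 5,
                       dimnames = list(NULL, c("RingCount", "AromaticRingCount",
                                               "HeavyAtomCount", "FormalCharge",
                                               "FracCSP3")))
  for (m in seq_along(smiles)) {
    sdfset <- smiles_to_sdf(smiles[m])
    sdf <- sdfset[[1]]
    gr <- sdf_graph(sdf)
    n <- length(gr$element)
    n_edges <- length(gr$i)
    comp <- graph_components(n, gr$i, gr$j)
    arom_all <- sdf_aromatic_atoms(sdf, length(ChemmineR::atomblock(sdf)[, 1]))
    heavy_idx <- which(gsub("_.*$", "", rownames(ChemmineR::atomblock(sdf))) != "H")
    arom <- arom_all[heavy_idx]
    is_c <- gr$element == "C"
    sp3 <- rep(TRUE, n)
    for (k in seq_along(gr$i)) {
      if (gr$order[k] > 1) { sp3[gr$i[k]] <- FALSE; sp3[gr$j[k]] <- FALSE }
    }
    sp3[arom] <- FALSE
    ring_count <- n_edges - n + comp
    arom_ring_count <- count_aromatic_rings(sdf)
    graph_desc[m, ] <- c(ring_count, arom_ring_count, n,
                         sum(gr$charge), if (any(is_c)) mean(sp3[is_c]) else 0)
  }
  tibble::as_tibble(cbind(as.data.frame(ob), as.data.frame(graph_desc)))
}

graph_components <- function(n, ei, ej) {
  if (n == 0) return(0L)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (k in seq_along(ei)) {
    a <- find(ei[k]); b <- find(ej[k])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

count_aromatic_rings <- function(sdf) {
  r <- tryCatch(ChemmineR::rings(sdf, type = "all", arom = TRUE),
                error = function(e) NULL)
  if (is.null(r) || !length(r$RINGS)) return(0L)
  sizes <- vapply(r$RINGS, length, integer(1))
  # count aromatic rings in the smallest-ring sense: aromatic cycles of
  # minimal size (the "all" set includes envelope rings of fused systems)
  arom <- vapply(seq_along(r$RINGS), function(k) isTRUE(r$AROMATIC[[k]]), logical(1))
  if (!any(arom)) return(0L)
  keep <- arom & sizes <= 7
  sum(keep)
}

#' Canonicalize SMILES
#'
#' @param smiles character vector.
#' @return canonical SMILES (Open Babel canonical form), used for duplicate
#'   detection in the leakage-aware split.
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    out <- ChemmineOB::convertFormat("SMI", "CAN", s)
    sub("\\s.*$", "", trimws(out))
  }, character(1), USE.NAMES = FALSE)
}

#' Morgan (circular) fingerprint
#'
#' Iteratively hashes each heavy atom's environment out to `radius` bonds
#' (initial invariant: element, degree, formal charge, aromatic and ring
#' flags; update: current identifier plus the sorted multiset of
#' (bond order, neighbour identifier) pairs) and folds every environment
#' identifier into an `nbits`-long bit vector. Order-invariant by
#' construction, hence identical for any valid SMILES of the same molecule.
#'
#' @param smiles single SMILES string.
#' @param radius environment radius in bonds (default 2).
#' @param nbits fingerprint length (default 2048).
#' @return integer 0/1 vector of length `nbits` with at least one bit set.
#' @export
morgan_fingerprint <- function(smiles, radius = 2L, nbits = 2048L) {
  sdfset <- smiles_to_sdf(smiles)
  sdf <- sdfset[[1]]
  gr <- sdf_graph(sdf)
  n <- length(gr$element)
  if (n == 0) stop("empty molecule: ", smiles)
  all_el <- gsub("_.*$", "", rownames(ChemmineR::atomblock(sdf)))
  arom <- sdf_aromatic_atoms(sdf, length(all_el))[all_el != "H"]
  in_ring <- ring_membership(n, gr$i, gr$j)
  deg <- tabulate(c(gr$i, gr$j), nbins = n)
  ids <- vapply(seq_len(n), function(a) {
    fnv1a32(paste(gr$element[a], deg[a], gr$charge[a],
                  as.integer(arom[a]), as.integer(in_ring[a]), sep = ":"))
  }, numeric(1))
  nbrs <- lapply(seq_len(n), function(a) integer(0))
  bord <- lapply(seq_len(n), function(a) integer(0))
  for (k in seq_along(gr$i)) {
    a <- gr$i[k]; b <- gr$j[k]
    nbrs[[a]] <- c(nbrs[[a]], b); bord[[a]] <- c(bord[[a]], gr$order[k])
    nbrs[[b]] <- c(nbrs[[b]], a); bord[[b]] <- c(bord[[b]], gr$order[k])
  }
  bits <- integer(nbits)
  bits[(ids %% nbits) + 1] <- 1L
  if (radius > 0) {
    for (r in seq_len(radius)) {
      new_ids <- vapply(seq_len(n), function(a) {
        if (!length(nbrs[[a]])) return(fnv1a32(paste0("iso:", ids[a])))
        pairs <- paste(bord[[a]], ids[nbrs[[a]]], sep = "-")
        fnv1a32(paste(ids[a], paste(sort(pairs), collapse = ","), sep = "|"))
      }, numeric(1))
      ids <- new_ids
      bits[(ids %% nbits) + 1] <- 1L
    }
  }
  bits
}

#' Two-step descriptor selection
#'
#' Step 1 removes near-zero-variance descriptors and ranks the survivors by
#' a chi-square score against the binary label (descriptors are min-max
#' scaled to unit range and binned into deciles first), keeping the top
#' `chi2_keep`. Step 2 fits a gradient-boosted tree ensemble on the
#' survivors and keeps the top `k` by gain importance (ties broken by the
#' chi-square rank). Deterministic given `seed`.
#'
#' @param table data frame / tibble of descriptor columns (numeric).
#' @param labels binary labels (0/1 or logical), one per row.
#' @param k number of descriptors to keep (default 6).
#' @param chi2_keep survivors passed to the tree step (default 9).
#' @param seed RNG seed for the tree ensemble.
#' @param nrounds,max_depth,eta gradient-boosting settings.
#' @return list with `mask` (named logical over columns) and `report`
#'   (tibble: variance, chi-square score, importance, selected flag).
#' @export
select_features <- function(table, labels, k = 6L, chi2_keep = 9L, seed = 1L,
                            nrounds = 100L, max_depth = 3L, eta = 0.1) {
  X <- as.matrix(as.data.frame(table))
  y <- as.integer(labels)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2) stop("labels must contain both classes")
  nm <- colnames(X)
  v <- apply(X, 2, stats::var)
  alive <- is.finite(v) & v > 1e-10

  chi2 <- rep(NA_real_, ncol(X)); names(chi2) <- nm
  for (j in which(alive)) {
    x <- X[, j]
    xs <- (x - min(x)) / (max(x) - min(x))
    bins <- cut(xs, breaks = unique(c(-Inf, stats::quantile(xs, seq(0.1, 0.9, 0.1)), Inf)))
    tab <- table(bins, y)
    exp_ <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    ok <- exp_ > 0
    chi2[j] <- sum((tab[ok] - exp_[ok])^2 / exp_[ok])
  }
  chi_rank <- rank(-chi2, ties.method = "first", na.last = "keep")
  survivors <- which(alive & chi_rank <= chi2_keep)

  importance <- rep(0, ncol(X)); names(importance) <- nm
  if (length(survivors) >= 2) {
    set.seed(seed)
    dtrain <- xgboost::xgb.DMatrix(X[, survivors, drop = FALSE], label = y,
                                   nthread = 1)
    bst <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = max_depth,
                    eta = eta, nthread = 1, seed = seed),
      data = dtrain, nrounds = nrounds, verbose = 0
    )
    imp <- xgboost::xgb.importance(model = bst)
    importance[imp$Feature] <- imp$Gain
  }
  if (k > length(survivors)) {
    warning("k exceeds surviving descriptors; keeping all ", length(survivors))
    k <- length(survivors)
  }
  ord <- order(-importance[survivors], chi_rank[survivors])
  chosen <- survivors[ord][seq_len(k)]
  mask <- stats::setNames(rep(FALSE, ncol(X)), nm)
  mask[chosen] <- TRUE
  report <- tibble::tibble(
    descriptor = nm, variance = unname(v), chi2 = unname(chi2),
    importance = unname(importance), selected = unname(mask)
  )
  list(mask = mask, report = report)
}

#' Standardize descriptors on training statistics
#'
#' @param X descriptor matrix (rows = samples).
#' @param stats optional list(center, scale) from a training split; computed
#'   from `X` when absent.
#' @return list(X = standardized matrix, stats = list(center, scale)).
#' @export
standardize_descriptors <- function(X, stats = NULL) {
  X <- as.matrix(X)
  if (is.null(stats)) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
    stats <- list(center = center, scale = scale)
  }
  Xs <- sweep(sweep(X, 2, stats$center, "-"), 2, stats$scale, "/")
  list(X = Xs, stats = stats)
}

#' Fuse selected descriptors and fingerprint into the attribute vector
#'
#' Two independent one-layer perceptrons embed the standardized selected
#' descriptors and the Morgan fingerprint; their outputs (each of length
#' `hidden_dim / 2`) are concatenated into the attribute vector, whose
#' length equals the node-embedding width so it can be added to the pooled
#' graph embedding.
#'
#' @param descriptors standardized selected-descriptor vector.
#' @param fingerprint 0/1 fingerprint vector.
#' @param params attribute parameters (`init_attr_params()` inside a model).
#' @return numeric attribute vector of length `hidden_dim`.
#' @export
build_attribute_vector <- function(descriptors, fingerprint, params) {
  d1 <- drop(linear_fwd(matrix(descriptors, 1), params$desc))
  d2 <- drop(linear_fwd(matrix(fingerprint, 1), params$fp))
  c(d1, d2)
}
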