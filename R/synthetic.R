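# Self-contained synthetic fixtures: random 3D molecular graphs written as
# valid TRIPOS mol2, toy protein pockets written as fixed-column PDB, simple
# chain SMILES for descriptor variation, and a planted-signal ternary
# dataset whose label is a known function of quantities the model can see
# (PROTAC geometry plus one chemical descriptor).

#' Random 3D molecule with round-trippable mol2 text
#'
#' Builds a connected random tree plus a few extra edges, places
#' coordinates by a Gaussian chain so bonded atoms sit about 1.5 Angstrom
#' apart, and renders a valid mol2 file.
#'
#' @param n_atoms number of heavy atoms (>= 2).
#' @param seed RNG seed (byte-identical output for equal seeds).
#' @param extra_edge_prob chance of adding one extra (ring-closing) edge
#'   per spare atom pair.
#' @return list with `graph` (a featurized PROTAC `molecule_graph`) and
#'   `mol2` (character vector of file lines).
#' @export
random_molecule <- function(n_atoms, seed = 1L, extra_edge_prob = 0.15) {
  stopifnot(n_atoms >= 2)
  set.seed(seed)
  elements <- sample(c("C", "N", "O", "S", "Cl"), n_atoms, replace = TRUE,
                     prob = c(0.66, 0.12, 0.14, 0.04, 0.04))
  parent <- c(NA, vapply(2:n_atoms, function(k) sample.int(k - 1, 1), 1L))
  # per-molecule bond-length scale: molecules differ in spatial extent both
  # through size and through this scale, so global geometry (e.g. the mean
  # pairwise atom distance) is reflected in the local edge distances the
  # encoder consumes
  bond_len <- stats::runif(1, 1.2, 1.9)
  coords <- matrix(0, n_atoms, 3)
  for (k in 2:n_atoms) {
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    coords[k, ] <- coords[parent[k], ] + bond_len * dir + stats::rnorm(3, 0, 0.08)
  }
  ei <- parent[-1]; ej <- 2:n_atoms
  n_extra <- stats::rbinom(1, max(0, n_atoms - 3), extra_edge_prob)
  if (n_extra > 0) {
    for (t in seq_len(n_extra)) {
      cand <- sample.int(n_atoms, 2)
      a <- min(cand); b <- max(cand)
      if (!any(ei == a & ej == b) && !any(ei == b & ej == a) && a != b) {
        ei <- c(ei, a); ej <- c(ej, b)
      }
    }
  }
  order_lab <- sample(c("single", "double"), length(ei), replace = TRUE,
                      prob = c(0.85, 0.15))
  edges <- data.frame(i = ei, j = ej, kind = "bond", order = order_lab)
  g <- molecule_graph("PROTAC", elements, coords, edges,
                      provenance = list(source = "synthetic", seed = seed))
  g$features <- atom_features(g)
  list(graph = g, mol2 = render_mol2(g, name = sprintf("synth_%d", seed)))
}

# Render a molecule graph as TRIPOS mol2 lines (4 decimal places).
render_mol2 <- function(g, name = "mol") {
  e <- g$edges
  order_code <- c(single = "1", double = "2", triple = "3", aromatic = "ar")
  lines <- c(
    "@<TRIPOS>MOLECULE", name,
    sprintf("%d %d 0 0 0", g$n, nrow(e)),
    "SMALL", "NO_CHARGES", "", "@<TRIPOS>ATOM",
    sprintf("%7d %-4s %10.4f %10.4f %10.4f %-5s %3d LIG %8.4f",
            seq_len(g$n), paste0(g$elements, seq_len(g$n)),
            g$coords[, 1], g$coords[, 2], g$coords[, 3],
            g$elements, 1L, 0),
    "@<TRIPOS>BOND"
  )
  if (nrow(e))
    lines <- c(lines, sprintf("%6d %5d %5d %s", seq_len(nrow(e)), e$i, e$j,
                              order_code[e$order]))
  lines
}

# Fixed-column PDB rendering of atom records.
render_pdb <- function(atoms) {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$record, seq_len(nrow(atoms)),
          substr(atoms$atom_name, 1, 4), "",
          atoms$residue_name, "A", atoms$resno, "",
          atoms$x, atoms$y, atoms$z, 1.00, 0.00,
          toupper(atoms$element))
}

#' Random protein pocket with a central ligand
#'
#' Places `n_residues` small residues on a shell around a small-molecule
#' ligand so that a configurable fraction of them fall within the pocket
#' cutoff, and renders fixed-column PDB text (ATOM records for residues,
#' HETATM for the ligand).
#'
#' @param n_residues number of residues (>= 1).
#' @param seed RNG seed.
#' @param fraction_within fraction of residues planted inside the cutoff.
#' @param cutoff pocket cutoff the construction targets (Angstrom).
#' @return list with `pdb` (file lines), `ligand_atoms` and
#'   `receptor_atoms` tibbles, and `planted` (residue ids planted within).
#' @export
random_pocket <- function(n_residues, seed = 1L, fraction_within = 0.5,
                          cutoff = 5) {
  stopifnot(n_residues >= 1)
  set.seed(seed)
  n_lig <- sample(3:5, 1)
  lig <- tibble::tibble(
    element = sample(c("C", "N", "O"), n_lig, replace = TRUE, prob = c(.6, .2, .2)),
    x = stats::rnorm(n_lig, 0, 0.8), y = stats::rnorm(n_lig, 0, 0.8),
    z = stats::rnorm(n_lig, 0, 0.8),
    residue_id = NA_integer_, residue_name = "LIG",
    atom_name = NA_character_, resno = 900L, record = "HETATM"
  )
  lig$atom_name <- paste0(lig$element, seq_len(n_lig))
  n_in <- round(fraction_within * n_residues)
  rows <- list()
  backbone <- c("N", "CA", "C", "O", "CB")
  backbone_el <- c("N", "C", "C", "O", "C")
  # residue directions spaced on a golden spiral so neighbouring residues
  # do not overlap (keeps inter-residue contact sets realistic and sparse)
  golden <- pi * (3 - sqrt(5))
  for (r in seq_len(n_residues)) {
    # residue centroid: inside residues close enough that the nearest atom
    # is well under the cutoff; outside ones far beyond it
    rad <- if (r <= n_in) stats::runif(1, 2.5, 4.0) else stats::runif(1, cutoff + 6, cutoff + 14)
    zc <- 1 - 2 * (r - 0.5) / n_residues
    rho <- sqrt(max(0, 1 - zc^2))
    th <- golden * r + stats::runif(1, -0.2, 0.2)
    dir <- c(rho * cos(th), rho * sin(th), zc)
    centroid <- dir * rad
    n_at <- sample(4:5, 1)
    offs <- matrix(stats::rnorm(n_at * 3, 0, 0.7), n_at, 3)
    offs[1, ] <- 0
    rows[[r]] <- tibble::tibble(
      element = backbone_el[seq_len(n_at)],
      x = centroid[1] + offs[, 1], y = centroid[2] + offs[, 2],
      z = centroid[3] + offs[, 3],
      residue_id = r - 1L,
      residue_name = sample(AA3, 1),
      atom_name = backbone[seq_len(n_at)],
      resno = r, record = "ATOM"
    )
  }
  receptor <- do.call(rbind, rows)
  pdb <- c(render_pdb(receptor), render_pdb(lig), "END")
  list(pdb = pdb, ligand_atoms = lig, receptor_atoms = receptor,
       planted = seq_len(n_in) - 1L)
}

# Simple heteroatom chain SMILES: always valid, descriptor-variable.
random_chain_smiles <- function(n_heavy) {
  units <- sample(c("C", "C", "C", "N", "O"), n_heavy, replace = TRUE)
  # avoid O-O / N-O adjacencies that openbabel flags in odd protonation states
  for (k in 2:n_heavy) {
    if (units[k] != "C" && units[k - 1] != "C") units[k] <- "C"
  }
  paste(units, collapse = "")
}

#' Generate a planted-signal ternary PROTAC dataset
#'
#' Every entry pairs a random 3D PROTAC graph and chain SMILES with one
#' pocket from a small pool of synthetic POIs and E3 ligases. The latent
#' activity is `signal_strength * (z_geom + z_tpsa) / sqrt(2) + noise`,
#' where `z_geom` standardizes the mean pairwise atom distance of the
#' PROTAC 3D graph and `z_tpsa` the TPSA descriptor; the binary label is
#' its sign. DC50/Dmax annotations are emitted consistently with the
#' labeling rule (low iff DC50 >= 100 nM and Dmax < 80%), so
#' [assign_activity_label()] recovers the planted label exactly; a
#' configurable fraction of entries has both annotations withheld to form
#' an unlabeled pool.
#'
#' @param n_samples entries to generate.
#' @param seed RNG seed (identical seeds give identical datasets).
#' @param atoms_range PROTAC heavy-atom count range.
#' @param signal_strength planted effect size (default 3, about
#'   0.95 Bayes AUROC at unit noise).
#' @param noise_sd latent noise standard deviation (default 1).
#' @param label_balance intercept shift targeting this fraction of high
#'   labels (default 0.5).
#' @param unlabeled_frac fraction of entries with annotations withheld.
#' @param dup_frac fraction of entries duplicated under fresh ids (planted
#'   (POI, SMILES) collisions for split testing).
#' @param n_poi,n_e3 pool sizes for synthetic protein pockets.
#' @param config a [pdg_config()] for graph-construction cutoffs.
#' @return a `pdg_dataset`: list of assembled samples plus `manifest` and
#'   `truth` tibbles and the descriptor table.
#' @export
planted_signal_dataset <- function(n_samples, seed = 1L,
                                   atoms_range = c(10L, 18L),
                                   signal_strength = 3,
                                   noise_sd = 1,
                                   label_balance = 0.5,
                                   unlabeled_frac = 0,
                                   dup_frac = 0,
                                   n_poi = 5L, n_e3 = 3L,
                                   config = pdg_config()) {
  set.seed(seed)
  pocket_graph <- function(kind, pseed) {
    pk <- random_pocket(n_residues = sample(3:5, 1), seed = pseed,
                        fraction_within = 1, cutoff = config$pocket_cutoff)
    pocket <- extract_pocket(pk$receptor_atoms, pk$ligand_atoms,
                             cutoff = config$pocket_cutoff)
    build_protein_graph(pocket, kind = kind,
                        inter_cutoff = config$inter_cutoff,
                        intra_cutoff = config$intra_cutoff,
                        provenance = list(source = "synthetic", seed = pseed))
  }
  poi_seeds <- sample.int(1e6, n_poi)
  e3_seeds <- sample.int(1e6, n_e3)
  poi_pool <- lapply(poi_seeds, function(s) pocket_graph("POI", s))
  e3_pool <- lapply(e3_seeds, function(s) pocket_graph("E3", s))

  mol_seeds <- sample.int(1e6, n_samples)
  n_at <- sample(seq(atoms_range[1], atoms_range[2]), n_samples, replace = TRUE)
  mols <- lapply(seq_len(n_samples), function(m)
    random_molecule(n_at[m], seed = mol_seeds[m]))
  smiles <- vapply(seq_len(n_samples), function(m)
    random_chain_smiles(sample(8:20, 1)), character(1))
  poi_idx <- sample.int(n_poi, n_samples, replace = TRUE)
  e3_idx <- sample.int(n_e3, n_samples, replace = TRUE)

  desc <- compute_descriptors(smiles)
  geom <- vapply(mols, function(m) {
    D <- pairwise_dist(m$graph$coords)
    mean(D[upper.tri(D)])
  }, numeric(1))
  z_geom <- as.numeric(scale(geom))
  z_tpsa <- as.numeric(scale(desc$TPSA))
  if (any(!is.finite(z_tpsa))) z_tpsa[!is.finite(z_tpsa)] <- 0
  shift <- stats::qnorm(label_balance) * sqrt(signal_strength^2 + noise_sd^2)
  latent <- signal_strength * (z_geom + z_tpsa) / sqrt(2) +
    stats::rnorm(n_samples, 0, noise_sd) + shift
  truth_label <- as.integer(latent > 0)

  dc50 <- ifelse(truth_label == 1,
                 round(10^stats::runif(n_samples, -1, 1.9), 3),
                 round(10^stats::runif(n_samples, 2.1, 4), 3))
  dmax <- ifelse(truth_label == 1,
                 round(stats::runif(n_samples, 80, 100), 1),
                 round(stats::runif(n_samples, 0, 79), 1))
  unlabeled <- stats::runif(n_samples) < unlabeled_frac

  ids <- sprintf("S%04d", seq_len(n_samples))
  samples <- lapply(seq_len(n_samples), function(m) {
    list(
      entry_id = ids[m],
      smiles = smiles[m],
      poi_id = sprintf("POI%02d", poi_idx[m]),
      e3_id = sprintf("E3%02d", e3_idx[m]),
      graphs = list(PROTAC = mols[[m]]$graph,
                    POI = poi_pool[[poi_idx[m]]],
                    E3 = e3_pool[[e3_idx[m]]]),
      mol2 = mols[[m]]$mol2,
      desc = as.numeric(desc[m, ]),
      dc50 = if (unlabeled[m]) NA_real_ else dc50[m],
      dmax = if (unlabeled[m]) NA_real_ else dmax[m]
    )
  })

  latent_all <- latent
  if (dup_frac > 0) {
    n_dup <- round(dup_frac * n_samples)
    dup_src <- sample.int(n_samples, n_dup, replace = FALSE)
    for (t in seq_along(dup_src)) {
      s <- samples[[dup_src[t]]]
      s$entry_id <- sprintf("D%04d", t)
      samples[[length(samples) + 1]] <- s
      truth_label <- c(truth_label, truth_label[dup_src[t]])
      latent_all <- c(latent_all, latent[dup_src[t]])
    }
  }

  manifest <- tibble::tibble(
    entry_id = vapply(samples, `[[`, character(1), "entry_id"),
    smiles = vapply(samples, `[[`, character(1), "smiles"),
    poi_id = vapply(samples, `[[`, character(1), "poi_id"),
    e3_id = vapply(samples, `[[`, character(1), "e3_id"),
    dc50_nM = vapply(samples, function(s) s$dc50 %||% NA_real_, numeric(1)),
    dmax_pct = vapply(samples, function(s) s$dmax %||% NA_real_, numeric(1))
  )
  manifest$label <- mapply(assign_activity_label, manifest$dc50_nM,
                           manifest$dmax_pct)
  truth <- tibble::tibble(entry_id = manifest$entry_id,
                          truth_label = truth_label,
                          latent = latent_all)
  ds <- structure(list(
    samples = samples,
    manifest = manifest,
    truth = truth,
    descriptors = desc,
    config = list(seed = seed, signal_strength = signal_strength,
                  noise_sd = noise_sd, unlabeled_frac = unlabeled_frac)
  ), class = "pdg_dataset")
  attach_fingerprints(ds, config)
}

# Morgan fingerprints for every sample (computed once per dataset).
attach_fingerprints <- function(ds, config = pdg_config()) {
  smi <- vapply(ds$samples, `[[`, character(1), "smiles")
  uniq <- unique(smi)
  fps <- lapply(uniq, morgan_fingerprint, radius = config$fp_radius,
                nbits = config$fp_bits)
  names(fps) <- uniq
  for (m in seq_along(ds$samples)) ds$samples[[m]]$fp <- fps[[smi[m]]]
  ds
}

#' @export
print.pdg_dataset <- function(x, ...) {
  lab <- x$manifest$label
  cat(sprintf("<pdg_dataset: %d entries (%d high, %d low, %d unlabeled)>\n",
              nrow(x$manifest), sum(lab == "high", na.rm = TRUE),
              sum(lab == "low", na.rm = TRUE), sum(lab == "unlabeled")))
  invisible(x)
}

#' Withhold activity annotations from selected entries
#'
#' Marks the given entries unlabeled (DC50/Dmax set to missing), moving
#' them into the pool the semisupervised loop can score. Ground truth in
#' `$truth` is untouched.
#'
#' @param ds a `pdg_dataset`.
#' @param ids entry ids to mask.
#' @return the modified dataset.
#' @export
mask_labels <- function(ds, ids) {
  hit <- ds$manifest$entry_id %in% ids
  ds$manifest$dc50_nM[hit] <- NA_real_
  ds$manifest$dmax_pct[hit] <- NA_real_
  ds$manifest$label[hit] <- "unlabeled"
  for (m in which(dataset_ids(ds) %in% ids)) {
    ds$samples[[m]]$dc50 <- NA_real_
    ds$samples[[m]]$dmax <- NA_real_
  }
  ds
}

#' Write a synthetic dataset to a fixture directory
#'
#' Writes one mol2 per PROTAC, one PDB per distinct pocket, a manifest CSV
#' and a ground-truth CSV, exactly the layout [build_dataset()] reads back.
#'
#' @param ds a `pdg_dataset` from [planted_signal_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(file.path(dir, "structures"), recursive = TRUE,
             showWarnings = FALSE)
  man <- ds$manifest
  man$protac_path <- file.path("structures", paste0(man$entry_id, ".mol2"))
  for (m in seq_along(ds$samples)) {
    s <- ds$samples[[m]]
    writeLines(s$mol2, file.path(dir, "structures", paste0(s$entry_id, ".mol2")))
    for (kind in c("POI", "E3")) {
      id <- if (kind == "POI") s$poi_id else s$e3_id
      gpath <- file.path(dir, "structures", paste0(id, ".json"))
      if (!file.exists(gpath)) write_graph(s$graphs[[kind]], gpath)
    }
  }
  man$poi_structure_path <- file.path("structures", paste0(man$poi_id, ".json"))
  man$e3_structure_path <- file.path("structures", paste0(man$e3_id, ".json"))
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(ds$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Assemble a dataset from a manifest directory
#'
#' Reads the manifest CSV written by [write_dataset()] (or prepared by the
#' user with the same columns), parses each PROTAC mol2, loads the pocket
#' graph serializations, and recomputes descriptors and fingerprints.
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @param config a [pdg_config()].
#' @return a `pdg_dataset`.
#' @export
build_dataset <- function(dir, config = pdg_config()) {
  man <- tibble::as_tibble(utils::read.csv(file.path(dir, "manifest.csv"),
                                           stringsAsFactors = FALSE))
  desc <- compute_descriptors(man$smiles)
  pocket_cache <- new.env()
  load_pocket <- function(path) {
    if (is.null(pocket_cache[[path]]))
      pocket_cache[[path]] <- read_graph(file.path(dir, path))
    pocket_cache[[path]]
  }
  samples <- lapply(seq_len(nrow(man)), function(m) {
    g <- parse_mol2(file.path(dir, man$protac_path[m]),
                    keep_hydrogens = config$keep_hydrogens)
    g$features <- atom_features(g)
    list(
      entry_id = man$entry_id[m],
      smiles = man$smiles[m],
      poi_id = man$poi_id[m],
      e3_id = man$e3_id[m],
      graphs = list(PROTAC = g,
                    POI = load_pocket(man$poi_structure_path[m]),
                    E3 = load_pocket(man$e3_structure_path[m])),
      desc = as.numeric(desc[m, ]),
      dc50 = man$dc50_nM[m],
      dmax = man$dmax_pct[m]
    )
  })
  man$label <- mapply(assign_activity_label, man$dc50_nM, man$dmax_pct)
  truth_path <- file.path(dir, "truth.csv")
  ds <- structure(list(
    samples = samples,
    manifest = man,
    truth = if (file.exists(truth_path))
      tibble::as_tibble(utils::read.csv(truth_path)) else NULL,
    descriptors = desc,
    config = list(source = dir)
  ), class = "pdg_dataset")
  attach_fingerprints(ds, config)
}
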