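# Readers for the two structure formats consumed by the pipeline (TRIPOS
# mol2 for PROTAC molecules, PDB for protein receptors), pocket extraction
# by the 5-Angstrom ligand-distance rule, and protein graph construction.
# File parsing itself is delegated to bio3d; everything downstream of the
# raw atom tables is built here.

HALOGENS <- c("F", "Cl", "Br", "I")
WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O", "TIP", "SOL")

mol2_order_map <- c("1" = "single", "2" = "double", "3" = "triple",
                    "ar" = "aromatic", "am" = "single", "du" = "single",
                    "un" = "single")

element_from_mol2 <- function(elety, elena) {
  el <- sub("\\..*$", "", elety)
  bad <- !grepl("^[A-Za-z]", el)
  el[bad] <- gsub("[0-9'\"]", "", elena[bad])
  # normalize case: first letter upper, rest lower
  paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, nchar(el))))
}

#' Parse a TRIPOS mol2 file into a PROTAC molecule graph
#'
#' One node per atom (hydrogens dropped unless `keep_hydrogens`), one
#' undirected edge per bond, coordinates copied verbatim from the ATOM
#' section. Bond orders map to the edge-attribute one-hot
#' (single/double/triple/aromatic; amide and dummy types count as single,
#' "nc" records are dropped).
#'
#' @param path mol2 file with ATOM and BOND sections.
#' @param keep_hydrogens retain hydrogen atoms (default FALSE).
#' @return a `molecule_graph` of kind `"PROTAC"`.
#' @export
parse_mol2 <- function(path, keep_hydrogens = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  mol <- tryCatch(bio3d::read.mol2(path),
                  error = function(e) stop("mol2 parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  at <- mol$atom
  if (is.null(at) || !nrow(at)) stop("empty structure: no atoms in ", path)
  if (any(!is.finite(as.matrix(at[, c("x", "y", "z")]))))
    stop("mol2 parse error: unreadable coordinates in ", path)
  el <- element_from_mol2(at$elety, at$elena)
  keep <- rep(TRUE, nrow(at))
  if (!keep_hydrogens) keep <- el != "H"
  if (!any(keep)) stop("empty structure: no heavy atoms in ", path)
  idx_map <- cumsum(keep)            # old index -> new index (valid where keep)
  bd <- mol$bond
  edges <- data.frame(i = integer(0), j = integer(0),
                      kind = character(0), order = character(0))
  if (!is.null(bd) && nrow(bd)) {
    type <- tolower(as.character(bd$type))
    ok <- type != "nc" & keep[bd$origin] & keep[bd$target]
    if (any(ok)) {
      edges <- data.frame(
        i = idx_map[bd$origin[ok]],
        j = idx_map[bd$target[ok]],
        kind = "bond",
        order = unname(mol2_order_map[type[ok]])
      )
      edges$order[is.na(edges$order)] <- "single"
    }
  }
  molecule_graph(
    kind = "PROTAC",
    elements = el[keep],
    coords = as.matrix(at[keep, c("x", "y", "z")]),
    edges = edges,
    provenance = list(source = path, format = "mol2",
                      name = mol$name %||% basename(path))
  )
}

#' Parse a PDB file into an atom table
#'
#' Returns one row per retained atom with element, coordinates, a 0-based
#' `residue_id` (ordered by chain / residue number / insertion code as
#' encountered in the file), the 3-letter `residue_name`, and the record
#' type. Water is stripped; alternate locations are resolved by keeping the
#' highest-occupancy copy (ties: first listed); hydrogens are dropped
#' unless `keep_hydrogens`.
#'
#' @param path PDB file containing ATOM/HETATM records.
#' @param keep_hydrogens retain hydrogens (default FALSE).
#' @param keep_water retain water molecules (default FALSE).
#' @return a tibble with columns `element`, `x`, `y`, `z`, `residue_id`,
#'   `residue_name`, `atom_index` (0-based), `atom_name`, `chain`, `resno`,
#'   `record`.
#' @export
parse_pdb <- function(path, keep_hydrogens = FALSE, keep_water = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE)),
                  error = function(e) stop("PDB parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || !nrow(at)) stop("empty structure: no atoms in ", path)
  if (any(!is.finite(as.matrix(at[, c("x", "y", "z")])))) {
    bad <- which(!stats::complete.cases(at[, c("x", "y", "z")]))[1]
    stop("PDB parse error: unreadable coordinate columns in record ",
         at$eleno[bad], " of ", path)
  }
  el <- at$elesy
  missing_el <- is.na(el) | el == ""
  # fall back to the atom name with digits/primes stripped; a protein CA/CD
  # is a carbon, not calcium/cadmium
  fallback <- sub("^[0-9]*", "", gsub("[0-9'\"]*$", "", at$elety))
  el[missing_el] <- substr(fallback[missing_el], 1, 1)
  el <- substr(el, 1, 2)
  at$element <- paste0(toupper(substr(el, 1, 1)),
                       tolower(substr(el, 2, nchar(el))))

  keep <- rep(TRUE, nrow(at))
  if (!keep_water) keep <- keep & !(at$resid %in% WATER_RESIDUES)
  if (!keep_hydrogens) keep <- keep & !(at$element %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  if (!nrow(at)) stop("empty structure: no atoms retained from ", path)

  # altLoc resolution: highest occupancy per (chain, resno, insert, atom name)
  alt <- at$alt; alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
    occ <- at$o; occ[is.na(occ)] <- 1
    ord <- order(key, -occ, seq_len(nrow(at)))
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                               sep = "|")), , drop = FALSE]
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }

  ins <- at$insert; ins[is.na(ins)] <- ""
  res_key <- paste(at$chain, at$resno, ins, sep = "|")
  residue_id <- as.integer(factor(res_key, levels = unique(res_key))) - 1L
  tibble::tibble(
    element = at$element,
    x = at$x, y = at$y, z = at$z,
    residue_id = residue_id,
    residue_name = at$resid,
    atom_index = seq_len(nrow(at)) - 1L,
    atom_name = at$elety,
    chain = at$chain,
    resno = at$resno,
    record = at$type
  )
}

#' Extract the binding pocket around a ligand
#'
#' Keeps every residue having at least one (heavy) atom within `cutoff` of
#' any ligand atom; residues are kept or dropped whole. This is the
#' 5-Angstrom pocket rule applied to docked warhead / E3-ligand poses.
#'
#' @param receptor atom table (as from [parse_pdb()]) with `x`,`y`,`z` and
#'   `residue_id` columns.
#' @param ligand atom table with `x`,`y`,`z` columns; must be nonempty.
#' @param cutoff pocket distance in Angstrom (default 5).
#' @return the subset of `receptor` rows belonging to pocket residues, in
#'   the original order. An empty receptor yields an empty result.
#' @export
extract_pocket <- function(receptor, ligand, cutoff = 5) {
  stopifnot(cutoff > 0)
  if (!nrow(ligand)) stop("ligand_atoms must be nonempty")
  if (!nrow(receptor)) return(receptor[0, , drop = FALSE])
  D <- pairwise_dist(as.matrix(receptor[, c("x", "y", "z")]),
                     as.matrix(ligand[, c("x", "y", "z")]))
  near_atom <- apply(D, 1, min) <= cutoff
  keep_res <- unique(receptor$residue_id[near_atom])
  receptor[receptor$residue_id %in% keep_res, , drop = FALSE]
}

#' Build a protein pocket graph
#'
#' Atoms are nodes. Intra-residue edges connect atom pairs of the same
#' residue within `intra_cutoff` (a heavy-atom covalent distance rule);
#' inter-residue edges connect atoms of different residues within
#' `inter_cutoff`. Node features are attached with [atom_features()].
#'
#' @param pocket_atoms nonempty atom table (see [parse_pdb()]).
#' @param kind `"POI"` or `"E3"`.
#' @param inter_cutoff inter-residue contact distance, Angstrom (default 4.5).
#' @param intra_cutoff intra-residue covalent distance, Angstrom (default 1.9).
#' @param provenance optional provenance list.
#' @return a featurized `molecule_graph`.
#' @export
build_protein_graph <- function(pocket_atoms, kind = c("POI", "E3"),
                                inter_cutoff = 4.5, intra_cutoff = 1.9,
                                provenance = list()) {
  kind <- match.arg(kind)
  n <- nrow(pocket_atoms)
  if (!n) stop("pocket_atoms must be nonempty")
  xyz <- as.matrix(pocket_atoms[, c("x", "y", "z")])
  res <- pocket_atoms$residue_id
  edges <- data.frame(i = integer(0), j = integer(0),
                      kind = character(0), order = character(0))
  if (n > 1) {
    D <- pairwise_dist(xyz)
    same <- outer(res, res, "==")
    ut <- upper.tri(D)
    is_intra <- ut & same & D <= intra_cutoff
    is_inter <- ut & !same & D <= inter_cutoff
    idx_a <- which(is_intra, arr.ind = TRUE)
    idx_e <- which(is_inter, arr.ind = TRUE)
    edges <- data.frame(
      i = c(idx_a[, 1], idx_e[, 1]),
      j = c(idx_a[, 2], idx_e[, 2]),
      kind = c(rep("intra_residue", nrow(idx_a)),
               rep("inter_residue", nrow(idx_e))),
      order = NA_character_
    )
  }
  g <- molecule_graph(
    kind = kind,
    elements = pocket_atoms$element,
    coords = xyz,
    edges = edges,
    residue_id = pocket_atoms$residue_id,
    residue_name = pocket_atoms$residue_name,
    provenance = provenance
  )
  g$features <- atom_features(g)
  g
}
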