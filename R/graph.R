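# The attributed 3D molecule graph: the common container for the PROTAC
# molecule and the two protein pockets. Edges are stored undirected (i < j)
# with a kind (bond / intra_residue / inter_residue) and, for bonds, an
# order label. Edge attributes are the fixed one-hot layout below plus the
# interatomic distance at construction time.

EDGE_ATTR_NAMES <- c("single", "double", "triple", "aromatic",
                     "intra_residue", "inter_residue", "distance")

GRAPH_KINDS <- c("PROTAC", "POI", "E3")

#' Construct a 3D molecule graph
#'
#' Low-level constructor; most users get graphs from [parse_mol2()],
#' [build_protein_graph()] or the synthetic generators.
#'
#' @param kind one of `"PROTAC"`, `"POI"`, `"E3"`.
#' @param elements character vector of element symbols, one per atom.
#' @param coords numeric n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param edges data frame with columns `i`, `j` (1-based atom indices,
#'   `i < j`), `kind` (edge kind) and `order` (bond order label or `NA`).
#' @param residue_id integer residue index per atom (`NA` for small
#'   molecules), `residue_name` the 3-letter code (`NA` likewise).
#' @param residue_name see `residue_id`.
#' @param provenance free-form list recording where the graph came from.
#' @return an object of class `molecule_graph` with per-edge attribute
#'   matrix `edge_attr` (see `feature_layout("edge")`) and, once
#'   [atom_features()] has run, a per-atom `features` matrix.
#' @export
molecule_graph <- function(kind, elements, coords, edges,
                           residue_id = NULL, residue_name = NULL,
                           provenance = list()) {
  kind <- match.arg(kind, GRAPH_KINDS)
  n <- length(elements)
  if (n < 1) stop("empty structure: graph must contain at least one atom")
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3 || nrow(coords) != n)
    stop("coords must be an n x 3 numeric matrix matching the atom count")
  if (any(!is.finite(coords))) stop("coords contain non-finite values")
  edges <- as.data.frame(edges)
  if (nrow(edges)) {
    if (any(edges$i == edges$j)) stop("self-loops are not allowed")
    swap <- edges$i > edges$j
    tmp <- edges$i[swap]; edges$i[swap] <- edges$j[swap]; edges$j[swap] <- tmp
    edges <- edges[!duplicated(edges[, c("i", "j")]), , drop = FALSE]
    if (any(edges$i < 1 | edges$j > n)) stop("edge indices out of range")
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(i = integer(0), j = integer(0),
                        kind = character(0), order = character(0))
  }
  g <- structure(list(
    kind = kind,
    n = n,
    elements = elements,
    coords = coords,
    features = NULL,
    edges = edges,
    edge_attr = NULL,
    residue_id = residue_id %||% rep(NA_integer_, n),
    residue_name = residue_name %||% rep(NA_character_, n),
    provenance = provenance
  ), class = "molecule_graph")
  g$edge_attr <- edge_attributes(g)
  g$dir <- graph_directed(g)
  g
}

# One-hot edge-kind/bond-order encoding plus interatomic distance.
edge_attributes <- function(g) {
  e <- g$edges
  m <- matrix(0, nrow(e), length(EDGE_ATTR_NAMES),
              dimnames = list(NULL, EDGE_ATTR_NAMES))
  if (!nrow(e)) return(m)
  for (k in seq_len(nrow(e))) {
    col <- if (e$kind[k] == "bond") {
      switch(e$order[k], single = "single", double = "double",
             triple = "triple", aromatic = "aromatic", "single")
    } else e$kind[k]
    m[k, col] <- 1
  }
  d <- sqrt(rowSums((g$coords[e$i, , drop = FALSE] -
                       g$coords[e$j, , drop = FALSE])^2))
  m[, "distance"] <- d
  m
}

#' Dense adjacency matrix of a molecule graph
#'
#' @param g a `molecule_graph`.
#' @return symmetric 0/1 integer matrix with zero diagonal.
#' @export
graph_adjacency <- function(g) {
  A <- matrix(0L, g$n, g$n)
  if (nrow(g$edges)) {
    A[cbind(g$edges$i, g$edges$j)] <- 1L
    A[cbind(g$edges$j, g$edges$i)] <- 1L
  }
  A
}

# Directed edge expansion used by the encoder: every undirected edge
# becomes two directed (receiver i, sender j) entries sharing attributes.
graph_directed <- function(g) {
  e <- g$edges
  list(
    i = c(e$i, e$j),
    j = c(e$j, e$i),
    attr = rbind(g$edge_attr, g$edge_attr)
  )
}

#' Validate molecule-graph invariants
#'
#' Checks the structural contract: at least one atom, finite coordinates,
#' symmetric zero-diagonal adjacency, feature/coordinate row agreement, and
#' the edge-kind discipline (PROTAC graphs carry only chemical bonds,
#' protein graphs only intra-/inter-residue contacts).
#'
#' @param g a `molecule_graph`.
#' @return `g`, invisibly; stops with a message on violation.
#' @export
validate_molecule_graph <- function(g) {
  stopifnot(inherits(g, "molecule_graph"))
  if (g$n < 1) stop("graph has no nodes")
  if (any(!is.finite(g$coords))) stop("non-finite coordinates")
  A <- graph_adjacency(g)
  if (!isTRUE(all.equal(A, t(A)))) stop("adjacency not symmetric")
  if (any(diag(A) != 0)) stop("adjacency has nonzero diagonal")
  if (!is.null(g$features) && nrow(g$features) != nrow(g$coords))
    stop("feature rows do not match coordinate rows")
  kinds <- unique(g$edges$kind)
  if (g$kind == "PROTAC") {
    if (length(setdiff(kinds, "bond")))
      stop("PROTAC graphs may only contain bond edges")
  } else {
    if (length(setdiff(kinds, c("intra_residue", "inter_residue"))))
      stop("protein graphs may only contain intra/inter-residue edges")
  }
  invisible(g)
}

#' @export
print.molecule_graph <- function(x, ...) {
  cat(sprintf("<molecule_graph %s: %d atoms, %d edges>\n",
              x$kind, x$n, nrow(x$edges)))
  invisible(x)
}

#' Write / read a portable graph serialization
#'
#' One JSON file per sample holding adjacency (as an edge list), coordinates,
#' features, edge kinds and attributes, and provenance identifiers.
#'
#' @param g a `molecule_graph`.
#' @param path output / input file path.
#' @return `write_graph` returns `path` invisibly; `read_graph` the graph.
#' @export
write_graph <- function(g, path) {
  obj <- list(
    kind = g$kind,
    elements = g$elements,
    coords = unname(g$coords),
    features = if (is.null(g$features)) NULL else unname(g$features),
    edges = g$edges,
    residue_id = g$residue_id,
    residue_name = g$residue_name,
    provenance = g$provenance
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- molecule_graph(
    kind = obj$kind,
    elements = obj$elements,
    coords = matrix(unlist(obj$coords), ncol = 3, byrow = FALSE,
                    dimnames = NULL),
    edges = as.data.frame(obj$edges),
    residue_id = obj$residue_id,
    residue_name = obj$residue_name,
    provenance = as.list(obj$provenance)
  )
  if (!is.null(obj$features))
    g$features <- matrix(unlist(obj$features), nrow = g$n)
  g
}
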