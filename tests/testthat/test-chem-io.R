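# Structure parsing, pocket extraction and protein graph construction.

test_that("mol2 round trip preserves atoms, bonds and coordinates", {
  m <- random_molecule(12, seed = 31)
  path <- withr::local_tempfile(fileext = ".mol2")
  writeLines(m$mol2, path)
  g <- parse_mol2(path)
  expect_equal(g$n, 12)
  expect_equal(nrow(g$edges), nrow(m$graph$edges))
  expect_equal(g$coords, m$graph$coords, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(g$elements, m$graph$elements)
  expect_silent(validate_molecule_graph(g))
})

test_that("a hand-written 3-atom mol2 parses to the expected graph", {
  lines <- c("@<TRIPOS>MOLECULE", "toy", "3 2 0 0 0", "SMALL", "NO_CHARGES",
             "", "@<TRIPOS>ATOM",
             " 1 C1  0.0 0.0 0.0 C.3 1 LIG 0.0",
             " 2 O1  1.5 0.0 0.0 O.3 1 LIG 0.0",
             " 3 N1  0.0 1.4 0.0 N.3 1 LIG 0.0",
             "@<TRIPOS>BOND", " 1 1 2 1", " 2 1 3 2")
  path <- withr::local_tempfile(fileext = ".mol2")
  writeLines(lines, path)
  g <- parse_mol2(path)
  expect_equal(g$n, 3)
  expect_equal(g$elements, c("C", "O", "N"))
  expect_equal(g$coords[2, ], c(1.5, 0, 0), ignore_attr = TRUE)
  expect_equal(nrow(g$edges), 2)
  expect_setequal(g$edges$order, c("single", "double"))
})

test_that("atom order in the file does not change the molecular graph", {
  m <- random_molecule(9, seed = 77)
  path1 <- withr::local_tempfile(fileext = ".mol2")
  writeLines(m$mol2, path1)
  g1 <- parse_mol2(path1)
  # reverse the atom records; bond indices must be remapped accordingly
  n <- g1$n
  e <- m$graph$edges
  rev_map <- rev(seq_len(n))
  lines <- c("@<TRIPOS>MOLECULE", "rev", sprintf("%d %d 0 0 0", n, nrow(e)),
             "SMALL", "NO_CHARGES", "", "@<TRIPOS>ATOM",
             sprintf(" %d %s%d %.4f %.4f %.4f %s 1 LIG 0.0",
                     seq_len(n), rev(m$graph$elements), seq_len(n),
                     rev(m$graph$coords[, 1]), rev(m$graph$coords[, 2]),
                     rev(m$graph$coords[, 3]), rev(m$graph$elements)),
             "@<TRIPOS>BOND",
             sprintf(" %d %d %d %s", seq_len(nrow(e)), rev_map[e$i],
                     rev_map[e$j],
                     c(single = "1", double = "2")[e$order]))
  path2 <- withr::local_tempfile(fileext = ".mol2")
  writeLines(lines, path2)
  g2 <- parse_mol2(path2)
  # coordinates follow the atom, not the row index
  expect_equal(g2$coords[rev_map, ], g1$coords, tolerance = 1e-4,
               ignore_attr = TRUE)
  A1 <- graph_adjacency(g1)
  A2 <- graph_adjacency(g2)
  expect_equal(A2[rev_map, rev_map], A1, ignore_attr = TRUE)
})

test_that("parsed adjacency matches an independent minimal mol2 parser", {
  m <- random_molecule(12, seed = 5)
  path <- withr::local_tempfile(fileext = ".mol2")
  writeLines(m$mol2, path)
  g <- parse_mol2(path)
  ref <- ref_read_mol2(path)
  A_ref <- matrix(0L, nrow(ref$atoms), nrow(ref$atoms))
  for (k in seq_len(nrow(ref$bonds))) {
    A_ref[ref$bonds$i[k], ref$bonds$j[k]] <- 1L
    A_ref[ref$bonds$j[k], ref$bonds$i[k]] <- 1L
  }
  expect_equal(graph_adjacency(g), A_ref)
  expect_equal(g$coords, as.matrix(ref$atoms[, c("x", "y", "z")]),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("mol2 parsing drops hydrogens by default and errors on empty input", {
  lines <- c("@<TRIPOS>MOLECULE", "h2", "3 2 0 0 0", "SMALL", "NO_CHARGES",
             "", "@<TRIPOS>ATOM",
             " 1 C1 0.0 0.0 0.0 C.3 1 LIG 0.0",
             " 2 H1 1.0 0.0 0.0 H   1 LIG 0.0",
             " 3 H2 -1.0 0.0 0.0 H  1 LIG 0.0",
             "@<TRIPOS>BOND", " 1 1 2 1", " 2 1 3 1")
  path <- withr::local_tempfile(fileext = ".mol2")
  writeLines(lines, path)
  g <- parse_mol2(path)
  expect_equal(g$n, 1)
  expect_equal(nrow(g$edges), 0)
  g2 <- parse_mol2(path, keep_hydrogens = TRUE)
  expect_equal(g2$n, 3)
  expect_error(parse_mol2(withr::local_tempfile(fileext = ".mol2")),
               "not found")
})

test_that("PDB fixture with 2 residues x 3 atoms parses to 6 atoms, ids 0 and 1", {
  at <- tibble::tibble(
    element = rep(c("N", "C", "C"), 2),
    x = c(0, 1.4, 2.8, 10, 11.4, 12.8), y = 0, z = 0,
    residue_name = rep(c("ALA", "GLY"), each = 3),
    atom_name = rep(c("N", "CA", "C"), 2),
    resno = rep(1:2, each = 3), record = "ATOM"
  )
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(protacdeg:::render_pdb(at), "END"), path)
  parsed <- parse_pdb(path)
  expect_equal(nrow(parsed), 6)
  expect_equal(sort(unique(parsed$residue_id)), c(0L, 1L))
  expect_equal(parsed$residue_name[1:3], rep("ALA", 3))
})

test_that("altLoc duplicates resolve to the highest-occupancy copy", {
  lines <- c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BALA A   1       9.000   0.000   0.000  0.60  0.00           N",
    "ATOM      3  CA  ALA A   1       1.400   0.000   0.000  1.00  0.00           C",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  parsed <- parse_pdb(path)
  expect_equal(nrow(parsed), 2)
  # the B copy (occupancy 0.6) wins
  expect_equal(parsed$x[parsed$atom_name == "N"], 9.0)
})

test_that("PDB coordinates equal an independent fixed-column read", {
  pk <- random_pocket(10, seed = 8, fraction_within = 0.6)
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pk$pdb, path)
  parsed <- parse_pdb(path)
  ref <- ref_read_pdb_coords(path)
  expect_gte(nrow(parsed), 40)
  expect_equal(as.matrix(parsed[, c("x", "y", "z")]), ref[seq_len(nrow(parsed)), ],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("pocket rule keeps whole residues within the cutoff", {
  ligand <- tibble::tibble(element = "C", x = 0, y = 0, z = 0)
  receptor <- tibble::tibble(
    element = "C",
    x = c(3, 4.2, 10, 11), y = 0, z = 0,
    residue_id = c(0L, 0L, 1L, 1L),
    residue_name = c("ALA", "ALA", "GLY", "GLY")
  )
  poc <- extract_pocket(receptor, ligand, cutoff = 5)
  expect_equal(unique(poc$residue_id), 0L)
  expect_equal(nrow(poc), 2)           # the whole residue, both atoms
  # empty receptor is an empty result, not an error
  expect_equal(nrow(extract_pocket(receptor[0, ], ligand, 5)), 0)
  # a nonempty ligand is required
  expect_error(extract_pocket(receptor, ligand[0, ], 5), "nonempty")
})

test_that("pocket extraction matches brute force, nests with cutoff, and is idempotent", {
  for (seed in c(3, 14, 27)) {
    pk <- random_pocket(30, seed = seed, fraction_within = 0.4)
    rec <- pk$receptor_atoms
    lig <- pk$ligand_atoms
    p5 <- extract_pocket(rec, lig, 5)
    ref <- ref_pocket(rec, lig, 5)
    expect_equal(sort(unique(p5$residue_id)), sort(unique(ref$residue_id)))
    # monotonicity: pocket(5) is a subset of pocket(6)
    p6 <- extract_pocket(rec, lig, 6)
    expect_true(all(unique(p5$residue_id) %in% unique(p6$residue_id)))
    # idempotence on its own output
    expect_equal(extract_pocket(p5, lig, 5), p5)
  }
})

test_that("protein graph edges split into intra and inter by distance", {
  atoms <- tibble::tibble(
    element = rep("C", 4),
    x = c(0, 1.4, 20, 21.4), y = 0, z = 0,
    residue_id = c(0L, 0L, 1L, 1L),
    residue_name = "ALA"
  )
  g <- build_protein_graph(atoms, "POI", inter_cutoff = 4.5)
  expect_equal(unique(g$edges$kind), "intra_residue")
  expect_equal(nrow(g$edges), 2)
  # move residue 1 so exactly one cross pair sits just inside the cutoff
  atoms2 <- atoms
  atoms2$x[3:4] <- c(1.4 + 4.5 - 1e-6, 1.4 + 4.5 - 1e-6 + 1.4)
  g2 <- build_protein_graph(atoms2, "POI", inter_cutoff = 4.5)
  expect_equal(sum(g2$edges$kind == "inter_residue"), 1)
  # and just outside: no inter edge
  atoms3 <- atoms
  atoms3$x[3:4] <- c(1.4 + 4.5 + 1e-6, 1.4 + 4.5 + 1e-6 + 1.4)
  g3 <- build_protein_graph(atoms3, "POI", inter_cutoff = 4.5)
  expect_equal(sum(g3$edges$kind == "inter_residue"), 0)
})

test_that("protein graph edge set equals all-pairs brute force on random pockets", {
  for (seed in c(2, 9)) {
    pk <- random_pocket(5, seed = seed, fraction_within = 1)
    poc <- extract_pocket(pk$receptor_atoms, pk$ligand_atoms, 5)
    g <- build_protein_graph(poc, "E3", inter_cutoff = 4.5, intra_cutoff = 1.9)
    xyz <- as.matrix(poc[, c("x", "y", "z")])
    res <- poc$residue_id
    expected <- list()
    for (i in seq_len(nrow(poc) - 1)) for (j in (i + 1):nrow(poc)) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      kind <- if (res[i] == res[j] && d <= 1.9) "intra_residue"
        else if (res[i] != res[j] && d <= 4.5) "inter_residue" else NA
      if (!is.na(kind)) expected[[length(expected) + 1]] <- c(i, j, kind)
    }
    exp_df <- do.call(rbind, expected)
    got <- g$edges[order(g$edges$i, g$edges$j), ]
    expect_equal(nrow(got), nrow(exp_df))
    expect_equal(got$i, as.integer(exp_df[, 1]))
    expect_equal(got$j, as.integer(exp_df[, 2]))
    expect_equal(got$kind, exp_df[, 3])
  }
})

test_that("single-atom pocket yields one node and no edges", {
  atoms <- tibble::tibble(element = "C", x = 0, y = 0, z = 0,
                          residue_id = 0L, residue_name = "GLY")
  g <- build_protein_graph(atoms, "POI")
  expect_equal(g$n, 1)
  expect_equal(nrow(g$edges), 0)
  expect_silent(validate_molecule_graph(g))
})

test_that("graph topology is invariant to rigid motions of the input", {
  pk <- random_pocket(6, seed = 12, fraction_within = 0.7)
  rec <- pk$receptor_atoms; lig <- pk$ligand_atoms
  tr <- random_transform(seed = 4)
  move <- function(df) {
    m <- as.matrix(df[, c("x", "y", "z")]) %*% t(tr$rotation)
    df$x <- m[, 1] + tr$translation[1]
    df$y <- m[, 2] + tr$translation[2]
    df$z <- m[, 3] + tr$translation[3]
    df
  }
  p1 <- extract_pocket(rec, lig, 5)
  p2 <- extract_pocket(move(rec), move(lig), 5)
  expect_equal(p1$residue_id, p2$residue_id)
  g1 <- build_protein_graph(p1, "POI")
  g2 <- build_protein_graph(p2, "POI")
  expect_equal(g1$edges[, c("i", "j", "kind")], g2$edges[, c("i", "j", "kind")])
})

test_that("graph serialization round-trips through JSON", {
  g <- make_pocket_graph("E3", seed = 21)
  path <- withr::local_tempfile(fileext = ".json")
  write_graph(g, path)
  g2 <- read_graph(path)
  expect_equal(g2$kind, g$kind)
  expect_equal(g2$coords, g$coords, ignore_attr = TRUE)
  expect_equal(g2$edges$i, g$edges$i)
  expect_equal(g2$edges$kind, g$edges$kind)
  expect_equal(g2$features, g$features, ignore_attr = TRUE)
  expect_equal(g2$edge_attr, g$edge_attr, ignore_attr = TRUE)
})
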