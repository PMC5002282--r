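# PDB parsing, parameter assignment and ligand selection

two_leu_pdb <- function() {
  # hand-written 2-residue (LEU-LEU), 16-atom structure
  c("ATOM      1  N   LEU A   1      10.000  10.000  10.000  1.00  0.00           N",
    "ATOM      2  CA  LEU A   1      11.458  10.000  10.000  1.00  0.00           C",
    "ATOM      3  C   LEU A   1      12.009  11.420  10.000  1.00  0.00           C",
    "ATOM      4  O   LEU A   1      11.251  12.390  10.000  1.00  0.00           O",
    "ATOM      5  CB  LEU A   1      11.990   9.210  11.200  1.00  0.00           C",
    "ATOM      6  CG  LEU A   1      13.500   9.100  11.300  1.00  0.00           C",
    "ATOM      7  CD1 LEU A   1      13.980   8.200  12.440  1.00  0.00           C",
    "ATOM      8  CD2 LEU A   1      14.120   8.600  10.000  1.00  0.00           C",
    "ATOM      9  N   LEU A   2      13.340  11.560  10.000  1.00  0.00           N",
    "ATOM     10  CA  LEU A   2      14.010  12.860  10.000  1.00  0.00           C",
    "ATOM     11  C   LEU A   2      15.520  12.700  10.100  1.00  0.00           C",
    "ATOM     12  O   LEU A   2      16.050  11.590  10.200  1.00  0.00           O",
    "ATOM     13  CB  LEU A   2      13.650  13.680  11.250  1.00  0.00           C",
    "ATOM     14  CG  LEU A   2      12.180  14.110  11.350  1.00  0.00           C",
    "ATOM     15  CD1 LEU A   2      11.920  14.910  12.620  1.00  0.00           C",
    "ATOM     16  CD2 LEU A   2      11.800  14.950  10.140  1.00  0.00           C",
    "END")
}

test_that("parsing a hand-written structure recovers atoms and residues", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(two_leu_pdb(), path)
  at <- read_structure(path)
  expect_equal(nrow(at), 16)
  expect_equal(nrow(structure_residues(at)), 2)
  expect_equal(unique(at$chain), "A")
  expect_equal(at$name[1:4], c("N", "CA", "C", "O"))
  expect_equal(at$x[2], 11.458)
  expect_false(any(at$is_hydrogen))
  expect_equal(chain_sequence(at, "A")$aa, c("L", "L"))
  expect_error(read_structure(withr::local_tempfile(fileext = ".pdb")),
               "cannot read")
})

test_that("parsing errors on files without ATOM records", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
               "END"), path)
  expect_error(read_structure(path), "no ATOM records")
})

test_that("only the requested model of a multi-model file is read", {
  path <- withr::local_tempfile(fileext = ".pdb")
  atom1 <- two_leu_pdb()[1:16]
  atom2 <- sub("10.000  10.000  10.000", "20.000  20.000  20.000",
               atom1, fixed = TRUE)
  writeLines(c("MODEL        1", atom1, "ENDMDL",
               "MODEL        2", atom2, "ENDMDL", "END"), path)
  m1 <- read_structure(path, model = 1)
  m2 <- read_structure(path, model = 2)
  expect_equal(nrow(m1), 16)
  expect_equal(m1$x[1], 10.0)
  expect_equal(m2$x[1], 20.0)
  expect_equal(m1$x[-1], m2$x[-1])
  expect_error(read_structure(path, model = 3), "out of range")
})

test_that("alternate locations resolve to one atom by the occupancy policy", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(
    c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
      "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.60  0.00           C",
      "ATOM      3  CA BALA A   1       1.600   0.100   0.000  0.40  0.00           C",
      "ATOM      4  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
      "END"), path)
  at <- read_structure(path)
  expect_equal(nrow(at), 3)
  ca <- at[at$name == "CA", ]
  expect_equal(ca$altloc, "A")
  expect_equal(ca$x, 1.458)
  # ties go to the first record in file order
  tie <- sub("0.60", "0.40", readLines(path), fixed = TRUE)
  writeLines(tie, path)
  at2 <- read_structure(path)
  expect_equal(at2[at2$name == "CA", ]$altloc, "A")
})

test_that("write + re-parse round-trips atoms, coordinates and residues", {
  fx <- small_fixture()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(fx$atoms, path)
  back <- read_structure(path)
  for (col in c("record", "name", "resname", "chain", "resseq", "element"))
    expect_equal(back[[col]], fx$atoms[[col]])
  expect_equal(back$x, round(fx$atoms$x, 3))
  expect_equal(back$y, round(fx$atoms$y, 3))
  expect_equal(back$z, round(fx$atoms$z, 3))
  expect_equal(structure_residues(back), structure_residues(fx$atoms))
})

test_that("parm94 parameters attach by residue/atom name", {
  params <- vdw_param_table()
  ct <- params[params$type == "CT", ]
  amide_h <- params[params$type == "H", ]

  at <- toy_atoms(c(0, 1.5, 3), c(0, 0, 0), c(0, 0, 0),
                  name = c("CB", "N", "H"), resname = "ALA",
                  resseq = c(1, 1, 1), element = c("C", "N", "H"))
  out <- assign_vdw_params(at)
  expect_equal(out$type, c("CT", "N", "H"))
  expect_equal(out$r_vdw[1], ct$r_vdw)
  expect_equal(out$eps[1], ct$eps)
  expect_equal(out$r_vdw[3], amide_h$r_vdw)
  expect_equal(out$eps[3], amide_h$eps)
  # fully mapped input comes back unchanged apart from the parameter columns
  expect_equal(out[names(at)], at)
})

test_that("unmapped atoms fall back to element-generic parameters or error", {
  at <- toy_atoms(c(0, 2), c(0, 0), c(0, 0), name = c("CA", "SE"),
                  resname = c("GLY", "MSE"), resseq = c(1, 2),
                  element = c("C", "SE"))
  expect_warning(out <- assign_vdw_params(at), "element-generic")
  expect_equal(out$type[2], "S-generic")
  expect_true(out$r_vdw[2] > 0)
  expect_error(assign_vdw_params(at, fallback = FALSE), "MSE/SE")
})

test_that("ligand filter enforces the heavy-atom and contact thresholds", {
  # 9 heavy atoms with abundant contacts: rejected
  at9 <- ligand_filter_case(n_heavy = 9, n_close = 25)
  expect_equal(nrow(select_ligands(at9)), 0)
  # 10 heavy atoms, exactly 69 contacts: rejected; exactly 70: accepted
  at69 <- ligand_filter_case(n_heavy = 10, n_close = 6, tuner_z = -3.2)
  at70 <- ligand_filter_case(n_heavy = 10, n_close = 6, tuner_z = -3.0)
  expect_equal(nrow(select_ligands(at69)), 0)
  lig <- select_ligands(at70)
  expect_equal(nrow(lig), 1)
  expect_equal(lig$n_heavy, 10L)
  expect_equal(lig$n_contacts, 70L)
  expect_equal(lig$components[[1]], "LIG")
})

test_that("water is excluded and raising thresholds never adds a ligand", {
  water <- toy_atoms(runif(20, 0, 3), runif(20, 0, 3), runif(20, 0, 3),
                     record = "HETATM", name = "O", resname = "HOH",
                     resseq = 1:20, element = "O")
  prot <- toy_atoms(0, 0, 0)
  expect_equal(nrow(select_ligands(bind_rows(prot, water))), 0)

  at <- ligand_filter_case(n_heavy = 12, n_close = 8)
  base <- select_ligands(at)
  expect_equal(nrow(base), 1)
  for (mh in c(10, 13)) for (mc in c(70, 200)) {
    harder <- select_ligands(at, min_heavy = mh, min_contacts = mc)
    expect_lte(nrow(harder), nrow(base))
  }
})

test_that("single-linkage HET grouping matches a connected-components oracle", {
  skip_if_not_installed("igraph")
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:50, 1)
    xyz <- matrix(runif(3 * n, 0, 12), ncol = 3)
    got <- pocketcons:::single_linkage_groups(xyz, 4.0)
    adj <- as.matrix(dist(xyz)) <= 4.0
    ref <- igraph::components(
      igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))$membership
    # same partition: co-membership matrices agree
    expect_equal(unname(outer(got, got, "==")),
                 unname(outer(unname(ref), unname(ref), "==")))
  }
})
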