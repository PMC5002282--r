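#' Specification of a synthetic pocket fixture
#'
#' The generator emits a fully synthetic protein-like structure: a slab of
#' CA-only glycine pseudo-residues on a 2 Angstrom lattice with a
#' hemispherical pocket carved into the top face, a compact pseudo-ligand
#' (HET code `LIG`, carbon atoms) planted in the cavity close enough to the
#' wall to pass the biological-ligand filter (at least 10 heavy atoms and
#' 70 contacts within 4 Angstrom), and the true binding residues by the
#' 4 Angstrom rule.  With `dimer = TRUE` a second chain, an exact rigid
#' (translated) copy of the first including its ligand, creates two
#' geometrically identical pockets.  Identical spec and seed give
#' byte-identical output files.
#'
#' @param pocket_radius,pocket_depth Cavity radius and depth in Angstrom.
#' @param wall_atom_count Approximate number of wall atoms per chain; sets
#'   the lateral size of the slab.
#' @param conserved_pocket Mark pocket-lining residues as conserved in the
#'   generated conservation files.
#' @param dimer Emit a two-chain homodimer with two symmetric pockets.
#' @param seed Integer seed for the small random jitter on wall atoms.
#' @return A `pocket_fixture_spec` list.
#' @export
pocket_fixture_spec <- function(pocket_radius = 5, pocket_depth = 5,
                                wall_atom_count = 1500L,
                                conserved_pocket = TRUE, dimer = FALSE,
                                seed = 1L) {
  if (pocket_radius <= 0 || pocket_depth <= 0)
    abort("pocket geometry parameters must be positive")
  structure(list(pocket_radius = pocket_radius, pocket_depth = pocket_depth,
                 wall_atom_count = as.integer(wall_atom_count),
                 conserved_pocket = isTRUE(conserved_pocket),
                 dimer = isTRUE(dimer), seed = as.integer(seed)),
            class = "pocket_fixture_spec")
}

# fixed construction constants: wall lattice spacing, slab thickness,
# ligand stand-off from the cavity surface, jitter amplitude
FIXTURE_LATTICE <- 2.0
FIXTURE_THICKNESS <- 10.0
FIXTURE_LIGAND_STANDOFF <- 2.7
FIXTURE_JITTER <- 0.15
FIXTURE_DIMER_GAP <- 4.0

#' Generate a synthetic pocket structure
#'
#' Writes `structure.pdb` (ATOM records for the wall residues, HETATM for
#' the planted pseudo-ligand) and `truth_residues.tsv` (the 4 Angstrom
#' ground truth) into `dir`, verifies that [select_ligands()] with the
#' default filters accepts exactly the planted ligand(s), and returns the
#' parsed pieces.
#'
#' @param spec A [pocket_fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return List with `spec`, `dir`, `pdb` (path), `truth_tsv` (path),
#'   `atoms` (parsed atom tibble), `ligands` ([select_ligands()] result),
#'   `truth` (residue tibble) and `pocket_center` (per-chain list of
#'   cavity centers).
#' @export
make_pocket_structure <- function(spec = pocket_fixture_spec(),
                                  dir = tempfile("pocket_fixture")) {
  stopifnot(inherits(spec, "pocket_fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  a <- FIXTURE_LATTICE
  n_layers <- round(FIXTURE_THICKNESS / a) + 1L
  n_side <- max(4L, as.integer(ceiling(sqrt(spec$wall_atom_count / n_layers))))
  L <- (n_side - 1) * a
  # cavity centre sits halfway between lattice sites so the wall-atom shell
  # around the ligand is independent of the slab size parity
  cxy <- a * floor((n_side - 1) / 2) + a / 2
  centre <- c(cxy, cxy, spec$pocket_radius - spec$pocket_depth)

  lat <- expand.grid(x = seq(0, L, by = a), y = seq(0, L, by = a),
                     z = seq(0, -FIXTURE_THICKNESS, by = -a))
  d_centre <- sqrt((lat$x - centre[1])^2 + (lat$y - centre[2])^2 +
                     (lat$z - centre[3])^2)
  lat <- lat[d_centre >= spec$pocket_radius, , drop = FALSE]

  set.seed(spec$seed)
  jit <- matrix(stats::runif(3 * nrow(lat), -FIXTURE_JITTER, FIXTURE_JITTER),
                ncol = 3)
  wall <- tibble(x = round(lat$x + jit[, 1], 3),
                 y = round(lat$y + jit[, 2], 3),
                 z = round(lat$z + jit[, 3], 3))

  rl <- spec$pocket_radius - FIXTURE_LIGAND_STANDOFF
  if (rl <= 0.3)
    abort(paste0("infeasible fixture geometry: pocket_radius must exceed ",
                 FIXTURE_LIGAND_STANDOFF + 0.3,
                 " A for the ligand to fit; increase pocket_radius"))
  dirs <- fibonacci_lower_hemisphere(12L)
  lig <- tibble(x = round(centre[1] + rl * dirs[, 1], 3),
                y = round(centre[2] + rl * dirs[, 2], 3),
                z = round(centre[3] + rl * dirs[, 3], 3))
  lig <- lig[lig$z < 0.0, , drop = FALSE]

  chains <- if (spec$dimer) c("A", "B") else "A"
  offset <- L + FIXTURE_DIMER_GAP
  atom_rows <- list()
  serial <- 0L
  for (ci in seq_along(chains)) {
    dx <- (ci - 1) * offset
    nres <- nrow(wall)
    atom_rows[[length(atom_rows) + 1]] <- tibble(
      record = "ATOM", serial = serial + seq_len(nres), name = "CA",
      altloc = "", resname = "GLY", chain = chains[ci],
      resseq = seq_len(nres), icode = "",
      x = wall$x + dx, y = wall$y, z = wall$z,
      occupancy = 1, bfactor = 0, element = "C")
    serial <- serial + nres
  }
  for (ci in seq_along(chains)) {
    dx <- (ci - 1) * offset
    nl <- nrow(lig)
    atom_rows[[length(atom_rows) + 1]] <- tibble(
      record = "HETATM", serial = serial + seq_len(nl),
      name = paste0("C", seq_len(nl)), altloc = "", resname = "LIG",
      chain = chains[ci], resseq = 9001L, icode = "",
      x = lig$x + dx, y = lig$y, z = lig$z,
      occupancy = 1, bfactor = 0, element = "C")
    serial <- serial + nl
  }
  all_atoms <- bind_rows(atom_rows)

  pdb_path <- file.path(dir, "structure.pdb")
  write_structure_pdb(all_atoms, pdb_path)
  atoms <- read_structure(pdb_path)

  ligands <- select_ligands(atoms)
  if (nrow(ligands) != length(chains))
    abort(paste0("infeasible fixture geometry: the planted ligand fails the ",
                 "biological-ligand filter (", nrow(ligands), " of ",
                 length(chains), " groups accepted); increase ",
                 "wall_atom_count or pocket_radius"))

  truth <- true_binding_residues(atoms, ligands, radius = 4)
  truth_tsv <- file.path(dir, "truth_residues.tsv")
  utils::write.table(truth |> select("chain", "resseq", "icode", "resname"),
                     truth_tsv, sep = "\t", row.names = FALSE, quote = FALSE)

  centers <- lapply(seq_along(chains), function(ci)
    centre + c((ci - 1) * offset, 0, 0))
  names(centers) <- chains
  list(spec = spec, dir = dir, pdb = pdb_path, truth_tsv = truth_tsv,
       atoms = atoms, ligands = ligands, truth = truth,
       pocket_center = centers)
}

# deterministic, roughly uniform directions on the lower unit hemisphere
fibonacci_lower_hemisphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- -i / n                      # z in (-1, 0): lower hemisphere only
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- 2 * pi * i * (sqrt(5) - 1) / 2
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Generate matched conservation inputs for a fixture
#'
#' For every chain of the fixture, emits a PSI-BLAST-style ASCII PSSM and an
#' equivalent aligned FASTA.  On conserved chains the pocket-lining (truth)
#' residues receive near-single-letter position profiles; everything else
#' stays near the background.  Per position the generating frequency vector
#' is `conc * delta(query letter) + (1 - conc) * background` with
#' `conc = high` on conserved pocket positions and `conc = low` elsewhere.
#'
#' @param fixture Result of [make_pocket_structure()].
#' @param high,low Concentration levels, `0 <= low < high <= 1`.
#' @param conserved_chains Chains whose pocket positions are conserved
#'   (defaults to all chains when the spec says `conserved_pocket`, none
#'   otherwise).
#' @param n_msa_seqs Number of sequences in the emitted alignment.
#' @param background Background distribution.
#' @return Tibble with one row per chain: `chain`, `pssm` and `msa` file
#'   paths, and `profile` (list-column with the generating frequencies).
#' @export
make_conservation_files <- function(fixture, high = 0.95, low = 0.05,
                                    conserved_chains = NULL,
                                    n_msa_seqs = 100L,
                                    background = background_frequencies()) {
  if (!(low >= 0 && low < high && high <= 1))
    abort("concentrations must satisfy 0 <= low < high <= 1")
  atoms <- fixture$atoms
  chains <- names(fixture$pocket_center)
  if (is.null(conserved_chains))
    conserved_chains <- if (fixture$spec$conserved_pocket) chains else
      character(0)

  purrr::map_dfr(chains, function(ch) {
    seqtb <- chain_sequence(atoms, ch)
    pocket <- fixture$truth |> filter(.data$chain == ch)
    conc <- rep(low, nrow(seqtb))
    if (ch %in% conserved_chains)
      conc[seqtb$resseq %in% pocket$resseq] <- high
    prof <- build_fixture_profile(seqtb$aa, conc, background)
    pssm_path <- file.path(fixture$dir, paste0("conservation_", ch, ".pssm"))
    msa_path <- file.path(fixture$dir, paste0("conservation_", ch, ".fasta"))
    write_fixture_pssm(prof, seqtb$aa, background, pssm_path)
    write_fixture_msa(prof, seqtb$aa, n_msa_seqs, msa_path)
    tibble(chain = ch, pssm = pssm_path, msa = msa_path,
           profile = list(prof))
  })
}

build_fixture_profile <- function(aa, conc, background) {
  prof <- matrix(rep(background, length(aa)), nrow = length(aa),
                 byrow = TRUE, dimnames = list(NULL, AA20))
  prof <- prof * (1 - conc)
  idx <- match(aa, AA20)
  prof[cbind(seq_along(aa), idx)] <- prof[cbind(seq_along(aa), idx)] + conc
  prof
}

write_fixture_pssm <- function(prof, aa, background, path) {
  n <- nrow(prof)
  pct <- round(100 * prof)
  lo <- round(2 * log2(pmax(prof, 1e-4) / rep(background, each = n)))
  hdr <- paste0("           ",
                paste(sprintf("%3s", AA20), collapse = ""),
                " ", paste(sprintf("%3s", AA20), collapse = ""))
  rows <- vapply(seq_len(n), function(i) {
    sprintf("%5d %s  %s  %s %5.2f %8.2f", i, aa[i],
            paste(sprintf("%3d", lo[i, ]), collapse = ""),
            paste(sprintf("%3d", pct[i, ]), collapse = ""),
            0, 0)
  }, character(1))
  writeLines(c("",
               paste("Last position-specific scoring matrix computed,",
                     "weighted observed percentages rounded down,",
                     "information per position, and relative weight of",
                     "gapless real matches to pseudocounts"),
               hdr, rows, "", "                      K         Lambda"), path)
  invisible(path)
}

write_fixture_msa <- function(prof, aa, n_seqs, path) {
  n <- nrow(prof)
  cols <- matrix("", nrow = n_seqs, ncol = n)
  for (i in seq_len(n)) {
    counts <- round(prof[i, ] * n_seqs)
    qi <- match(aa[i], AA20)
    counts[qi] <- max(1L, counts[qi] + (n_seqs - sum(counts)))
    pool <- rep(AA20, times = counts)
    pool <- c(aa[i], pool[-match(aa[i], pool)])    # query letter first
    length(pool) <- n_seqs
    pool[is.na(pool)] <- aa[i]
    cols[, i] <- pool
  }
  seqs <- apply(cols, 1, paste, collapse = "")
  out <- character(2 * n_seqs)
  out[c(TRUE, FALSE)] <- paste0(">seq", seq_len(n_seqs),
                                ifelse(seq_len(n_seqs) == 1, " query", ""))
  out[c(FALSE, TRUE)] <- seqs
  writeLines(out, path)
  invisible(path)
}
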