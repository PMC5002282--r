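#' Build a probe grid around a protein
#'
#' Axis-aligned regular grid covering the protein bounding box expanded by
#' `margin` on all sides.  Positions are exactly reproducible from the grid
#' specification: `position = origin + spacing * index`.
#'
#' @param atoms Atom tibble; only `ATOM` records define the bounding box.
#' @param spacing Grid spacing in Angstrom.
#' @param margin Box extension in Angstrom.
#' @return A `grid_spec`: list with `origin` (3-vector), `spacing`, `shape`
#'   (integer 3-vector), `margin`.
#' @export
build_grid <- function(atoms, spacing = 0.5, margin = 8) {
  if (spacing <= 0) abort("grid spacing must be > 0")
  if (margin < 0) abort("grid margin must be >= 0")
  prot <- atoms |> filter(.data$record == "ATOM")
  if (nrow(prot) == 0) abort("structure has no protein atoms")
  lo <- c(min(prot$x), min(prot$y), min(prot$z)) - margin
  hi <- c(max(prot$x), max(prot$y), max(prot$z)) + margin
  shape <- as.integer(ceiling((hi - lo) / spacing - 1e-9)) + 1L
  structure(list(origin = lo, spacing = spacing, shape = shape,
                 margin = margin),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> origin (%.3f, %.3f, %.3f), spacing %.3g A, shape %s (%d probes)\n",
              x$origin[1], x$origin[2], x$origin[3], x$spacing,
              paste(x$shape, collapse = " x "), prod(x$shape)))
  invisible(x)
}

#' Enumerate grid probe positions
#'
#' @param grid A `grid_spec` from [build_grid()].
#' @return Tibble with 0-based integer indices `ix`, `iy`, `iz` and
#'   positions `x`, `y`, `z`.
#' @export
grid_probes <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  s <- grid$shape
  ix <- rep.int(seq_len(s[1]) - 1L, s[2] * s[3])
  iy <- rep.int(rep(seq_len(s[2]) - 1L, each = s[1]), s[3])
  iz <- rep(seq_len(s[3]) - 1L, each = s[1] * s[2])
  tibble(ix = ix, iy = iy, iz = iz,
         x = grid$origin[1] + grid$spacing * ix,
         y = grid$origin[2] + grid$spacing * iy,
         z = grid$origin[3] + grid$spacing * iz)
}

#' Lennard-Jones 6-12 pair energy
#'
#' `sqrt(eps_i * eps_j) * (((R_i + R_j) / r)^12 - 2 * ((R_i + R_j) / r)^6)`:
#' the minimum is exactly `-sqrt(eps_i * eps_j)` at `r = R_i + R_j` and the
#' zero crossing sits at `r = (R_i + R_j) / 2^(1/6)`.  The well depths enter
#' through their geometric mean.  Vectorized over all arguments.
#'
#' @param r Interatomic distance(s) in Angstrom, strictly positive.
#' @param r_i,eps_i van der Waals radius and well depth of the probe.
#' @param r_j,eps_j van der Waals radius and well depth of the atom.
#' @return Energy in kcal/mol.
#' @export
lj_energy <- function(r, r_i, eps_i, r_j, eps_j) {
  if (any(r <= 0)) abort("lj_energy requires r > 0")
  s6 <- ((r_i + r_j) / r)^6
  sqrt(eps_i * eps_j) * (s6 * s6 - 2 * s6)
}

#' Compute probe van der Waals energies
#'
#' Sums the Lennard-Jones pair energy between each probe and every
#' parameterized protein atom within `cutoff` (boundary inclusive), using a
#' cell-list spatial index.  Probes with no atom in range get energy 0.
#'
#' @param probes Probe tibble with `x`, `y`, `z` (e.g. from [grid_probes()]).
#' @param atoms Parameterized atom tibble from [assign_vdw_params()].
#' @param cutoff Neighbor cutoff in Angstrom.
#' @param probe_radius,probe_depth Probe vdW parameters (parm94 aliphatic
#'   carbon by default).
#' @param ignore_hydrogens Drop hydrogen atoms from the sum.
#' @return `probes` with an `e_vdw` column added.
#' @export
compute_probe_energies <- function(probes, atoms, cutoff = 10,
                                   probe_radius = 1.9080,
                                   probe_depth = 0.1094,
                                   ignore_hydrogens = FALSE) {
  prot <- protein_energy_atoms(atoms, ignore_hydrogens)
  e <- probe_energies_cpp(as_xyz(probes), as_xyz(prot), prot$r_vdw, prot$eps,
                          probe_radius, probe_depth, cutoff)
  probes$e_vdw <- e
  probes
}

protein_energy_atoms <- function(atoms, ignore_hydrogens = FALSE) {
  prot <- atoms |> filter(.data$record == "ATOM")
  if (ignore_hydrogens) prot <- prot |> filter(!.data$is_hydrogen)
  if (!("r_vdw" %in% names(prot)) || anyNA(prot$r_vdw) || anyNA(prot$eps))
    abort("atoms without vdW parameters: run assign_vdw_params() first")
  prot
}

#' All-pairs reference implementation of the probe energies
#'
#' Literal double-loop transcription of the energy sum, without any spatial
#' index.  Serves as the independent oracle for
#' [compute_probe_energies()] in tests; quadratic cost, small inputs only.
#'
#' @inheritParams compute_probe_energies
#' @return `probes` with an `e_vdw` column added.
#' @export
probe_energies_brute <- function(probes, atoms, cutoff = 10,
                                 probe_radius = 1.9080,
                                 probe_depth = 0.1094,
                                 ignore_hydrogens = FALSE) {
  prot <- protein_energy_atoms(atoms, ignore_hydrogens)
  e <- numeric(nrow(probes))
  for (i in seq_len(nrow(probes))) {
    total <- 0
    for (j in seq_len(nrow(prot))) {
      r <- sqrt((probes$x[i] - prot$x[j])^2 + (probes$y[i] - prot$y[j])^2 +
                  (probes$z[i] - prot$z[j])^2)
      if (r <= cutoff)
        total <- total + lj_energy(r, probe_radius, probe_depth,
                                   prot$r_vdw[j], prot$eps[j])
    }
    e[i] <- total
  }
  probes$e_vdw <- e
  probes
}

#' Discard repulsive probes
#'
#' Removes probes with `e_vdw > e_max` (default 0: keep only non-repulsive
#' positions).  Because clustering activates probes from the lowest energy
#' upwards, pruning at any `e_max` at or above the final clustering
#' threshold leaves the clustering result unchanged.
#'
#' @param probes Probe tibble with `e_vdw`.
#' @param e_max Retention threshold in kcal/mol.
#' @return Filtered probe tibble.
#' @export
prune_probes <- function(probes, e_max = 0) {
  probes |> filter(.data$e_vdw <= e_max)
}

#' Dump probes as a PDB of pseudo-atoms
#'
#' Writes probes as carbon pseudo-atoms with the probe energy in the
#' B-factor column, for inspection in a molecular viewer.
#'
#' @param probes Probe tibble with `x`, `y`, `z` and `e_vdw`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probes_pdb <- function(probes, path) {
  at <- tibble(record = "HETATM", serial = seq_len(nrow(probes)),
               name = "C", altloc = "", resname = "PRB", chain = "X",
               resseq = 1L, icode = "",
               x = probes$x, y = probes$y, z = probes$z,
               occupancy = 1, bfactor = pmax(pmin(probes$e_vdw, 999), -999),
               element = "C")
  write_structure_pdb(at, path)
}
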