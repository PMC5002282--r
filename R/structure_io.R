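#' Read a PDB structure into an atom table
#'
#' Parses a PDB file (via \pkg{bio3d}) into one tibble with a row per atom.
#' `ATOM` records form the protein; `HETATM` records are retained in the same
#' table (column `record`) for ligand selection.  Only the requested model is
#' read; alternate locations are resolved to a single atom per
#' (chain, residue, name) according to `altloc`.
#'
#' @param path Path to a PDB file containing at least one `ATOM` record.
#' @param model 1-based model index for multi-model files.
#' @param altloc Alternate-location policy: `"occupancy"` keeps the highest
#'   occupancy copy (ties resolved to the first in file order), `"first"`
#'   keeps the first copy in file order.
#' @return A tibble with columns `record`, `serial`, `name`, `altloc`,
#'   `resname`, `chain`, `resseq`, `icode`, `x`, `y`, `z`, `occupancy`,
#'   `bfactor`, `element`, `is_hydrogen`, `res_uid`, `res_index`.
#'   `res_index` numbers residues consecutively in file order (protein
#'   residues first).
#' @export
read_structure <- function(path, model = 1L, altloc = c("occupancy", "first")) {
  altloc <- match.arg(altloc)
  if (!file.exists(path)) abort(paste0("cannot read PDB file: ", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) abort(paste0("unreadable PDB file: ", path, " (",
                                     conditionMessage(e), ")")))
  at <- pdb$atom
  if (!any(at$type == "ATOM"))
    abort(paste0("no ATOM records in ", path, ": empty structure"))

  xyz <- pdb$xyz
  if (is.matrix(xyz) && nrow(xyz) > 1) {
    if (model < 1 || model > nrow(xyz))
      abort(paste0("model index ", model, " out of range (file has ",
                   nrow(xyz), " models)"))
    coords <- matrix(xyz[model, ], ncol = 3, byrow = TRUE)
    at$x <- coords[, 1]; at$y <- coords[, 2]; at$z <- coords[, 3]
  } else if (model != 1) {
    abort("model index > 1 requested but file has a single model")
  }

  atoms <- tibble(
    record = at$type,
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    altloc = ifelse(is.na(at$alt), "", trimws(at$alt)),
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "", at$chain),
    resseq = as.integer(at$resno),
    icode = ifelse(is.na(at$insert), "", trimws(at$insert)),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    bfactor = ifelse(is.na(at$b), 0, at$b)
  )
  elesy <- if (!is.null(at$elesy)) trimws(at$elesy) else rep("", nrow(atoms))
  atoms$element <- ifelse(nzchar(elesy), toupper(elesy),
                          guess_element(atoms$name))
  atoms$is_hydrogen <- atoms$element %in% c("H", "D")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    abort("non-finite coordinates in PDB file")

  atoms <- resolve_altloc(atoms, policy = altloc)
  atoms$res_uid <- res_key(atoms$chain, atoms$resseq, atoms$icode)
  ord <- c(which(atoms$record == "ATOM"), which(atoms$record != "ATOM"))
  uids <- unique(atoms$res_uid[ord])
  atoms$res_index <- match(atoms$res_uid, uids)
  atoms
}

guess_element <- function(name) {
  core <- gsub("[0-9' ]", "", name)
  el <- ifelse(grepl("^[0-9]*[HD]", name), "H", substr(core, 1, 1))
  # two-letter elements common in PDB het groups
  el <- ifelse(core %in% c("FE", "ZN", "MG", "MN", "CU", "SE", "NI", "BR",
                           "CL", "CO"), core, el)
  toupper(el)
}

resolve_altloc <- function(atoms, policy = "occupancy") {
  if (all(atoms$altloc == "")) return(atoms)
  atoms$.row <- seq_len(nrow(atoms))
  picked <- atoms |>
    group_by(.data$record, .data$chain, .data$resseq, .data$icode,
             .data$resname, .data$name) |>
    group_modify(function(g, key) {
      if (nrow(g) == 1) return(g)
      if (policy == "occupancy") {
        best <- which(g$occupancy == max(g$occupancy))[1]
      } else {
        best <- 1L
      }
      g[best, , drop = FALSE]
    }) |>
    ungroup() |>
    arrange(.data$.row)
  picked$.row <- NULL
  picked
}

#' Write an atom table back to PDB
#'
#' Fixed-width PDB writer for parsed or synthetic atom tables; coordinates
#' are written to three decimals.  Used for fixtures, round-trips and
#' cluster dumps.
#'
#' @param atoms Atom tibble as returned by [read_structure()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(atoms, path) {
  lines <- pdb_atom_lines(atoms)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

pdb_atom_lines <- function(atoms) {
  name_fld <- ifelse(nchar(atoms$name) < 4,
                     sprintf(" %-3s", atoms$name),
                     substr(atoms$name, 1, 4))
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$record, atoms$serial %% 100000L, name_fld,
          ifelse(atoms$altloc == "", " ", atoms$altloc),
          atoms$resname,
          ifelse(atoms$chain == "", " ", atoms$chain),
          atoms$resseq,
          ifelse(atoms$icode == "", " ", atoms$icode),
          atoms$x, atoms$y, atoms$z, atoms$occupancy, atoms$bfactor,
          atoms$element)
}

#' Assign parm94 van der Waals parameters to protein atoms
#'
#' Maps each `ATOM`-record atom name to a parm94 atom type through the
#' shipped name map and attaches the type's van der Waals radius and well
#' depth.  Atoms of non-standard residues (or names missing from the map)
#' fall back to element-generic parameters with a warning; with
#' `fallback = FALSE` they raise an error listing the offending atoms.
#'
#' @param atoms Atom tibble from [read_structure()].
#' @param param_table parm94 parameter tibble, see [vdw_param_table()].
#' @param name_map Atom-name map tibble, see [atom_type_map()].
#' @param fallback Use element-generic parameters for unmapped atoms.
#' @return The atom tibble with columns `type`, `r_vdw`, `eps` added
#'   (`NA` for `HETATM` records, which take no part in the energy grid).
#' @export
assign_vdw_params <- function(atoms, param_table = vdw_param_table(),
                              name_map = atom_type_map(), fallback = TRUE) {
  is_protein <- atoms$record == "ATOM"
  lookup_res <- atoms$resname
  lookup_res[lookup_res %in% c("HID", "HIE", "HIP")] <- "HIS"
  lookup_res[lookup_res == "CYX"] <- "CYS"

  exact <- setNames(name_map$type, paste(name_map$resname, name_map$atom))
  type <- unname(exact[paste(lookup_res, atoms$name)])
  wild <- is.na(type)
  type[wild] <- unname(exact[paste("*", atoms$name[wild])])

  params <- setNames(seq_len(nrow(param_table)), param_table$type)
  pidx <- params[type]
  r_vdw <- param_table$r_vdw[pidx]
  eps <- param_table$eps[pidx]
  if (any(!is.na(type) & is.na(pidx)))
    abort(paste0("atom types missing from the parameter table: ",
                 paste(unique(type[!is.na(type) & is.na(pidx)]),
                       collapse = ", ")))

  unmapped <- is_protein & is.na(type)
  if (any(unmapped)) {
    labels <- unique(paste0(atoms$resname[unmapped], "/",
                            atoms$name[unmapped]))
    if (!fallback)
      abort(paste0("no force-field type for ", sum(unmapped), " atoms: ",
                   paste(head(labels, 20), collapse = ", ")))
    fb <- element_fallback_params()
    fi <- match(atoms$element[unmapped], fb$element)
    if (anyNA(fi))
      abort(paste0("no element-generic parameters for elements: ",
                   paste(unique(atoms$element[unmapped][is.na(fi)]),
                         collapse = ", ")))
    type[unmapped] <- fb$type[fi]
    r_vdw[unmapped] <- fb$r_vdw[fi]
    eps[unmapped] <- fb$eps[fi]
    warn(paste0("element-generic vdW parameters used for ", sum(unmapped),
                " unmapped atoms (", paste(head(labels, 10), collapse = ", "),
                if (length(labels) > 10) ", ..." else "", ")"))
  }

  atoms$type <- ifelse(is_protein, type, NA_character_)
  atoms$r_vdw <- ifelse(is_protein, r_vdw, NA_real_)
  atoms$eps <- ifelse(is_protein, eps, NA_real_)
  bad <- is_protein & (is.na(atoms$r_vdw) | atoms$r_vdw <= 0 | atoms$eps < 0)
  if (any(bad))
    abort("invalid vdW parameters assigned (radius must be > 0, depth >= 0)")
  atoms
}

#' Select biologically relevant ligands from HETATM records
#'
#' Non-water `HETATM` heavy atoms are merged into connected groups by
#' single linkage at `cluster_cutoff`; a group is kept when it has at least
#' `min_heavy` heavy atoms and makes at least `min_contacts` (ligand heavy
#' atom, protein atom) pairs within `contact_cutoff`.
#'
#' @param atoms Atom tibble from [read_structure()] containing both the
#'   protein and the `HETATM` records.
#' @param min_heavy Minimum heavy-atom count per group.
#' @param min_contacts Minimum number of interatomic contacts.
#' @param contact_cutoff Contact distance (boundary inclusive).
#' @param cluster_cutoff Single-linkage distance between heavy atoms.
#' @return A tibble with one row per accepted ligand group: `ligand` (id),
#'   `components` (list of HET codes), `n_heavy`, `n_contacts` and `atoms`
#'   (list-column of heavy-atom tibbles).  Empty tibble when nothing passes.
#' @export
select_ligands <- function(atoms, min_heavy = 10L, min_contacts = 70L,
                           contact_cutoff = 4.0, cluster_cutoff = 4.0) {
  het <- atoms |>
    filter(.data$record == "HETATM",
           !.data$resname %in% WATER_RESNAMES,
           !.data$is_hydrogen)
  empty <- tibble(ligand = integer(), components = list(),
                  n_heavy = integer(), n_contacts = integer(),
                  atoms = list())
  if (nrow(het) == 0) return(empty)

  grp <- single_linkage_groups(as_xyz(het), cluster_cutoff)
  prot <- atoms |> filter(.data$record == "ATOM")
  prot_xyz <- as_xyz(prot)

  out <- lapply(split(seq_len(nrow(het)), grp), function(idx) {
    g <- het[idx, , drop = FALSE]
    if (nrow(g) < min_heavy) return(NULL)
    nc <- count_contacts_cpp(as_xyz(g), prot_xyz, contact_cutoff)
    if (nc < min_contacts) return(NULL)
    tibble(components = list(sort(unique(g$resname))),
           n_heavy = nrow(g), n_contacts = as.integer(nc),
           atoms = list(g |> select("name", "resname", "chain", "resseq",
                                    "element", "x", "y", "z")))
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) return(empty)
  out |> mutate(ligand = row_number(), .before = 1)
}

# connected components of points under single linkage at `cutoff`
single_linkage_groups <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n == 1) return(1L)
  uf <- uf_new(n)
  d2 <- cross_dist2(xyz, xyz)
  cut2 <- cutoff^2
  pairs <- which(upper.tri(d2) & d2 <= cut2, arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) uf_union(uf, pairs[k, 1], pairs[k, 2])
  comp <- uf_components(uf)
  match(comp, unique(comp))
}

#' Residue-level view of an atom table
#'
#' @param atoms Atom tibble.
#' @param record Which records to keep (default protein `ATOM` rows).
#' @return One row per residue in file order: `res_index`, `chain`,
#'   `resseq`, `icode`, `resname`, `res_uid`.
#' @export
structure_residues <- function(atoms, record = "ATOM") {
  atoms[atoms$record %in% record, , drop = FALSE] |>
    distinct(.data$res_index, .data$chain, .data$resseq, .data$icode,
             .data$resname, .data$res_uid) |>
    arrange(.data$res_index)
}

#' One-letter sequence of a chain as observed in the structure
#'
#' @param atoms Atom tibble.
#' @param chain Chain identifier.
#' @return Tibble with `res_index`, `resseq`, `icode`, `resname`, `aa`
#'   (unknown residues become `X`).
#' @export
chain_sequence <- function(atoms, chain) {
  res <- structure_residues(atoms)
  res <- res[res$chain == chain, , drop = FALSE]
  if (nrow(res) == 0) abort(paste0("no protein residues on chain ", chain))
  res$aa <- unname(AA3[res$resname])
  res$aa[is.na(res$aa)] <- "X"
  res
}
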