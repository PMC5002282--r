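#' Built-in parameter tables
#'
#' `vdw_param_table()` returns the AMBER parm94 nonbonded parameters (van der
#' Waals radius `r_vdw` in Angstrom, well depth `eps` in kcal/mol per
#' force-field atom type).  `atom_type_map()` returns the atom-name to
#' force-field-type map covering backbone and side-chain heavy atoms of the
#' 20 standard residues (resname `*` rows apply to any residue).
#' `background_frequencies()` returns the background amino-acid distribution
#' used for conservation scoring: the Robinson-Robinson frequencies
#' associated with BLOSUM62, or a uniform distribution.
#'
#' All three are plain text assets under `inst/extdata/` and can be replaced
#' by user-supplied tables of the same shape.
#'
#' @param path Optional path to an alternative table in the same layout.
#' @return A tibble (`vdw_param_table`, `atom_type_map`) or a named numeric
#'   20-vector summing to 1 in PSSM column order (`background_frequencies`).
#' @export
vdw_param_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "parm94_vdw.tsv", package = "pocketcons")
  tb <- read_tsv_plain(path)
  stopifnot(all(c("type", "r_vdw", "eps") %in% names(tb)))
  as_tibble(tb)
}

#' @rdname vdw_param_table
#' @export
atom_type_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "atom_type_map.tsv", package = "pocketcons")
  tb <- read_tsv_plain(path)
  stopifnot(all(c("resname", "atom", "type") %in% names(tb)))
  as_tibble(tb)
}

#' @rdname vdw_param_table
#' @param kind `"blosum62"` (Robinson-Robinson background) or `"uniform"`.
#' @export
background_frequencies <- function(kind = c("blosum62", "uniform"),
                                   path = NULL) {
  kind <- match.arg(kind)
  if (kind == "uniform" && is.null(path))
    return(setNames(rep(1 / 20, 20), AA20))
  if (is.null(path))
    path <- system.file("extdata", "background_blosum62.tsv",
                        package = "pocketcons")
  tb <- read_tsv_plain(path)
  q <- setNames(tb$freq, tb$aa)[AA20]
  if (anyNA(q)) abort("background table must cover the 20 standard amino acids")
  q / sum(q)
}

# strict TSV reader: never treats the string "NA" (an AMBER atom type) as
# missing
read_tsv_plain <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read table: ", path))
  read.delim(path, sep = "\t", header = TRUE, na.strings = NULL,
             stringsAsFactors = FALSE, check.names = FALSE)
}

# element-generic fallback parameters used when an atom name has no
# force-field type mapping (parm94 values of the closest generic type)
element_fallback_params <- function() {
  tibble(
    element = c("C", "N", "O", "S", "H", "P", "SE"),
    type = c("C-generic", "N-generic", "O-generic", "S-generic",
             "H-generic", "P-generic", "S-generic"),
    r_vdw = c(1.9080, 1.8240, 1.6612, 2.0000, 1.4870, 2.1000, 2.0000),
    eps = c(0.1094, 0.1700, 0.2100, 0.2500, 0.0157, 0.2000, 0.2500)
  )
}
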