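#' Binding-space precision of predicted clusters
#'
#' A member probe overlaps the ligand when it lies within `overlap_radius`
#' (boundary inclusive) of any ligand heavy atom.  The precision of a
#' cluster is the percentage of its member probes that overlap; a cluster
#' with precision at or above `threshold` counts as a success.
#'
#' @param probes Clustered probe tibble (column `cluster`), or any probe
#'   tibble: rows with `cluster` `NA` are ignored; without a `cluster`
#'   column all rows form one cluster.
#' @param ligand_atoms Tibble of ligand heavy-atom positions (`x`, `y`,
#'   `z`), e.g. one element of the `atoms` list-column of
#'   [select_ligands()], or all of them bound together.
#' @param overlap_radius Overlap distance in Angstrom.
#' @param threshold Success threshold in percent.
#' @return Tibble with one row per cluster: `cluster`, `n_probes`,
#'   `n_overlap`, `precision` (percent), `success`.
#' @export
space_precision <- function(probes, ligand_atoms, overlap_radius = 1.6,
                            threshold = 25) {
  if (!("cluster" %in% names(probes))) probes$cluster <- 1L
  members <- probes |> filter(!is.na(.data$cluster))
  if (nrow(members) == 0 || nrow(ligand_atoms) == 0)
    return(tibble(cluster = integer(), n_probes = integer(),
                  n_overlap = integer(), precision = numeric(),
                  success = logical()))
  members$overlap <- near_points_cpp(as_xyz(ligand_atoms), as_xyz(members),
                                     overlap_radius)
  members |>
    group_by(.data$cluster) |>
    summarise(n_probes = n(), n_overlap = sum(.data$overlap),
              .groups = "drop") |>
    mutate(precision = 100 * .data$n_overlap / .data$n_probes,
           success = .data$precision >= threshold)
}

#' True ligand-binding residues
#'
#' Residues with any atom within `radius` (boundary inclusive) of any
#' ligand heavy atom, unioned over all ligands.
#'
#' @param atoms Atom tibble of the structure.
#' @param ligands Ligand tibble from [select_ligands()] (its `atoms`
#'   list-column is used), or a plain tibble of heavy-atom positions.
#' @param radius Distance defining a binding residue (4 Angstrom default).
#' @return Residue tibble (`chain`, `resseq`, `icode`, `resname`,
#'   `res_index`, `res_uid`).
#' @export
true_binding_residues <- function(atoms, ligands, radius = 4) {
  lig_xyz <- ligand_positions(ligands)
  if (nrow(lig_xyz) == 0) abort("no ligand atoms: cannot define ground truth")
  contact_residues(lig_xyz, atoms, radius = radius)
}

ligand_positions <- function(ligands) {
  if (is.null(ligands)) return(tibble(x = numeric(), y = numeric(),
                                      z = numeric()))
  if ("atoms" %in% names(ligands) && is.list(ligands$atoms))
    ligands <- bind_rows(ligands$atoms)
  ligands |> select("x", "y", "z")
}

#' Confusion-table metrics for binding-residue prediction
#'
#' Standard counts over a residue universe, the residue-level precision
#' `S_residue = 100 * TP / (TP + FP)` (0 when nothing is predicted) and the
#' Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, set to 0
#' when any factor of the denominator vanishes.
#'
#' @param predicted,truth,universe Residue identifiers: character vectors,
#'   or tibbles with a `res_uid` column.  `predicted` and `truth` must be
#'   subsets of `universe`.
#' @return One-row tibble: `tp`, `fp`, `fn`, `tn`, `s_residue`, `mcc`.
#' @export
residue_metrics <- function(predicted, truth, universe) {
  as_ids <- function(x) {
    if (is.data.frame(x)) unique(x$res_uid) else unique(as.character(x))
  }
  p <- as_ids(predicted); t_ <- as_ids(truth); u <- as_ids(universe)
  if (!all(p %in% u)) abort("predicted residues outside the universe")
  if (!all(t_ %in% u)) abort("truth residues outside the universe")
  tp <- length(intersect(p, t_))
  fp <- length(setdiff(p, t_))
  fn <- length(setdiff(t_, p))
  tn <- length(u) - tp - fp - fn
  s_residue <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0)
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom) else 0
  tibble(tp = tp, fp = fp, fn = fn, tn = tn, s_residue = s_residue,
         mcc = mcc)
}

#' Top-k success over ranked sites
#'
#' `TRUE` when any of the k best-ranked representative sites meets the
#' criterion (metric at or above `threshold`).
#'
#' @param evals Per-site tibble carrying a `rank` column and the metric
#'   column.
#' @param k Number of top ranks considered.
#' @param threshold Success threshold (percent).
#' @param metric Name of the metric column (`"precision"` or
#'   `"s_residue"`).
#' @return Logical scalar.
#' @export
topk_success <- function(evals, k = 3, threshold = 25,
                         metric = "precision") {
  if (k < 1) abort("k must be >= 1")
  if (!metric %in% names(evals))
    abort(paste0("no `", metric, "` column in the evaluation table"))
  sel <- !is.na(evals$rank) & evals$rank <= k
  any(evals[[metric]][sel] >= threshold, na.rm = TRUE)
}

#' Aggregate top-k success over a structure set
#'
#' @param flags Logical vector of per-structure success flags.
#' @param precisions Optional per-structure best precisions, averaged over
#'   successes and over all structures separately.
#' @return One-row tibble: `n`, `n_success`, `ratio` (percent) and, when
#'   precisions are supplied, `mean_precision_successes`,
#'   `mean_precision_all`.
#' @export
aggregate_success <- function(flags, precisions = NULL) {
  out <- tibble(n = length(flags), n_success = sum(flags),
                ratio = 100 * mean(flags))
  if (!is.null(precisions)) {
    out$mean_precision_successes <-
      if (any(flags)) mean(precisions[flags]) else NA_real_
    out$mean_precision_all <- mean(precisions)
  }
  out
}
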