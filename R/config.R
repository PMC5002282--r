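#' Pipeline configuration
#'
#' Bundles every tunable of the prediction pipeline with its default.
#' Lengths are in Angstrom, energies in kcal/mol.  Defaults follow the
#' published protocol: 0.5 A probe grid, 10 A energy cutoff, 0.1 kcal/mol
#' clustering threshold step, 1 A linkage radius, cluster size cap
#' `p_num = 500`, score weights `(w1, w2, w3) = (1, -0.05, 9)`, 6 A
#' conservation gate, 1.6 A ligand-overlap radius with a 25 % precision
#' success threshold, and the 5 A cluster-to-residue rule.
#'
#' @param spacing Grid spacing between probe positions.
#' @param margin Extension of the grid beyond the protein bounding box.
#' @param energy_cutoff Atom-probe distance cutoff for the energy sum.
#' @param conservation_cutoff Probe-residue distance gate for conservation
#'   terms of the weighted score.
#' @param p_num Maximum cluster size; reaching it stops clustering.
#' @param threshold_step Energy-threshold increment during clustering.
#' @param linkage_radius Probe-probe linkage distance during clustering.
#' @param prune_energy Probes with raw energy above this are discarded
#'   before clustering (0 keeps only non-repulsive positions).
#' @param weights Named vector `c(w1, w2, w3)` of score weights.
#' @param top_k Number of top-ranked sites considered in evaluation.
#' @param precision_threshold,sresidue_threshold Success thresholds (%).
#' @param dedup Collapse symmetric multimer sites to one representative.
#' @param dedup_jaccard Minimum Jaccard overlap of chain-stripped contact
#'   residue sets for two sites to be considered symmetric copies.
#' @param dedup_score_tol Maximum relative weighted-score difference for
#'   symmetric copies.
#' @param contact_radius Cluster-to-residue distance for predicted residues.
#' @param truth_radius Ligand-to-residue distance defining true binding
#'   residues.
#' @param overlap_radius Probe-to-ligand distance defining spatial overlap.
#' @param ignore_hydrogens Drop hydrogen atoms before energy calculation.
#' @param strict_conservation Error (instead of warn and use 0) when a
#'   contacting chain has no conservation profile.
#' @param gate_cross_term Apply the 6 A conservation gate to the energy x
#'   conservation cross term as well as to the bare conservation term.
#' @param probe_radius,probe_depth van der Waals parameters of the carbon
#'   probe (parm94 aliphatic sp3 carbon CT by default).
#' @param require_negative_start Clustering returns no clusters unless the
#'   lowest probe energy is negative.
#' @param seed Integer seed recorded with the run.
#' @return A `site_config` object (a validated named list).
#' @export
site_config <- function(spacing = 0.5,
                        margin = 8,
                        energy_cutoff = 10,
                        conservation_cutoff = 6,
                        p_num = 500L,
                        threshold_step = 0.1,
                        linkage_radius = 1,
                        prune_energy = 0,
                        weights = c(w1 = 1, w2 = -0.05, w3 = 9),
                        top_k = 3L,
                        precision_threshold = 25,
                        sresidue_threshold = 25,
                        dedup = TRUE,
                        dedup_jaccard = 0.7,
                        dedup_score_tol = 0.1,
                        contact_radius = 5,
                        truth_radius = 4,
                        overlap_radius = 1.6,
                        ignore_hydrogens = FALSE,
                        strict_conservation = FALSE,
                        gate_cross_term = TRUE,
                        probe_radius = 1.9080,
                        probe_depth = 0.1094,
                        require_negative_start = TRUE,
                        seed = 1L) {
  weights <- unlist(weights)
  if (is.null(names(weights)) || !all(c("w1", "w2", "w3") %in% names(weights)))
    names(weights) <- c("w1", "w2", "w3")
  cfg <- list(spacing = spacing, margin = margin,
              energy_cutoff = energy_cutoff,
              conservation_cutoff = conservation_cutoff,
              p_num = as.integer(p_num), threshold_step = threshold_step,
              linkage_radius = linkage_radius, prune_energy = prune_energy,
              weights = weights[c("w1", "w2", "w3")],
              top_k = as.integer(top_k),
              precision_threshold = precision_threshold,
              sresidue_threshold = sresidue_threshold,
              dedup = isTRUE(dedup), dedup_jaccard = dedup_jaccard,
              dedup_score_tol = dedup_score_tol,
              contact_radius = contact_radius, truth_radius = truth_radius,
              overlap_radius = overlap_radius,
              ignore_hydrogens = isTRUE(ignore_hydrogens),
              strict_conservation = isTRUE(strict_conservation),
              gate_cross_term = isTRUE(gate_cross_term),
              probe_radius = probe_radius, probe_depth = probe_depth,
              require_negative_start = isTRUE(require_negative_start),
              seed = as.integer(seed))
  validate_site_config(cfg)
  structure(cfg, class = "site_config")
}

validate_site_config <- function(cfg) {
  pos <- c("spacing", "energy_cutoff", "conservation_cutoff", "p_num",
           "threshold_step", "linkage_radius", "contact_radius",
           "truth_radius", "overlap_radius", "probe_radius")
  for (nm in pos)
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0)
      abort(paste0("config field `", nm, "` must be a positive scalar"))
  if (cfg$margin < 0) abort("config field `margin` must be non-negative")
  if (cfg$probe_depth < 0) abort("config field `probe_depth` must be >= 0")
  if (!all(is.finite(cfg$weights))) abort("weights must be finite")
  if (cfg$top_k < 1) abort("config field `top_k` must be >= 1")
  invisible(cfg)
}

#' @export
print.site_config <- function(x, ...) {
  cat("<site_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-22s %s\n", nm, paste(format(v), collapse = " ")))
  }
  invisible(x)
}

#' Read / write a pipeline configuration
#'
#' Configurations serialize to YAML so a run can be reproduced from its
#' logged configuration alone.
#'
#' @param cfg A [site_config()] object.
#' @param path File path.
#' @return `write_site_config` returns `path` invisibly; `read_site_config`
#'   returns a `site_config`.
#' @export
write_site_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "site_config"))
  out <- unclass(cfg)
  out$weights <- as.list(out$weights)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_site_config
#' @export
read_site_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$weights <- unlist(raw$weights)
  do.call(site_config, raw)
}
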