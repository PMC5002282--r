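#' Predict ligand-binding sites for a structure
#'
#' Full pipeline: parse the structure (unless an already-parsed atom tibble
#' is supplied), assign parm94 van der Waals parameters, place carbon
#' probes on a regular grid, compute probe energies, prune repulsive
#' probes, grow clusters with the incremental energy-threshold procedure,
#' score probes with the conservation-weighted score and rank the clusters.
#' Without conservation input the pipeline runs in energy-only mode
#' (`w2 = w3 = 0`).
#'
#' @param structure Path to a PDB file, or an atom tibble from
#'   [read_structure()].
#' @param conservation `NULL` for energy-only mode, a conservation tibble
#'   from [conservation_profiles()], or a named list/vector of per-chain
#'   profile inputs (PSSM/MSA paths or profile tibbles).
#' @param config A [site_config()].
#' @return A `site_prediction` object: list with `sites` (ranked tibble),
#'   `probes` (cluster members with energies and scores), `atoms`,
#'   `conservation`, `grid`, `config`, `n_grid_probes`, `final_threshold`.
#' @export
predict_binding_sites <- function(structure, conservation = NULL,
                                  config = site_config()) {
  stopifnot(inherits(config, "site_config"))
  atoms <- if (is.character(structure)) read_structure(structure) else
    structure
  if (!("r_vdw" %in% names(atoms)))
    atoms <- assign_vdw_params(atoms)

  if (is.null(conservation)) {
    config$weights[c("w2", "w3")] <- 0
  } else if (!is.data.frame(conservation)) {
    conservation <- conservation_profiles(atoms, conservation)
  }

  grid <- build_grid(atoms, spacing = config$spacing, margin = config$margin)
  probes <- grid_probes(grid)
  n_grid <- nrow(probes)
  probes <- compute_probe_energies(probes, atoms,
                                   cutoff = config$energy_cutoff,
                                   probe_radius = config$probe_radius,
                                   probe_depth = config$probe_depth,
                                   ignore_hydrogens = config$ignore_hydrogens)
  probes <- prune_probes(probes, e_max = config$prune_energy)
  probes <- cluster_probes(probes, p_num = config$p_num,
                           threshold_step = config$threshold_step,
                           linkage_radius = config$linkage_radius,
                           require_negative_start =
                             config$require_negative_start)
  members <- probes |> filter(!is.na(.data$cluster))
  members <- probe_score_components(members, atoms, conservation,
                                    energy_cutoff = config$energy_cutoff,
                                    conservation_cutoff =
                                      config$conservation_cutoff,
                                    gate_cross_term = config$gate_cross_term,
                                    probe_radius = config$probe_radius,
                                    probe_depth = config$probe_depth,
                                    ignore_hydrogens = config$ignore_hydrogens,
                                    strict = config$strict_conservation)
  members <- weighted_probe_score(members, weights = config$weights)
  sites <- rank_clusters(members, atoms, dedup = config$dedup,
                         contact_radius = config$contact_radius,
                         jaccard_min = config$dedup_jaccard,
                         score_tol = config$dedup_score_tol)
  structure(list(sites = sites, probes = members, atoms = atoms,
                 conservation = conservation, grid = grid, config = config,
                 n_grid_probes = n_grid,
                 final_threshold = attr(probes, "final_threshold")),
            class = "site_prediction")
}

#' @export
print.site_prediction <- function(x, ...) {
  cat(sprintf("<site_prediction> %d ranked sites (%d clusters) from %d grid probes\n",
              sum(x$sites$representative), nrow(x$sites), x$n_grid_probes))
  top <- x$sites |> filter(.data$representative) |> head(5) |>
    select("rank", "cluster", "n_probes", "e_vdw_total", "e_weighted_total",
           "chain")
  print(as.data.frame(top), row.names = FALSE)
  invisible(x)
}

#' @describeIn predict_binding_sites Ranked-site table of a prediction
#'   (one row per site, list-column of contact residues).
#' @param x A `site_prediction`.
#' @param ... Unused.
#' @export
tidy.site_prediction <- function(x, ...) {
  x$sites
}

#' @describeIn predict_binding_sites One-row summary of a prediction.
#' @export
glance.site_prediction <- function(x, ...) {
  rep1 <- x$sites |> filter(.data$rank == 1)
  tibble(n_sites = sum(x$sites$representative),
         n_clusters = nrow(x$sites),
         n_grid_probes = x$n_grid_probes,
         n_clustered_probes = nrow(x$probes),
         final_threshold = x$final_threshold,
         best_score = if (nrow(rep1)) rep1$e_weighted_total else NA_real_,
         best_size = if (nrow(rep1)) rep1$n_probes else NA_integer_)
}

#' @describeIn predict_binding_sites Ranked-site score profile as a ggplot.
#' @param object A `site_prediction`.
#' @param top_n Number of top-ranked sites to display.
#' @export
autoplot.site_prediction <- function(object, top_n = 10, ...) {
  df <- object$sites |> filter(.data$representative) |> head(top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$rank),
                                   y = .data$e_weighted_total)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$e_vdw_total),
                        colour = "black", shape = 1) +
    ggplot2::labs(x = "site rank", y = "total score (kcal/mol scale)",
                  title = "Ranked candidate binding sites",
                  subtitle = "bars: weighted score; circles: raw vdW energy") +
    ggplot2::theme_minimal()
}

#' Evaluate a prediction against ligands or a truth residue set
#'
#' Applies both assessment protocols to the representative sites of a
#' prediction: binding-space precision against the ligand heavy atoms
#' (bound mode) and binding-residue S_residue / MCC against the true
#' binding residues (the 4 Angstrom rule, or a supplied truth table for
#' unbound structures).
#'
#' @param prediction A `site_prediction`.
#' @param ligands [select_ligands()] result (or tibble of ligand heavy-atom
#'   positions); omit in unbound mode.
#' @param truth Residue tibble (or vector of `res_uid`s) of true binding
#'   residues; computed from `ligands` when omitted.
#' @param config A [site_config()]; evaluation thresholds and radii are
#'   taken from here.
#' @return A `site_evaluation` object: list with `sites` (per-site tibble:
#'   rank, precision, S_residue, MCC, confusion counts) and `summary`
#'   (one-row tibble with Top-1/Top-k success flags).
#' @export
evaluate_prediction <- function(prediction, ligands = NULL, truth = NULL,
                                config = prediction$config) {
  stopifnot(inherits(prediction, "site_prediction"))
  sites <- prediction$sites |> filter(.data$representative)
  atoms <- prediction$atoms
  universe <- structure_residues(atoms)$res_uid

  if (is.null(truth)) {
    if (is.null(ligands))
      abort("supply `ligands` or a `truth` residue set")
    truth <- true_binding_residues(atoms, ligands,
                                   radius = config$truth_radius)
  }
  truth_ids <- if (is.data.frame(truth)) truth$res_uid else
    as.character(truth)

  per_site <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    metrics <- residue_metrics(sites$contact_residues[[i]]$res_uid,
                               truth_ids, universe)
    metrics$cluster <- sites$cluster[i]
    metrics$rank <- sites$rank[i]
    metrics
  })

  if (!is.null(ligands)) {
    lig_xyz <- ligand_positions(ligands)
    prec <- space_precision(prediction$probes, lig_xyz,
                            overlap_radius = config$overlap_radius,
                            threshold = config$precision_threshold)
    per_site <- per_site |>
      left_join(prec |> select("cluster", "precision"), by = "cluster")
  } else {
    per_site$precision <- NA_real_
  }
  per_site <- per_site |>
    select("rank", "cluster", "precision", "s_residue", "mcc", "tp", "fp",
           "fn", "tn") |>
    arrange(.data$rank)

  summary <- tibble(
    top1_space = !is.null(ligands) &&
      topk_success(per_site, 1, config$precision_threshold, "precision"),
    topk_space = !is.null(ligands) &&
      topk_success(per_site, config$top_k, config$precision_threshold,
                   "precision"),
    top1_residue = topk_success(per_site, 1, config$sresidue_threshold,
                                "s_residue"),
    topk_residue = topk_success(per_site, config$top_k,
                                config$sresidue_threshold, "s_residue"),
    k = config$top_k)
  structure(list(sites = per_site, summary = summary, config = config),
            class = "site_evaluation")
}

#' @export
print.site_evaluation <- function(x, ...) {
  cat("<site_evaluation>\n")
  print(as.data.frame(head(x$sites, 5)), row.names = FALSE)
  cat(sprintf("Top-1 space %s | Top-%d space %s | Top-1 residue %s | Top-%d residue %s\n",
              x$summary$top1_space, x$summary$k, x$summary$topk_space,
              x$summary$top1_residue, x$summary$k, x$summary$topk_residue))
  invisible(x)
}

#' @describeIn evaluate_prediction Per-site evaluation table.
#' @param x A `site_evaluation`.
#' @param ... Unused.
#' @export
tidy.site_evaluation <- function(x, ...) {
  x$sites
}

#' @describeIn evaluate_prediction One-row success summary.
#' @export
glance.site_evaluation <- function(x, ...) {
  x$summary
}

#' @describeIn evaluate_prediction Precision/S_residue by rank as a ggplot.
#' @param object A `site_evaluation`.
#' @param top_n Number of top-ranked sites to display.
#' @export
autoplot.site_evaluation <- function(object, top_n = 10, ...) {
  df <- object$sites |> head(top_n) |>
    tidyr::pivot_longer(c("precision", "s_residue"), names_to = "metric",
                        values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$rank), y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = object$config$precision_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "site rank", y = "percent",
                  title = "Per-site evaluation") +
    ggplot2::theme_minimal()
}

#' Success-rate grid over conservation weights
#'
#' Re-ranks precomputed predictions under every combination of `w2` and
#' `w3` (with `w1` fixed) and records the Top-k success rate over the
#' supplied structures.  Because the weighted probe score is linear in the
#' weights, the per-probe components are computed once per structure.
#'
#' @param runs List of prepared structures: each element a list with
#'   `prediction` (a `site_prediction`) and `ligands` (its ligand set).
#' @param w2,w3 Numeric vectors spanning the grid.
#' @param w1 Scalar weight on the energy term (0 or 1 in the published
#'   protocol).
#' @param k Top-k criterion.
#' @param metric `"precision"` or `"s_residue"`.
#' @param threshold Success threshold (percent).
#' @return Tibble: `w1`, `w2`, `w3`, `success_rate` (percent), `n_success`,
#'   `n`, `n_rank1_ties` (structures whose rank-1 score is tied).
#' @export
run_weight_grid <- function(runs, w2, w3, w1 = 1, k = 3,
                            metric = "precision", threshold = 25) {
  if (length(w2) == 0 || length(w3) == 0) abort("empty weight ranges")
  if (length(runs) == 0) abort("no structures supplied")
  grid <- expand.grid(w2 = w2, w3 = w3, KEEP.OUT.ATTRS = FALSE)
  purrr::map_dfr(seq_len(nrow(grid)), function(g) {
    weights <- c(w1 = w1, w2 = grid$w2[g], w3 = grid$w3[g])
    res <- purrr::map(runs, function(run) {
      pred <- run$prediction
      pred$probes <- weighted_probe_score(pred$probes, weights = weights)
      pred$sites <- rank_clusters(pred$probes, pred$atoms,
                                  dedup = pred$config$dedup,
                                  contact_radius = pred$config$contact_radius,
                                  jaccard_min = pred$config$dedup_jaccard,
                                  score_tol = pred$config$dedup_score_tol)
      ev <- evaluate_prediction(pred, ligands = run$ligands)
      top2 <- pred$sites |> filter(.data$representative) |> head(2)
      tie <- nrow(top2) == 2 &&
        isTRUE(all.equal(top2$e_weighted_total[1], top2$e_weighted_total[2]))
      list(success = topk_success(ev$sites, k, threshold, metric),
           tie = tie)
    })
    tibble(w1 = w1, w2 = grid$w2[g], w3 = grid$w3[g],
           success_rate = 100 * mean(purrr::map_lgl(res, "success")),
           n_success = sum(purrr::map_lgl(res, "success")),
           n = length(res),
           n_rank1_ties = sum(purrr::map_lgl(res, "tie")))
  })
}
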