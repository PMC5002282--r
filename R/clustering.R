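#' Cluster low-energy probes into candidate binding sites
#'
#' Incremental energy-threshold clustering.  The threshold starts at the
#' lowest probe energy and is raised in steps of `threshold_step`; probes at
#' or below the threshold become active (one at a time, in ascending-energy
#' order with ties broken lexicographically on position) and join every
#' existing cluster that has a member within `linkage_radius` (boundary
#' inclusive); a probe bridging several clusters merges them.  The distance
#' between clusters is the distance between their two nearest member
#' probes.  The procedure stops the moment a cluster reaches `p_num`
#' members, or once every probe is active; all clusters existing at that
#' instant are returned.
#'
#' @param probes Probe tibble with `x`, `y`, `z`, `e_vdw`.
#' @param p_num Cluster size cap stopping the procedure.
#' @param threshold_step Energy-threshold increment (kcal/mol).
#' @param linkage_radius Probe-probe linkage distance (Angstrom).
#' @param require_negative_start Return no clusters when the lowest probe
#'   energy is non-negative.
#' @return `probes` with an integer `cluster` column (`NA` for probes not
#'   active at termination).  Cluster ids are ordered by ascending total raw
#'   energy (ties: lexicographically smallest member position).  Attributes
#'   `capped_cluster` (id of the cluster that reached `p_num`, or `NA`) and
#'   `final_threshold` record the stop state.
#' @export
cluster_probes <- function(probes, p_num = 500L, threshold_step = 0.1,
                           linkage_radius = 1, require_negative_start = TRUE) {
  check_cluster_params(p_num, threshold_step, linkage_radius)
  probes$cluster <- NA_integer_
  if (nrow(probes) == 0) {
    attr(probes, "capped_cluster") <- NA_integer_
    attr(probes, "final_threshold") <- NA_real_
    return(probes)
  }
  ord <- probe_processing_order(probes)
  res <- cluster_probes_cpp(as_xyz(probes[ord, ]), probes$e_vdw[ord],
                            linkage_radius, threshold_step, as.integer(p_num),
                            require_negative_start)
  comp <- integer(nrow(probes))
  comp[ord] <- res$comp
  finish_clusters(probes, comp, res$capped, res$threshold)
}

check_cluster_params <- function(p_num, threshold_step, linkage_radius) {
  if (p_num < 1) abort("p_num must be >= 1")
  if (threshold_step <= 0) abort("threshold_step must be > 0")
  if (linkage_radius <= 0) abort("linkage_radius must be > 0")
}

probe_processing_order <- function(probes) {
  order(probes$e_vdw, probes$x, probes$y, probes$z)
}

# renumber components by ascending total raw energy (tie: smallest member
# position, lexicographic) and attach bookkeeping attributes
finish_clusters <- function(probes, comp, capped, threshold) {
  active <- comp > 0
  if (!any(active)) {
    probes$cluster <- NA_integer_
    attr(probes, "capped_cluster") <- NA_integer_
    attr(probes, "final_threshold") <- threshold
    return(probes)
  }
  totals <- tibble(comp = comp[active], e = probes$e_vdw[active],
                   x = probes$x[active], y = probes$y[active],
                   z = probes$z[active]) |>
    group_by(.data$comp) |>
    summarise(total = sum(.data$e),
              kx = min(.data$x),
              ky = min(.data$y[.data$x == min(.data$x)]),
              kz = min(.data$z[.data$x == min(.data$x) &
                                 .data$y == min(.data$y[.data$x == min(.data$x)])]),
              .groups = "drop") |>
    arrange(.data$total, .data$kx, .data$ky, .data$kz)
  relabel <- setNames(seq_len(nrow(totals)), totals$comp)
  probes$cluster <- ifelse(active, relabel[as.character(comp)], NA_integer_)
  attr(probes, "capped_cluster") <-
    if (capped > 0) unname(relabel[as.character(capped)]) else NA_integer_
  attr(probes, "final_threshold") <- threshold
  probes
}

#' Literal reference implementation of the threshold clustering
#'
#' Direct transcription of the clustering procedure as a threshold loop over
#' explicit cluster sets, without any spatial index: at each threshold the
#' newly eligible probes are taken in processing order; each joins (and
#' merges) every cluster whose nearest member lies within `linkage_radius`,
#' or starts a new cluster.  Quadratic cost; intended as the independent
#' oracle for [cluster_probes()] on small inputs.
#'
#' @inheritParams cluster_probes
#' @return Same shape and attributes as [cluster_probes()].
#' @export
brute_force_cluster_oracle <- function(probes, p_num = 500L,
                                       threshold_step = 0.1,
                                       linkage_radius = 1,
                                       require_negative_start = TRUE) {
  check_cluster_params(p_num, threshold_step, linkage_radius)
  n <- nrow(probes)
  probes$cluster <- NA_integer_
  if (n == 0) {
    attr(probes, "capped_cluster") <- NA_integer_
    attr(probes, "final_threshold") <- NA_real_
    return(probes)
  }
  ord <- probe_processing_order(probes)
  e <- probes$e_vdw[ord]
  xyz <- as_xyz(probes[ord, ])
  if (require_negative_start && e[1] >= 0)
    return(finish_clusters(probes, integer(n), 0L, NA_real_))

  clusters <- list()  # each element: integer vector of sorted-probe indices
  e0 <- e[1]
  i <- 1L
  k <- 0L
  capped <- 0L
  T <- e0
  repeat {
    while (i <= n && e[i] <= T) {
      # clusters whose nearest member is within the linkage radius
      hits <- which(vapply(clusters, function(cl) {
        d2 <- (xyz[cl, 1] - xyz[i, 1])^2 + (xyz[cl, 2] - xyz[i, 2])^2 +
          (xyz[cl, 3] - xyz[i, 3])^2
        any(d2 <= linkage_radius^2)
      }, logical(1)))
      if (length(hits) == 0) {
        clusters[[length(clusters) + 1L]] <- i
        target <- length(clusters)
      } else {
        target <- hits[1]
        merged <- c(unlist(clusters[hits]), i)
        clusters[[target]] <- merged
        if (length(hits) > 1) clusters[hits[-1]] <- NULL
        target <- which(vapply(clusters, function(cl) i %in% cl, logical(1)))
      }
      i <- i + 1L
      if (length(clusters[[target]]) >= p_num) {
        capped <- target
        break
      }
    }
    if (capped > 0L || i > n) break
    # raise the threshold just far enough to admit the next probe (idle
    # increments admit nothing; skipping them leaves the procedure unchanged)
    kn <- ceiling((e[i] - e0) / threshold_step - 1e-12)
    k <- if (kn > k) kn else k + 1
    T <- e0 + k * threshold_step
  }

  comp_sorted <- integer(n)
  for (ci in seq_along(clusters)) comp_sorted[clusters[[ci]]] <- ci
  comp <- integer(n)
  comp[ord] <- comp_sorted
  capped_lab <- if (capped > 0L) capped else 0L
  finish_clusters(probes, comp, capped_lab, T)
}

#' Summarise clusters
#'
#' @param probes Clustered probe tibble from [cluster_probes()]; if an
#'   `e_weighted` column is present its per-cluster total is included.
#' @return One row per cluster: `cluster`, `n_probes`, `e_vdw_total`,
#'   optionally `e_weighted_total`, and centroid `cx`, `cy`, `cz`.
#' @export
cluster_summary <- function(probes) {
  members <- probes |> filter(!is.na(.data$cluster))
  out <- members |>
    group_by(.data$cluster) |>
    summarise(n_probes = n(),
              e_vdw_total = sum(.data$e_vdw),
              e_weighted_total = if ("e_weighted" %in% names(members))
                sum(.data$e_weighted) else NA_real_,
              cx = mean(.data$x), cy = mean(.data$y), cz = mean(.data$z),
              .groups = "drop") |>
    arrange(.data$cluster)
  out
}

#' Dump clusters as a multi-MODEL PDB and a TSV summary
#'
#' One `MODEL` per cluster (in rank order when `sites` is given), probes as
#' carbon pseudo-atoms with the probe energy in the B-factor column.
#'
#' @param probes Clustered probe tibble.
#' @param path Output PDB path; the TSV summary goes to `paste0(path, ".tsv")`.
#' @param sites Optional ranked-site tibble from [rank_clusters()] to order
#'   and subset the dumped clusters.
#' @return `path`, invisibly.
#' @export
write_clusters_pdb <- function(probes, path, sites = NULL) {
  members <- probes |> filter(!is.na(.data$cluster))
  ids <- if (!is.null(sites)) sites$cluster else
    sort(unique(members$cluster))
  lines <- character(0)
  for (m in seq_along(ids)) {
    g <- members |> filter(.data$cluster == ids[m])
    at <- tibble(record = "HETATM", serial = seq_len(nrow(g)), name = "C",
                 altloc = "", resname = "CLU", chain = "X",
                 resseq = m, icode = "", x = g$x, y = g$y, z = g$z,
                 occupancy = 1, bfactor = pmax(pmin(g$e_vdw, 999), -999),
                 element = "C")
    lines <- c(lines, sprintf("MODEL %8d", m), pdb_atom_lines(at), "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  summ <- cluster_summary(probes) |> filter(.data$cluster %in% ids)
  utils::write.table(summ, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
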