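#' Per-probe components of the weighted score
#'
#' For each probe, sums over protein atoms `j` within `energy_cutoff`:
#' the raw pair energy (`e_sum`), the conservation score of atom `j`'s
#' residue (`c_sum`) and their product (`ec_sum`).  The weighted probe score
#' is the linear combination `w1 * e_sum + w2 * c_sum + w3 * ec_sum`.
#' A residue's conservation enters only when that residue has at least one
#' atom within `conservation_cutoff` of the probe (otherwise its score
#' counts as 0); the score applies to all atoms of the residue.  By default
#' the distance gate applies to both conservation-containing terms; with
#' `gate_cross_term = FALSE` the cross term uses conservation over the full
#' energy cutoff.
#'
#' @param probes Probe tibble with `x`, `y`, `z`.
#' @param atoms Parameterized atom tibble ([assign_vdw_params()]).
#' @param conservation Conservation tibble ([conservation_profiles()]), or
#'   `NULL` for energy-only scoring (all conservation scores 0).
#' @param energy_cutoff,conservation_cutoff Distance cutoffs in Angstrom.
#' @param gate_cross_term Apply the conservation gate to the cross term.
#' @param probe_radius,probe_depth Probe vdW parameters.
#' @param ignore_hydrogens Drop hydrogens from the sums.
#' @param strict Error when a chain contacted by the protein has no
#'   conservation profile (default: warn once and use 0).
#' @return `probes` with `e_sum`, `c_sum`, `ec_sum` columns added.
#' @export
probe_score_components <- function(probes, atoms, conservation = NULL,
                                   energy_cutoff = 10,
                                   conservation_cutoff = 6,
                                   gate_cross_term = TRUE,
                                   probe_radius = 1.9080,
                                   probe_depth = 0.1094,
                                   ignore_hydrogens = FALSE,
                                   strict = FALSE) {
  prot <- protein_energy_atoms(atoms, ignore_hydrogens)
  nres <- max(atoms$res_index)
  cvec <- rep(0, nres)
  if (!is.null(conservation) && nrow(conservation) > 0) {
    cvec[conservation$res_index] <- conservation$c_score
    missing_chains <- setdiff(unique(prot$chain), unique(conservation$chain))
    if (length(missing_chains) > 0) {
      msg <- paste0("no conservation profile for chain(s) ",
                    paste(missing_chains, collapse = ", "))
      if (strict) abort(msg) else warn(paste0(msg, "; using C_score = 0"))
    }
  }
  comp <- score_components_cpp(as_xyz(probes), as_xyz(prot), prot$r_vdw,
                               prot$eps, as.integer(prot$res_index), cvec,
                               probe_radius, probe_depth, energy_cutoff,
                               conservation_cutoff, gate_cross_term)
  probes$e_sum <- comp[, 1]
  probes$c_sum <- comp[, 2]
  probes$ec_sum <- comp[, 3]
  probes
}

#' Weighted probe score
#'
#' Applies score weights to precomputed components (computing them first if
#' absent): `e_weighted = w1 * e_sum + w2 * c_sum + w3 * ec_sum`.
#'
#' @param probes Probe tibble; components are computed via
#'   [probe_score_components()] when missing (extra arguments are passed
#'   along).
#' @param weights Named vector `c(w1, w2, w3)`.
#' @param ... Passed to [probe_score_components()] when needed.
#' @return `probes` with an `e_weighted` column added.
#' @export
weighted_probe_score <- function(probes, weights = c(w1 = 1, w2 = -0.05,
                                                     w3 = 9), ...) {
  if (!all(c("e_sum", "c_sum", "ec_sum") %in% names(probes)))
    probes <- probe_score_components(probes, ...)
  w <- unlist(weights)
  probes$e_weighted <- w[["w1"]] * probes$e_sum + w[["w2"]] * probes$c_sum +
    w[["w3"]] * probes$ec_sum
  probes
}

#' Residues in contact with a probe set
#'
#' Residues with any atom within `radius` (boundary inclusive) of any of
#' the given probe positions.
#'
#' @param probes Probe tibble (typically one cluster's members).
#' @param atoms Atom tibble.
#' @param radius Contact radius in Angstrom (5 by default, the
#'   cluster-to-residue rule of the residue evaluation protocol).
#' @return Tibble of residues: `chain`, `resseq`, `icode`, `resname`,
#'   `res_index`, `res_uid`.
#' @export
contact_residues <- function(probes, atoms, radius = 5) {
  prot <- atoms |> filter(.data$record == "ATOM")
  if (nrow(probes) == 0)
    return(prot[0, c("chain", "resseq", "icode", "resname", "res_index",
                     "res_uid")])
  hit <- near_points_cpp(as_xyz(probes), as_xyz(prot), radius)
  prot[hit, ] |>
    distinct(.data$chain, .data$resseq, .data$icode, .data$resname,
             .data$res_index, .data$res_uid)
}

#' Rank clusters by total weighted score
#'
#' Sums the weighted probe scores per cluster and sorts ascending (most
#' negative first); ties break on lower total raw energy, then on the
#' lexicographically smallest member position.  With `dedup = TRUE`,
#' clusters sitting on distinct chains whose chain-stripped contact-residue
#' sets overlap with Jaccard at least `jaccard_min` and whose totals agree
#' within `score_tol` (relative) are treated as symmetric copies of one
#' multimer site: only the lowest-scoring one stays representative, the
#' others are suppressed (`representative = FALSE`, `rank = NA`).
#' Representative sites carry consecutive ranks from 1.
#'
#' @param probes Clustered, scored probe tibble (columns `cluster`,
#'   `e_vdw`, `e_weighted`).
#' @param atoms Atom tibble of the structure.
#' @param dedup Collapse symmetric multimer duplicates.
#' @param contact_radius Radius for the contact-residue sets.
#' @param jaccard_min,score_tol Duplicate-detection thresholds.
#' @return Ranked-site tibble: `cluster`, `rank`, `representative`,
#'   `duplicate_of`, `n_probes`, `e_vdw_total`, `e_weighted_total`,
#'   centroid `cx`, `cy`, `cz`, `chain` (primary chain by contact count)
#'   and `contact_residues` (list-column).
#' @export
rank_clusters <- function(probes, atoms, dedup = TRUE, contact_radius = 5,
                          jaccard_min = 0.7, score_tol = 0.1) {
  members <- probes |> filter(!is.na(.data$cluster))
  if (nrow(members) == 0)
    return(tibble(cluster = integer(), rank = integer(),
                  representative = logical(), duplicate_of = integer(),
                  n_probes = integer(), e_vdw_total = numeric(),
                  e_weighted_total = numeric(), cx = numeric(),
                  cy = numeric(), cz = numeric(), chain = character(),
                  contact_residues = list()))
  if (!("e_weighted" %in% names(members)))
    abort("probes carry no weighted scores: run weighted_probe_score() first")

  summ <- members |>
    group_by(.data$cluster) |>
    summarise(n_probes = n(), e_vdw_total = sum(.data$e_vdw),
              e_weighted_total = sum(.data$e_weighted),
              cx = mean(.data$x), cy = mean(.data$y), cz = mean(.data$z),
              kx = min(.data$x),
              ky = min(.data$y[.data$x == min(.data$x)]),
              .groups = "drop")

  contacts <- purrr::map(summ$cluster, function(ci)
    contact_residues(members |> filter(.data$cluster == ci), atoms,
                     radius = contact_radius))
  summ$contact_residues <- contacts
  summ$chain <- purrr::map_chr(contacts, function(tb) {
    if (nrow(tb) == 0) return(NA_character_)
    names(sort(table(tb$chain), decreasing = TRUE))[1]
  })
  summ <- summ |>
    arrange(.data$e_weighted_total, .data$e_vdw_total, .data$kx, .data$ky)

  summ$representative <- TRUE
  summ$duplicate_of <- NA_integer_
  if (dedup && nrow(summ) > 1) {
    stripped <- purrr::map(summ$contact_residues, function(tb)
      unique(paste0(tb$resseq, ifelse(tb$icode == "", "", tb$icode), ":",
                    tb$resname)))
    uf <- uf_new(nrow(summ))
    for (i in seq_len(nrow(summ) - 1)) {
      for (j in seq(i + 1, nrow(summ))) {
        if (is.na(summ$chain[i]) || is.na(summ$chain[j])) next
        if (summ$chain[i] == summ$chain[j]) next
        si <- summ$e_weighted_total[i]; sj <- summ$e_weighted_total[j]
        denom <- max(abs(si), abs(sj))
        if (denom > 0 && abs(si - sj) / denom > score_tol) next
        inter <- length(intersect(stripped[[i]], stripped[[j]]))
        uni <- length(union(stripped[[i]], stripped[[j]]))
        if (uni == 0 || inter / uni < jaccard_min) next
        uf_union(uf, i, j)
      }
    }
    comp <- uf_components(uf)
    # rows are sorted ascending by score, so the first row of each group is
    # its minimum and stays representative
    summ$representative <- !duplicated(comp)
    reps <- match(comp, comp[!duplicated(comp)])
    rep_rows <- which(!duplicated(comp))
    summ$duplicate_of <- ifelse(summ$representative, NA_integer_,
                                summ$cluster[rep_rows[reps]])
  }
  summ$rank <- NA_integer_
  summ$rank[summ$representative] <- seq_len(sum(summ$representative))
  summ |>
    select("cluster", "rank", "representative", "duplicate_of", "n_probes",
           "e_vdw_total", "e_weighted_total", "cx", "cy", "cz", "chain",
           "contact_residues")
}
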