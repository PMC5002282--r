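# shared builders and cached expensive fixtures

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# ---- toy atom tables -------------------------------------------------------

# minimal atom tibble in the read_structure() layout
toy_atoms <- function(x, y, z, record = "ATOM", name = "CA",
                      resname = "GLY", chain = "A",
                      resseq = seq_along(x), element = "C",
                      r_vdw = NULL, eps = NULL) {
  n <- length(x)
  at <- tibble(record = rep_len(record, n), serial = seq_len(n),
               name = rep_len(name, n), altloc = "",
               resname = rep_len(resname, n), chain = rep_len(chain, n),
               resseq = rep_len(resseq, n), icode = "",
               x = x, y = y, z = z, occupancy = 1, bfactor = 0,
               element = rep_len(element, n),
               is_hydrogen = rep_len(element, n) %in% c("H", "D"))
  at$res_uid <- paste0(at$chain, ":", at$resseq)
  ord <- c(which(at$record == "ATOM"), which(at$record != "ATOM"))
  at$res_index <- match(at$res_uid, unique(at$res_uid[ord]))
  if (!is.null(r_vdw)) {
    at$type <- ifelse(at$record == "ATOM", "CT", NA_character_)
    at$r_vdw <- ifelse(at$record == "ATOM", rep_len(r_vdw, n), NA_real_)
    at$eps <- ifelse(at$record == "ATOM", rep_len(eps, n), NA_real_)
  }
  at
}

# random parameterized atom cloud for energy tests
random_atom_cloud <- function(n, box = 12, seed = 1) {
  set.seed(seed)
  params <- vdw_param_table()
  pick <- sample(which(params$r_vdw > 0), n, replace = TRUE)
  toy_atoms(runif(n, 0, box), runif(n, 0, box), runif(n, 0, box),
            r_vdw = params$r_vdw[pick], eps = params$eps[pick])
}

random_probes <- function(n, box = 12, seed = 2) {
  set.seed(seed)
  tibble(x = runif(n, -2, box + 2), y = runif(n, -2, box + 2),
         z = runif(n, -2, box + 2))
}

# random clustering fixture: probe positions + negative energies
random_cluster_fixture <- function(n, seed, box = 6) {
  set.seed(seed)
  tibble(x = round(runif(n, 0, box), 2), y = round(runif(n, 0, box), 2),
         z = round(runif(n, 0, box), 2),
         e_vdw = round(-runif(n, 0.05, 3), 3))
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(df, rot, shift) {
  m <- cbind(df$x, df$y, df$z) %*% t(rot)
  df$x <- m[, 1] + shift[1]
  df$y <- m[, 2] + shift[2]
  df$z <- m[, 3] + shift[3]
  df
}

# cluster labels aligned on canonical row order, for partition comparison
cluster_labels <- function(probes) {
  ord <- order(probes$x, probes$y, probes$z)
  probes$cluster[ord]
}

# ---- the ligand-filter boundary construction -------------------------------

# HET group of `n_heavy` atoms in a tight ball plus one offset atom, with a
# protein arranged to give an exact number of (ligand, protein) contacts:
# `n_close` protein atoms contact every ligand atom, one tuner atom contacts
# either 9 or 10 of them depending on `tuner_z`.
ligand_filter_case <- function(n_heavy = 10, n_close = 6, tuner_z = -3.0) {
  stopifnot(n_heavy >= 2)
  lig_z <- c(rep(0, n_heavy - 1), 1)            # one atom offset upward
  lig_x <- c(seq(0, 0.1, length.out = n_heavy - 1), 0)
  lig <- toy_atoms(lig_x, rep(0, n_heavy), lig_z, record = "HETATM",
                   name = paste0("C", seq_len(n_heavy)), resname = "LIG",
                   resseq = 900)
  close_ang <- seq(0, 2 * pi, length.out = n_close + 1)[seq_len(n_close)]
  prot <- toy_atoms(c(2.5 * cos(close_ang), 0),
                    c(2.5 * sin(close_ang), 0),
                    c(rep(0.5, n_close), tuner_z),
                    resseq = seq_len(n_close + 1))
  bind_rows(prot, lig)
}

# ---- cached expensive fixtures --------------------------------------------

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, fn(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

default_pocket_fixture <- function() {
  cached("pocket_fx", function()
    make_pocket_structure(pocket_fixture_spec(seed = 42)))
}

default_pocket_prediction <- function() {
  cached("pocket_pred", function() {
    fx <- default_pocket_fixture()
    cons <- make_conservation_files(fx)
    predict_binding_sites(fx$atoms,
                          conservation = setNames(cons$pssm, cons$chain))
  })
}

dimer_fixture <- function() {
  cached("dimer_fx", function()
    make_pocket_structure(pocket_fixture_spec(dimer = TRUE, seed = 42)))
}

# energy-only, no dedup: used for the symmetry and dedup checks
dimer_energy_prediction <- function() {
  cached("dimer_pred_energy", function()
    predict_binding_sites(dimer_fixture()$atoms, conservation = NULL,
                          config = site_config(dedup = FALSE)))
}

# conservation on chain A only, no dedup
dimer_conserved_prediction <- function() {
  cached("dimer_pred_cons", function() {
    fx <- dimer_fixture()
    cons <- make_conservation_files(fx, conserved_chains = "A")
    predict_binding_sites(fx$atoms,
                          conservation = setNames(cons$pssm, cons$chain),
                          config = site_config(dedup = FALSE))
  })
}

# the two symmetric pocket clusters of a dimer prediction, by centroid
dimer_pocket_sites <- function(pred, fx = dimer_fixture()) {
  sites <- pred$sites
  near <- function(ctr) {
    d <- sqrt((sites$cx - ctr[1])^2 + (sites$cy - ctr[2])^2 +
                (sites$cz - ctr[3])^2)
    which(d < fx$spec$pocket_radius)
  }
  idx <- c(near(fx$pocket_center$A), near(fx$pocket_center$B))
  sites[idx, ]
}

# small, fast end-to-end configuration for unit (non-acceptance) tests
fast_config <- function(...) {
  site_config(margin = 5, p_num = 150L, ...)
}

small_fixture <- function() {
  cached("small_fx", function()
    make_pocket_structure(pocket_fixture_spec(wall_atom_count = 700L,
                                              seed = 7)))
}

small_prediction <- function() {
  cached("small_pred", function() {
    fx <- small_fixture()
    cons <- make_conservation_files(fx)
    predict_binding_sites(fx$atoms,
                          conservation = setNames(cons$pssm, cons$chain),
                          config = fast_config())
  })
}
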