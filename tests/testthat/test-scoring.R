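# weighted probe score, cluster ranking, contact residues

# toy conservation table assigning fixed scores to the residues of `atoms`
toy_conservation <- function(atoms, scores) {
  res <- structure_residues(atoms)
  tibble(chain = res$chain, res_index = res$res_index, resseq = res$resseq,
         icode = res$icode, resname = res$resname, res_uid = res$res_uid,
         c_score = rep_len(scores, nrow(res)), aligned = TRUE)
}

test_that("energy-only weights reduce the score to the raw energy", {
  at <- random_atom_cloud(15, seed = 41)
  pr <- compute_probe_energies(random_probes(30, seed = 42), at)
  cons <- toy_conservation(at, runif(15, 0, 1))
  scored <- weighted_probe_score(pr, weights = c(w1 = 1, w2 = 0, w3 = 0),
                                 atoms = at, conservation = cons)
  expect_equal(scored$e_weighted, pr$e_vdw, tolerance = 1e-9)
  expect_equal(scored$e_sum, pr$e_vdw, tolerance = 1e-9)
})

test_that("the weighted score reproduces the hand-computed example", {
  # one atom at the well distance with E_vdw = -0.5 (eps chosen so the well
  # depth is exactly 0.5), residue conservation 0.4 within the 6 A gate:
  # 1 * (-0.5) + (-0.05) * 0.4 + 9 * (-0.5) * 0.4 = -2.32
  eps_atom <- 0.25 / 0.1094
  at <- toy_atoms(1.908 + 1.908, 0, 0, r_vdw = 1.908, eps = eps_atom)
  pr <- tibble(x = 0, y = 0, z = 0)
  cons <- toy_conservation(at, 0.4)
  scored <- weighted_probe_score(pr, weights = c(w1 = 1, w2 = -0.05, w3 = 9),
                                 atoms = at, conservation = cons)
  expect_equal(scored$e_sum, -0.5, tolerance = 1e-12)
  expect_equal(scored$e_weighted, -2.32, tolerance = 1e-9)
})

test_that("conservation terms are gated at 6 A while energy runs to 10 A", {
  at <- toy_atoms(7, 0, 0, r_vdw = 1.908, eps = 0.1094)  # inside 10, outside 6
  cons <- toy_conservation(at, 0.9)
  pr <- tibble(x = 0, y = 0, z = 0)
  comp <- probe_score_components(pr, at, cons)
  e_pair <- lj_energy(7, 1.908, 0.1094, 1.908, 0.1094)
  expect_equal(comp$e_sum, e_pair, tolerance = 1e-12)
  expect_equal(comp$c_sum, 0)
  expect_equal(comp$ec_sum, 0)
  # with the gate lifted from the cross term, only c_sum stays gated
  open <- probe_score_components(pr, at, cons, gate_cross_term = FALSE)
  expect_equal(open$c_sum, 0)
  expect_equal(open$ec_sum, e_pair * 0.9, tolerance = 1e-12)
  # an atom of the same residue inside 6 A lifts the gate for both terms
  at2 <- bind_rows(at, toy_atoms(4, 0, 0, r_vdw = 1.908, eps = 0.1094))
  at2$resseq <- 1L; at2$res_uid <- "A:1"; at2$res_index <- 1L
  at2$serial <- 1:2
  comp2 <- probe_score_components(pr, at2, toy_conservation(at2, 0.9))
  e2 <- lj_energy(4, 1.908, 0.1094, 1.908, 0.1094)
  expect_equal(comp2$c_sum, 2 * 0.9)            # per atom within 10 A
  expect_equal(comp2$ec_sum, (e_pair + e2) * 0.9, tolerance = 1e-12)
})

test_that("probe scores are additive over atoms (per-atom oracle)", {
  at <- random_atom_cloud(12, seed = 51, box = 8)
  cons <- toy_conservation(at, runif(12, 0, 1))
  pr <- random_probes(20, seed = 52, box = 8)
  comp <- probe_score_components(pr, at, cons)
  cvec <- cons$c_score[match(at$res_index, cons$res_index)]
  for (i in seq_len(nrow(pr))) {
    d <- sqrt((at$x - pr$x[i])^2 + (at$y - pr$y[i])^2 + (at$z - pr$z[i])^2)
    inE <- d <= 10
    gate <- at$res_index %in% at$res_index[d <= 6]
    e <- ifelse(inE, lj_energy(pmax(d, 1e-9), 1.908, 0.1094, at$r_vdw,
                               at$eps), 0)
    expect_equal(comp$e_sum[i], sum(e), tolerance = 1e-9)
    expect_equal(comp$c_sum[i], sum(cvec[inE & gate]), tolerance = 1e-9)
    expect_equal(comp$ec_sum[i], sum((e * cvec)[inE & gate]),
                 tolerance = 1e-9)
  }
})

test_that("clusters rank ascending by total weighted score with tie-breaks", {
  at <- toy_atoms(c(0, 20), 0, 0, resseq = 1:2, r_vdw = 1.908, eps = 0.1094)
  pr <- tibble(x = c(0, 0.5, 20, 20.5), y = 0, z = 0,
               cluster = c(1L, 1L, 2L, 2L),
               e_vdw = c(-3, -2, -1.4, -1.2),
               e_weighted = c(-60, -40, -30, -20))
  sites <- rank_clusters(pr, at, dedup = FALSE)
  expect_equal(sites$rank, c(1L, 2L))
  expect_equal(sites$e_weighted_total, c(-100, -50))
  # exact tie on weighted totals: lower raw energy wins
  pr$e_weighted <- c(-25, -25, -30, -20)
  sites2 <- rank_clusters(pr, at, dedup = FALSE)
  expect_equal(sites2$cluster[sites2$rank == 1], 1L)
})

test_that("contact residues obey the 5 A boundary and match brute force", {
  at <- toy_atoms(c(4.9, 5.1), c(0, 0), c(0, 0), resseq = 1:2)
  probe <- tibble(x = 0, y = 0, z = 0)
  hit <- contact_residues(probe, at, radius = 5)
  expect_equal(hit$resseq, 1L)

  set.seed(61)
  at10 <- random_atom_cloud(30, seed = 61)
  at10$resseq <- rep(1:10, each = 3)
  at10$res_uid <- paste0("A:", at10$resseq)
  at10$res_index <- at10$resseq
  cl <- random_probes(3, seed = 62)
  got <- sort(contact_residues(cl, at10, radius = 5)$resseq)
  d2 <- pocketcons:::cross_dist2(cbind(cl$x, cl$y, cl$z),
                                 cbind(at10$x, at10$y, at10$z))
  want <- sort(unique(at10$resseq[apply(d2 <= 25, 2, any)]))
  expect_equal(got, want)
})

test_that("symmetric multimer sites collapse to one representative", {
  # chain B is a rigid copy of chain A, 30 A away; two identical clusters
  mk_chain <- function(ch, dx) {
    at <- toy_atoms(c(0, 3, 0, 3) + dx, c(0, 0, 3, 3), 0, chain = ch,
                    resseq = 1:4, resname = "GLY",
                    r_vdw = 1.908, eps = 0.1094)
    at
  }
  at <- bind_rows(mk_chain("A", 0), mk_chain("B", 30))
  at$res_index <- seq_len(nrow(at))
  at$serial <- seq_len(nrow(at))
  pr <- tibble(x = c(1.5, 1.6, 31.5, 31.6), y = 1.5, z = 0.5,
               cluster = c(1L, 1L, 2L, 2L),
               e_vdw = c(-2, -2, -2, -2),
               e_weighted = c(-5, -5, -5, -5 + 1e-9))
  dedup_on <- rank_clusters(pr, at, dedup = TRUE)
  expect_equal(sum(dedup_on$representative), 1)
  expect_equal(dedup_on$rank[dedup_on$representative], 1L)
  expect_equal(dedup_on$duplicate_of[!dedup_on$representative],
               dedup_on$cluster[dedup_on$representative])
  dedup_off <- rank_clusters(pr, at, dedup = FALSE)
  expect_equal(sum(dedup_off$representative), 2)
  # the representative of a duplicate group is its minimum score
  expect_equal(dedup_on$e_weighted_total[dedup_on$representative],
               min(pr$e_weighted[1:2] |> sum(),
                   pr$e_weighted[3:4] |> sum()))
})
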