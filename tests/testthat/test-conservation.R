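# PSSM/MSA profiles and Jensen-Shannon conservation

write_hand_pssm <- function(rows, letters) {
  # rows: list of 20-vectors of percentages
  path <- withr::local_tempfile(fileext = ".pssm", .local_envir = parent.frame())
  hdr <- paste0("           ",
                paste(sprintf("%3s", pocketcons:::AA20), collapse = ""), " ",
                paste(sprintf("%3s", pocketcons:::AA20), collapse = ""))
  body <- vapply(seq_along(rows), function(i)
    sprintf("%5d %s  %s  %s  0.00     0.00", i, letters[i],
            paste(sprintf("%3d", rep(0, 20)), collapse = ""),
            paste(sprintf("%3d", rows[[i]]), collapse = "")),
    character(1))
  writeLines(c("", "Last position-specific scoring matrix computed", hdr,
               body, ""), path)
  path
}

test_that("PSSM percentages become normalized frequencies", {
  rows <- list(c(100, rep(0, 19)),        # pure A
               rep(0, 20),                # no information: background
               c(50, 50, rep(0, 18)))     # A/R split
  path <- write_hand_pssm(rows, c("A", "G", "A"))
  prof <- parse_pssm(path)
  expect_equal(nrow(prof), 3)
  expect_equal(prof$A[1], 1)
  expect_equal(sum(prof[1, pocketcons:::AA20]), 1)
  expect_equal(unlist(prof[2, pocketcons:::AA20]),
               background_frequencies(), ignore_attr = TRUE)
  expect_equal(prof$A[3], 0.5)
  expect_equal(prof$R[3], 0.5)
})

test_that("the PSSM query sequence reads back from the file", {
  rows <- rep(list(c(rep(5, 20))), 5)
  path <- write_hand_pssm(rows, c("M", "K", "L", "V", "F"))
  prof <- parse_pssm(path)
  expect_equal(paste(prof$aa, collapse = ""), "MKLVF")
  expect_equal(prof$pos, 1:5)
})

test_that("malformed PSSM files are rejected with a line number", {
  path <- withr::local_tempfile(fileext = ".pssm")
  writeLines(c("", "not a pssm", "still not"), path)
  expect_error(parse_pssm(path), "no amino-acid header")
  rows <- list(c(100, rep(0, 19)))
  good <- write_hand_pssm(rows, "A")
  bad <- readLines(good)
  bad[4] <- "    1 A  only three fields"
  writeLines(bad, good)
  expect_error(parse_pssm(good), "line 4")
})

test_that("MSA columns count into frequencies, ignoring gaps", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">q",  "AAC",
               ">s1", "AAC",
               ">s2", "AC-",
               ">s3", "AC-"), path)
  prof <- profile_from_msa(path)
  expect_equal(nrow(prof), 3)
  expect_equal(prof$A[1], 1)                  # column A,A,A,A
  expect_equal(prof$A[2], 0.5)                # column A,A,C,C
  expect_equal(prof$C[2], 0.5)
  expect_equal(prof$C[3], 1)                  # column C,C,-,- ignores gaps
  # identical sequences concentrate all mass on the query letter
  writeLines(c(">q", "GW", ">a", "GW", ">b", "GW", ">c", "GW"), path)
  ident <- profile_from_msa(path)
  expect_equal(ident$G[1], 1)
  expect_equal(ident$W[2], 1)
})

test_that("Jensen-Shannon divergence has its closed-form anchors", {
  u <- rep(1 / 20, 20)
  expect_equal(jensen_shannon(u, u), 0)
  p <- c(rep(0.1, 10), rep(0, 10))
  q <- c(rep(0, 10), rep(0.1, 10))
  expect_equal(jensen_shannon(p, q), 1)       # disjoint support, base 2
  # independent term-by-term reference for an asymmetric pair
  q2 <- c(0.5, rep(0.5 / 19, 19))
  m <- (u + q2) / 2
  expected <- 0.5 * sum(u * log2(u / m)) +
    0.5 * sum(q2 * log2(q2 / m))
  expect_equal(jensen_shannon(u, q2), expected, tolerance = 1e-12)
  expect_error(jensen_shannon(u, u * 2), "sum to 1")
})

test_that("divergence is symmetric and bounded on random distributions", {
  set.seed(5)
  for (i in 1:200) {
    p <- rgamma(20, 0.4); p <- p / sum(p)
    q <- rgamma(20, 0.4); q <- q / sum(q)
    v <- jensen_shannon(p, q)
    expect_equal(v, jensen_shannon(q, p), tolerance = 1e-12)
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
})

test_that("chain conservation scores map positions onto residues", {
  at <- toy_atoms(seq(0, 12, by = 3), rep(0, 5), rep(0, 5),
                  resname = c("MET", "LYS", "LEU", "VAL", "PHE"))
  bg <- background_frequencies()
  rows <- list(c(rep(0, 12), 100, rep(0, 7)),   # pure M (column 13)
               round(100 * bg),                 # ~background
               c(rep(5, 20)), c(rep(5, 20)), c(rep(5, 20)))
  path <- write_hand_pssm(rows, c("M", "K", "L", "V", "F"))
  prof <- parse_pssm(path)
  cp <- conservation_for_chain(prof, at, "A")
  expect_equal(nrow(cp), 5)
  expect_true(all(cp$aligned))
  # fully conserved position scores as the oracle says
  expect_equal(cp$c_score[1],
               jensen_shannon(unlist(prof[1, pocketcons:::AA20]), bg))
  # near-background positions score near zero, far below the conserved one
  expect_lt(cp$c_score[2], 0.01)
  expect_gt(cp$c_score[1], 10 * cp$c_score[2])
  # an exactly-background profile scores exactly zero
  prof0 <- prof
  prof0[2, pocketcons:::AA20] <- as.list(bg)
  cp0 <- conservation_for_chain(prof0, at, "A")
  expect_equal(cp0$c_score[2], 0)
})

test_that("residues without a profile position get the chain median", {
  # structure chain misses the 3rd residue of the 5-position query: those
  # residues all map (substring), nothing is flagged
  at4 <- toy_atoms(seq(0, 9, by = 3), rep(0, 4), rep(0, 4),
                   resname = c("MET", "LYS", "VAL", "PHE"),
                   resseq = c(1, 2, 4, 5))
  rows5 <- list(c(rep(0, 12), 100, rep(0, 7)), rep(5, 20), rep(5, 20),
                rep(5, 20), rep(5, 20))
  prof5 <- parse_pssm(write_hand_pssm(rows5, c("M", "K", "L", "V", "F")))
  cp4 <- conservation_for_chain(prof5, at4, "A")
  expect_equal(nrow(cp4), 4)
  expect_true(all(cp4$aligned))

  # conversely, a 4-position profile against a 5-residue chain leaves one
  # structure residue unmatched: flagged, chain-median score
  at5 <- toy_atoms(seq(0, 12, by = 3), rep(0, 5), rep(0, 5),
                   resname = c("MET", "LYS", "LEU", "VAL", "PHE"))
  prof4 <- parse_pssm(write_hand_pssm(
    list(c(rep(0, 12), 100, rep(0, 7)), rep(5, 20), rep(5, 20), rep(5, 20)),
    c("M", "K", "V", "F")))
  expect_warning(cp5 <- conservation_for_chain(prof4, at5, "A"),
                 "chain-median")
  expect_false(cp5$aligned[3])
  expect_equal(cp5$c_score[3], median(cp5$c_score[cp5$aligned]))

  # a mismatching chain errors below the identity floor
  at_bad <- toy_atoms(seq(0, 12, by = 3), rep(0, 5), rep(0, 5),
                      resname = c("ALA", "ALA", "ALA", "ALA", "ALA"))
  expect_error(suppressWarnings(conservation_for_chain(prof5, at_bad, "A")),
               "identity")
})

test_that("queries identical to the MSA only sharpen conservation", {
  set.seed(9)
  bg <- background_frequencies()
  path <- withr::local_tempfile(fileext = ".fasta")
  letters20 <- pocketcons:::AA20
  q <- paste(sample(letters20, 8, replace = TRUE), collapse = "")
  others <- vapply(1:6, function(i)
    paste(sample(letters20, 8, replace = TRUE), collapse = ""), "")
  writeLines(c(rbind(paste0(">s", 0:6), c(q, others))), path)
  base <- profile_from_msa(path)
  base_scores <- vapply(seq_len(nrow(base)), function(i)
    jensen_shannon(unlist(base[i, letters20]), bg), numeric(1))
  writeLines(c(rbind(paste0(">s", 0:9), c(q, others, q, q, q))), path)
  more <- profile_from_msa(path)
  more_scores <- vapply(seq_len(nrow(more)), function(i)
    jensen_shannon(unlist(more[i, letters20]), bg), numeric(1))
  expect_true(all(more_scores >= base_scores - 1e-9))
})
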