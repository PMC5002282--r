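# internal helpers shared across modules

as_xyz <- function(df) {
  m <- cbind(df$x, df$y, df$z)
  storage.mode(m) <- "double"
  m
}

# squared cross-distances between two coordinate sets (small-n use only)
cross_dist2 <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# minimal union-find over 1..n
uf_new <- function(n) {
  env <- new.env(parent = emptyenv())
  env$parent <- seq_len(n)
  env
}

uf_find <- function(uf, i) {
  p <- uf$parent
  root <- i
  while (p[root] != root) root <- p[root]
  while (p[i] != root) {
    nxt <- p[i]
    p[i] <- root
    i <- nxt
  }
  uf$parent <- p
  root
}

uf_union <- function(uf, i, j) {
  ri <- uf_find(uf, i)
  rj <- uf_find(uf, j)
  if (ri != rj) uf$parent[max(ri, rj)] <- min(ri, rj)
  invisible(uf)
}

uf_components <- function(uf) {
  vapply(seq_along(uf$parent), function(i) uf_find(uf, i), integer(1))
}

res_key <- function(chain, resseq, icode = "") {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  paste0(chain, ":", resseq, icode)
}

# one-letter amino-acid codes for the 20 standard residues
AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

# PSSM column order (PSI-BLAST convention)
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

WATER_RESNAMES <- c("HOH", "WAT", "DOD")
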