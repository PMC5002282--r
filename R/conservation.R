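#' Parse a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Reads the standard `-out_ascii_pssm` layout (query column, 20 log-odds
#' columns, 20 weighted-observed-percentage columns).  Per position, the
#' weighted percentages divided by 100 and renormalized become the
#' amino-acid frequency vector; all-zero rows (positions carrying no
#' information) fall back to the background distribution.
#'
#' @param path Path to the ASCII PSSM file.
#' @param background Background distribution used for zero rows, see
#'   [background_frequencies()].
#' @return A tibble with one row per position: `pos`, `aa` (query letter)
#'   and the 20 frequency columns named by amino acid, each row summing
#'   to 1.
#' @export
parse_pssm <- function(path, background = background_frequencies()) {
  if (!file.exists(path)) abort(paste0("cannot read PSSM file: ", path))
  lines <- readLines(path, warn = FALSE)
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])

  header <- which(vapply(toks, function(tk)
    length(tk) >= 40 && all(tk[seq_len(40)] %in% AA20), logical(1)))
  if (length(header) == 0)
    abort("malformed PSSM: no amino-acid header row found")
  aa_cols <- toks[[header[1]]][1:20]

  rows <- list()
  for (ln in seq(header[1] + 1, length(lines))) {
    tk <- toks[[ln]]
    if (length(tk) == 0) next
    if (is.na(suppressWarnings(as.integer(tk[1])))) break
    if (length(tk) < 42)
      abort(paste0("malformed PSSM row at line ", ln,
                   ": expected >= 42 fields, got ", length(tk)))
    vals <- suppressWarnings(as.numeric(tk[3:42]))
    if (anyNA(vals))
      abort(paste0("malformed PSSM row at line ", ln, ": non-numeric field"))
    rows[[length(rows) + 1]] <- list(pos = as.integer(tk[1]), aa = tk[2],
                                     pct = vals[21:40])
  }
  if (length(rows) == 0) abort("malformed PSSM: no data rows")

  freq <- t(vapply(rows, function(r) {
    p <- r$pct / 100
    if (sum(p) <= 0) return(unname(background))
    unname(p / sum(p))
  }, numeric(20)))
  colnames(freq) <- aa_cols
  out <- tibble(pos = vapply(rows, `[[`, integer(1), "pos"),
                aa = vapply(rows, `[[`, character(1), "aa"))
  bind_cols(out, as_tibble(freq)[, AA20])
}

#' Position frequency profile from a multiple sequence alignment
#'
#' Reads an aligned FASTA file (first sequence is the query) and, for each
#' query non-gap column, turns the amino-acid counts (plus an optional
#' pseudocount) into a frequency vector.  Gaps and non-standard letters are
#' ignored in the counts.
#'
#' @param path Aligned FASTA file; all sequences must have equal length.
#' @param pseudocount Added to every amino-acid count per column.
#' @return Same shape as [parse_pssm()]: `pos`, `aa`, 20 frequency columns.
#' @export
profile_from_msa <- function(path, pseudocount = 0) {
  aln <- bio3d::read.fasta(path)
  mat <- toupper(aln$ali)
  if (nrow(mat) < 1) abort("alignment contains no sequences")
  lens <- apply(mat, 1, length)
  if (length(unique(lens)) != 1) abort("ragged alignment")
  query <- mat[1, ]
  keep <- which(!query %in% c("-", "."))
  rows <- lapply(seq_along(keep), function(i) {
    col <- mat[, keep[i]]
    counts <- table(factor(col[col %in% AA20], levels = AA20))
    f <- as.numeric(counts) + pseudocount
    if (sum(f) <= 0)
      abort(paste0("alignment column ", keep[i],
                   " has no amino acids and no pseudocount"))
    f / sum(f)
  })
  freq <- do.call(rbind, rows)
  colnames(freq) <- AA20
  bind_cols(tibble(pos = seq_along(keep), aa = query[keep]),
            as_tibble(freq))
}

#' Jensen-Shannon divergence between two distributions
#'
#' `JSD(p, q) = KL(p || m)/2 + KL(q || m)/2` with `m = (p + q)/2` and the
#' convention `0 * log 0 = 0`.  With base-2 logarithms the value lies in
#' `[0, 1]`, reaching 0 iff `p == q` and 1 iff the supports are disjoint.
#'
#' @param p,q Non-negative vectors of equal length, each summing to 1.
#' @param base Logarithm base (2 by default so scores live in `[0, 1]`).
#' @return A single non-negative number.
#' @export
jensen_shannon <- function(p, q, base = 2) {
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != length(q)) abort("p and q must have equal length")
  if (any(p < 0) || any(q < 0)) abort("distributions must be non-negative")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    abort("distributions must each sum to 1")
  m <- (p + q) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log(a[i] / m[i], base = base))
  }
  (kl(p) + kl(q)) / 2
}

#' Per-residue conservation scores for one chain
#'
#' Maps a per-position frequency profile onto the residues of one structure
#' chain and scores each mapped residue with the Jensen-Shannon divergence
#' between its position frequencies and the background (the conservation
#' score).  The profile query sequence is matched against the chain's
#' observed residue sequence exactly; when the two differ (unresolved
#' residues), a global alignment (Biostrings, BLOSUM62) supplies the
#' mapping, and the aligned region must retain at least `min_identity`
#' sequence identity.  Structure residues with no aligned position are
#' flagged and receive the chain-median score, with a warning.
#'
#' @param profile Profile tibble from [parse_pssm()] or [profile_from_msa()].
#' @param atoms Atom tibble of the structure.
#' @param chain Chain identifier to score.
#' @param background Background distribution, see [background_frequencies()].
#' @param min_identity Minimum identity over the aligned region.
#' @param base Logarithm base for the divergence.
#' @return Tibble with `chain`, `res_index`, `resseq`, `icode`, `resname`,
#'   `res_uid`, `c_score`, `aligned`.
#' @export
conservation_for_chain <- function(profile, atoms, chain,
                                   background = background_frequencies(),
                                   min_identity = 0.9, base = 2) {
  seqtb <- chain_sequence(atoms, chain)
  qseq <- paste(profile$aa, collapse = "")
  cseq <- paste(seqtb$aa, collapse = "")

  map <- map_query_to_chain(qseq, cseq, min_identity)
  scores <- vapply(seq_len(nrow(profile)), function(i)
    jensen_shannon(as.numeric(profile[i, AA20]), background, base = base),
    numeric(1))

  c_score <- rep(NA_real_, nrow(seqtb))
  hit <- !is.na(map)
  c_score[map[hit]] <- scores[hit]
  aligned <- !is.na(c_score)
  if (!any(aligned)) abort("no profile position maps onto the chain")
  if (any(!aligned)) {
    c_score[!aligned] <- median(c_score[aligned])
    warn(paste0(sum(!aligned), " residues of chain ", chain,
                " have no profile position; chain-median score assigned"))
  }
  tibble(chain = chain, res_index = seqtb$res_index, resseq = seqtb$resseq,
         icode = seqtb$icode, resname = seqtb$resname,
         res_uid = seqtb$res_uid, c_score = c_score, aligned = aligned)
}

# position map: map[i] = chain residue row for query position i (NA if none)
map_query_to_chain <- function(qseq, cseq, min_identity) {
  nq <- nchar(qseq)
  if (qseq == cseq) return(seq_len(nq))
  off <- as.integer(regexpr(cseq, qseq, fixed = TRUE))
  map <- rep(NA_integer_, nq)
  if (off > 0) {  # chain sequence is an exact substring of the query
    map[seq_len(nchar(cseq)) + off - 1L] <- seq_len(nchar(cseq))
    return(map)
  }
  aln <- Biostrings::pairwiseAlignment(qseq, cseq, type = "global",
                                       substitutionMatrix = "BLOSUM62",
                                       gapOpening = 10, gapExtension = 0.5)
  qa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  ca <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  qi <- 0L; ci <- 0L; match_n <- 0L; both <- 0L
  for (t in seq_along(qa)) {
    if (qa[t] != "-") qi <- qi + 1L
    if (ca[t] != "-") ci <- ci + 1L
    if (qa[t] != "-" && ca[t] != "-") {
      both <- both + 1L
      if (qa[t] == ca[t]) match_n <- match_n + 1L
      map[qi] <- ci
    }
  }
  if (both == 0 || match_n / both < min_identity)
    abort(sprintf(paste0("profile query and chain sequence share only ",
                         "%.1f %% identity over the aligned region ",
                         "(minimum %.0f %%)"),
                  if (both > 0) 100 * match_n / both else 0,
                  100 * min_identity))
  map
}

#' Conservation profiles for several chains
#'
#' Convenience wrapper: applies [conservation_for_chain()] to a named set of
#' profile inputs (tibbles or file paths; `.pssm`/`.mat` files go through
#' [parse_pssm()], anything else through [profile_from_msa()]).
#'
#' @param atoms Atom tibble.
#' @param inputs Named list or character vector, one entry per chain.
#' @inheritParams conservation_for_chain
#' @return One tibble with the per-chain results stacked.
#' @export
conservation_profiles <- function(atoms, inputs,
                                  background = background_frequencies(),
                                  min_identity = 0.9, base = 2) {
  if (is.null(names(inputs)) || any(!nzchar(names(inputs))))
    abort("`inputs` must be named by chain id")
  purrr::map_dfr(names(inputs), function(ch) {
    inp <- inputs[[ch]]
    prof <- if (is.character(inp)) {
      if (grepl("\\.(pssm|mat|asn)$", inp, ignore.case = TRUE))
        parse_pssm(inp, background = background)
      else profile_from_msa(inp)
    } else inp
    conservation_for_chain(prof, atoms, ch, background = background,
                           min_identity = min_identity, base = base)
  })
}
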