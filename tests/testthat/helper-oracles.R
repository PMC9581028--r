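# Independent brute-force oracles. These deliberately re-derive every score
# from its definition with explicit loops, sharing no code with the package
# internals, so that agreement is evidence of correctness rather than of
# shared bugs.

ORACLE_STARTS <- c("ATG", "GTG", "TTG")
ORACLE_NONSTART_VL <- c("GTA", "GTC", "GTT", "CTA", "CTC", "CTG", "CTT", "TTA")

# Block identity score: double loop over ordered row pairs and the r
# query-ungapped columns at/after aa_col. Returns NA when the block is not
# evaluable.
oracle_sblk <- function(aa_rows, query_index, aa_col, r,
                        norm = c("printed", "pair_count")) {
  norm <- match.arg(norm)
  mat <- do.call(rbind, strsplit(aa_rows, ""))
  n <- nrow(mat)
  qcols <- which(mat[query_index, ] != "-")
  qcols <- qcols[qcols >= aa_col]
  if (length(qcols) < r) return(NA_real_)
  J <- qcols[seq_len(r)]
  total <- 0
  for (m in seq_len(n)) {
    for (k in seq_len(n)) {
      if (m == k) next
      for (j in J) {
        a <- mat[m, j]; b <- mat[k, j]
        if (a != "-" && b != "-" && a != "X" && b != "X" && a == b)
          total <- total + 1
      }
    }
  }
  denom <- if (norm == "printed") r * (n - 1)^2 else r * n * (n - 1)
  total / denom
}

# Candidate conservation score: loop over target rows; a target supports the
# candidate when any of its codons whose first aligned nucleotide lies within
# x codons of the candidate column is a start codon; it is penalised when its
# codon at the candidate column is a non-start valine/leucine codon.
oracle_s5 <- function(nt_rows, query_index, cand_aa_col, x) {
  n <- length(nt_rows)
  L <- nchar(nt_rows[1]) / 3
  codon_at <- function(row, a) substr(nt_rows[row], 3 * (a - 1) + 1, 3 * a)
  total <- 0
  for (row in setdiff(seq_len(n), query_index)) {
    g <- 0
    for (a in seq_len(L)) {
      if (abs(a - cand_aa_col) <= x) {
        cod <- codon_at(row, a)
        if (cod %in% ORACLE_STARTS) g <- 1
      }
    }
    p <- if (codon_at(row, cand_aa_col) %in% ORACLE_NONSTART_VL) 1 else 0
    total <- total + g - p
  }
  total / (n - 1)
}

# Intergenic conservation: mode (ties to smallest |x| then most negative),
# then the fraction of distances inside [mode - f, mode + f].
oracle_dc <- function(distances, f) {
  counts <- table(distances)
  best <- max(counts)
  tied <- as.integer(names(counts)[counts == best])
  tied <- tied[order(abs(tied), tied)]
  mode_x <- tied[1]
  hits <- 0
  for (d in distances) {
    if (d >= mode_x - f && d <= mode_x + f) hits <- hits + 1
  }
  list(mode_x = mode_x, dc = hits / length(distances))
}

# Direct evaluation of the K2P estimator.
oracle_kimura <- function(p, q) {
  if (1 - 2 * p - q <= 0 || 1 - 2 * q <= 0) return(NA_real_)
  -0.5 * log((1 - 2 * p - q) * sqrt(1 - 2 * q))
}

# Closed-form K80 transition/transversion probabilities after expected
# distance d with ts/tv rate ratio R (used to check the simulator's moves).
oracle_k80_pq <- function(d, R) {
  a <- d * R / (R + 2)
  b <- d / (R + 2)
  list(P = 0.25 + 0.25 * exp(-4 * b) - 0.5 * exp(-2 * (a + b)),
       Q = 0.5 - 0.5 * exp(-4 * b))
}

# Brute-force frame-0 start-codon scan.
oracle_scan_candidates <- function(nt) {
  hits <- integer(0)
  for (i in seq(1, nchar(nt) - 2, by = 3)) {
    if (substr(nt, i, i + 2) %in% ORACLE_STARTS) hits <- c(hits, i - 1L)
  }
  hits
}
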