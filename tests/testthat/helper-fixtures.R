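# Builders for small in-memory alignments used across test files.

# A dual_msa from explicit codon-level nucleotide rows (no indels): rows are
# strings whose length is a multiple of 3; "---" marks a gap codon.
msa_from_nt_rows <- function(nt_rows, query_index = 1L, ids = NULL) {
  n <- length(nt_rows)
  if (is.null(ids)) ids <- c("query", sprintf("t%02d", seq_len(n - 1)))
  if (query_index != 1L) ids <- sprintf("s%02d", seq_len(n))
  recs <- vector("list", n)
  aligned <- character(n)
  for (i in seq_len(n)) {
    cods <- substring(nt_rows[i], seq(1, nchar(nt_rows[i]) - 2, 3),
                      seq(3, nchar(nt_rows[i]), 3))
    gap <- cods == "---"
    nt <- paste(cods[!gap], collapse = "")
    recs[[i]] <- lorf_record(ids[i], nt)
    aa <- strsplit(recs[[i]]$aa, "")[[1]]
    row <- character(length(cods))
    row[gap] <- "-"
    row[!gap] <- aa
    aligned[i] <- paste(row, collapse = "")
  }
  names(aligned) <- ids
  backmap_to_nucleotide(aligned, recs, query_id = ids[query_index])
}

# Random gapped protein alignment with consistent LORF records: generates
# random coding sequences, aligns them colinearly, then injects random gap
# codons (keeping at least min_codons per row). Rows always end with a stop.
random_gapped_msa <- function(n, len_codons, gap_prob = 0.15) {
  pool <- setdiff(startfinder:::ALL_CODONS, c("TAA", "TAG", "TGA"))
  rows <- vapply(seq_len(n), function(i) {
    cods <- sample(pool, len_codons, replace = TRUE)
    keep <- runif(len_codons) >= gap_prob
    keep[sample(len_codons, 2)] <- TRUE # never an all-gap row
    cods[!keep] <- "---"
    paste(c(cods, "TAA"), collapse = "")
  }, character(1))
  msa_from_nt_rows(rows)
}

# Explicitly-constructed pairwise alignment rows with a prescribed number of
# transitions/transversions over a given length (no gaps).
rows_with_pq <- function(n_sites, n_ts, n_tv) {
  stopifnot(n_ts + n_tv <= n_sites)
  a <- rep("A", n_sites)
  b <- rep("A", n_sites)
  if (n_ts > 0) b[seq_len(n_ts)] <- "G"             # A->G transitions
  if (n_tv > 0) b[n_ts + seq_len(n_tv)] <- "C"      # A->C transversions
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

# A relation-table row for select_targets with exact (P, Q) content.
relation_with_pq <- function(id, n_sites, n_ts, n_tv,
                             coverage_query = 1, coverage_target = 1) {
  r <- rows_with_pq(n_sites, n_ts, n_tv)
  tibble::tibble(
    target_id = id, aln_query = r$a, aln_target = r$b,
    coverage_query = coverage_query, coverage_target = coverage_target
  )
}

# Shorthand: simulate a family and run the full pipeline on it.
run_family <- function(spec, cfg = scoring_config()) {
  fam <- simulate_family(spec)
  res <- run_prediction(fam$query, fam$targets, fam$relations, cfg)
  list(family = fam, result = res)
}

# Codon vocabulary for hand-built fixtures: five codons with pairwise
# distinct residues (K, P, G, F, A), none of them start codons.
JUNK5 <- c("AAA", "CCC", "GGG", "TTT", "GCT")
CONS14 <- c("GAA", "CAA", "ATC", "TGG", "CGT", "ACT", "TCT",
            "CAT", "AAC", "GAT", "GCT", "GAA", "CAA", "ATC")

# n_rows x n_cols codon matrix filled with rotating junk so that every column
# holds pairwise distinct residues (column match count 0).
junk_matrix <- function(n_rows, n_cols) {
  m <- matrix("", n_rows, n_cols)
  for (j in seq_len(n_cols)) {
    m[, j] <- JUNK5[((seq_len(n_rows) + j) %% 5) + 1][seq_len(n_rows)]
  }
  m
}

msa_from_codon_matrix <- function(m) {
  msa_from_nt_rows(apply(cbind(m, "TAA"), 1, paste, collapse = ""))
}

# Fig. 5-left configuration: junk columns 1-10 with a single query ATG at
# column 3, then 14 identical (conserved) columns.
step_a_fixture <- function(two_candidates = FALSE) {
  m <- junk_matrix(5, 10)
  m[1, 3] <- "ATG"
  if (two_candidates) m[1, 5] <- "GTG"
  m <- cbind(m, matrix(rep(CONS14, each = 5), 5, 14))
  msa_from_codon_matrix(m)
}

# Step C fixture: u = ATG at column 1 with tunable support, d = ATG at column
# 5 (12 nt downstream) with tunable support; columns 2-4 junk or conserved.
step_c_fixture <- function(u_support, d_support, conserved_between = FALSE) {
  n <- 6
  m <- junk_matrix(n, 8)
  m[1, 1] <- "ATG"
  if (u_support > 0) m[1 + seq_len(u_support), 1] <- "ATG"
  m[1, 5] <- "ATG"
  if (d_support > 0) m[1 + seq_len(d_support), 5] <- "ATG"
  if (conserved_between) {
    m[, 2] <- "GAA"; m[, 3] <- "CAA"; m[, 4] <- "ATC"
  }
  msa_from_codon_matrix(m)
}
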