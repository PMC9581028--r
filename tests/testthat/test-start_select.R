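test_that("block score matches the printed normalization on boundary cases", {
  # every row identical over the block, N = 11, r = 10 -> N/(N-1) = 1.1
  m <- matrix(rep(CONS14[1:12], each = 11), 11, 12)
  msa <- msa_from_codon_matrix(m)
  b <- block_conservation_score(msa, 1, r = 10)
  expect_equal(b$score, 1.1)
  expect_true(b$conserved)
  # pair-count normalization caps the same block at exactly 1
  b2 <- block_conservation_score(msa, 1, r = 10,
                                 cfg = scoring_config(blk_norm = "pair_count"))
  expect_equal(b2$score, 1)
  # all rows pairwise distinct at every block column -> 0
  msa0 <- msa_from_codon_matrix(junk_matrix(5, 12))
  expect_equal(block_conservation_score(msa0, 1, r = 10)$score, 0)
  # block not evaluable when fewer than r query-ungapped columns remain
  expect_equal(nrow(block_conservation_score(msa0, 5, r = 10)), 0L)
})

test_that("block and candidate scores equal brute-force oracles on random alignments", {
  set.seed(321)
  cfg <- scoring_config()
  for (i in 1:60) {
    n <- sample(3:8, 1)
    len <- sample(12:30, 1)
    msa <- random_gapped_msa(n, len)
    r <- sample(2:4, 1)
    i0 <- sample.int(max(1, msa$L - r - 3), 1)
    got <- block_conservation_score(msa, i0, r = r, cfg = cfg)
    want <- oracle_sblk(unname(msa$aa), msa$query_index, i0, r)
    if (nrow(got) == 0L) {
      expect_true(is.na(want))
    } else {
      expect_equal(got$score, want)
      expect_lte(got$score, n / (n - 1) + 1e-12)
    }
    # candidate score against the loop oracle, at a random query codon column
    qcols <- which(!is.na(msa$aa_mat[msa$query_index, ]))
    a <- sample(qcols, 1)
    cand <- list(seq_offset = msa$col_map[[msa$query_index]][a] * 3L,
                 codon = msa$codon_mat[msa$query_index, a], aa_col = a)
    got5 <- candidate_score_s5(msa, cand, cfg)
    expect_equal(got5$s5, oracle_s5(unname(msa$nt), msa$query_index, a,
                                    cfg$neigh_codons))
    expect_lte(got5$s5, 1)
  }
})

test_that("leftmost conserved block agrees with an exhaustive scan", {
  set.seed(77)
  cfg <- scoring_config(block_len_aa = 3)
  for (i in 1:25) {
    msa <- random_gapped_msa(sample(3:6, 1), sample(10:20, 1), gap_prob = 0.1)
    got <- find_leftmost_conserved_block(msa, cfg)
    # exhaustive scan over scored columns (query-ungapped, excluding start
    # candidates, which are possible N-terminals and never block members)
    qcols <- setdiff(which(!is.na(msa$aa_mat[msa$query_index, ])),
                     msa$query_candidates$aa_col)
    mat <- do.call(rbind, strsplit(unname(msa$aa), ""))
    col_matches <- function(j) {
      tot <- 0
      for (m in seq_len(msa$n)) for (h in seq_len(msa$n)) {
        if (m == h) next
        a_ <- mat[m, j]; b_ <- mat[h, j]
        if (a_ != "-" && b_ != "-" && a_ == b_) tot <- tot + 1
      }
      tot
    }
    want <- NULL
    for (k in seq_along(qcols)) {
      J <- qcols[k:length(qcols)]
      if (length(J) < 3) break
      J <- J[1:3]
      if (sum(vapply(J, col_matches, numeric(1))) / (3 * (msa$n - 1)^2) >
          cfg$t_blk) {
        # boundary: first member column conserved on its own
        for (j in J) {
          if (col_matches(j) / (msa$n - 1)^2 > cfg$t_blk) { want <- j; break }
        }
        break
      }
    }
    if (is.null(want)) expect_null(got) else expect_equal(got$aa_col, want)
  }
  # fully conserved from column 0 -> block at the left edge
  msa <- msa_from_codon_matrix(matrix(rep(CONS14, each = 4), 4, 14))
  expect_equal(find_leftmost_conserved_block(msa, scoring_config())$aa_col, 1L)
  # fully random MSA -> none
  expect_null(find_leftmost_conserved_block(
    msa_from_codon_matrix(junk_matrix(5, 20)), scoring_config()))
})

test_that("step A fires on a single upstream candidate and falls through otherwise", {
  msa <- step_a_fixture()
  blk <- find_leftmost_conserved_block(msa, scoring_config())
  # the window qualifies from column 6 (5 fully conserved columns suffice),
  # and the block boundary sits on its first conserved column
  expect_equal(blk$aa_col, 11L)
  pred <- step_a(msa)
  expect_equal(pred$step, "A")
  expect_equal(pred$query_offset, 6L) # column 3, 0-based nt offset
  # two candidates upstream of the block: fall through
  expect_null(step_a(step_a_fixture(two_candidates = TRUE)))
  # no conserved block anywhere: fall through
  expect_null(step_a(msa_from_codon_matrix(junk_matrix(5, 20))))
})

test_that("candidate score handles support, penalties and all-gap windows", {
  # 10 targets: 8 with ATG at the candidate column, 2 with gap codons
  rows <- c("ATGGCTTAA",
            rep("ATGGCTTAA", 8),
            rep("---GCTTAA", 2))
  msa <- msa_from_nt_rows(rows)
  cand <- msa$query_candidates[1, ]
  expect_equal(candidate_score_s5(msa, cand)$s5, 0.8)
  # 8 support, 1 non-start valine (GTT) at the column, 1 gap
  rows2 <- c("ATGGCTTAA", rep("ATGGCTTAA", 8), "GTTGCTTAA", "---GCTTAA")
  msa2 <- msa_from_nt_rows(rows2)
  sc2 <- candidate_score_s5(msa2, msa2$query_candidates[1, ])
  expect_equal(sc2$s5, 0.7)
  expect_equal(sc2$n_support, 8L)
  expect_equal(sc2$n_penalty, 1L)
  # every target gap across the whole window -> 0
  rows3 <- c("ATGGCTAAATAA", rep("---------TAA", 3))
  msa3 <- msa_from_nt_rows(rows3)
  expect_equal(candidate_score_s5(msa3, msa3$query_candidates[1, ])$s5, 0)
})

test_that("step B selects a supported candidate near the upstream gene 3' end", {
  # query ATG at column 3 (offset 6), upstream gene ends at offset 10 (-4 overlap)
  m <- junk_matrix(5, 8)
  m[, 3] <- "ATG"
  msa <- msa_from_codon_matrix(m)
  pred <- step_b(msa, upstream_gene_end_offset = 10)
  expect_equal(pred$step, "B")
  expect_equal(pred$query_offset, 6L)
  # s5 at/below threshold: fall through (2 support, 2 penalties -> 0)
  m2 <- junk_matrix(5, 8)
  m2[1:3, 3] <- "ATG"
  m2[4:5, 3] <- "GTT"
  expect_null(step_b(msa_from_codon_matrix(m2), 10))
  # no candidate within 9 nt of the 3' end: fall through
  expect_null(step_b(msa, upstream_gene_end_offset = 30))
  # no context: step skipped
  expect_null(step_b(msa, NA))
})

test_that("step C screens candidates 5' to 3' and re-checks the downstream window", {
  # single supported candidate, nothing downstream: C-2 vacuous
  m <- junk_matrix(5, 14)
  m[, 3] <- "ATG"
  pred <- step_c(msa_from_codon_matrix(m))
  expect_equal(pred$step, "C")
  expect_equal(pred$query_offset, 6L)

  # u (s5 = 0.6) then better-supported d (s5 = 1) with no block between:
  # downstream candidate wins
  pred <- step_c(step_c_fixture(u_support = 3, d_support = 5))
  expect_equal(pred$query_offset, 12L)
  expect_equal(pred$step, "C")

  # same but a conserved block strictly between the candidates protects u
  pred <- step_c(step_c_fixture(u_support = 3, d_support = 5,
                                conserved_between = TRUE))
  expect_equal(pred$query_offset, 0L)

  # downstream candidate below threshold: u stands
  pred <- step_c(step_c_fixture(u_support = 3, d_support = 2))
  expect_equal(pred$query_offset, 0L)

  # no candidate above threshold anywhere: declined
  pred <- step_c(step_c_fixture(u_support = 0, d_support = 1))
  expect_equal(pred$step, "none")
  expect_true(is.na(pred$query_offset))
})

test_that("intergenic-distance conservation follows the mode and margin rules", {
  # all distances -4: mode -4, dc = 1 for any margin
  all4 <- intergenic_conservation_dc(rep(-4, 8), f = 0)
  expect_equal(all4$mode_x, -4L)
  expect_equal(all4$dc, 1)
  # mixed distances, f = 3: seven of ten fall in [-7, -1]
  d <- c(-4, -4, -4, -1, -1, 7, 0, -4, -4, 2)
  st <- intergenic_conservation_dc(d, f = 3)
  expect_equal(st$mode_x, -4L)
  expect_equal(st$dc, 0.7)
  # f = 0 collapses dc to the frequency of the mode itself
  expect_equal(intergenic_conservation_dc(d, f = 0)$dc, 0.5)
  # mode ties resolve to smallest |x| then most negative
  expect_equal(intergenic_conservation_dc(c(-4, -4, 1, 1), f = 0)$mode_x, 1L)
  expect_equal(intergenic_conservation_dc(c(-1, -1, 1, 1), f = 0)$mode_x, -1L)
  # dc is non-decreasing in f
  set.seed(13)
  dd <- sample(-10:10, 40, replace = TRUE)
  dcs <- vapply(0:8, function(f) intergenic_conservation_dc(dd, f)$dc, numeric(1))
  expect_true(all(diff(dcs) >= 0))
  expect_true(all(dcs >= 0 & dcs <= 1))
  # oracle agreement on random draws
  for (i in 1:50) {
    dd <- sample(-12:12, sample(5:30, 1), replace = TRUE)
    f <- sample(0:5, 1)
    want <- oracle_dc(dd, f)
    got <- intergenic_conservation_dc(dd, f)
    expect_equal(got$mode_x, want$mode_x)
    expect_equal(got$dc, want$dc)
  }
})

test_that("dispatch records exactly one producing step and valid offsets", {
  cfg <- scoring_config(min_targets = 4)
  # overlap context routes through B
  m <- junk_matrix(5, 8); m[, 3] <- "ATG"
  msa <- msa_from_codon_matrix(m)
  expect_equal(predict_start(msa, upstream_gene_end_offset = 10, cfg)$step, "B")
  # no context: A fires on the Fig. 5-left fixture
  expect_equal(predict_start(step_a_fixture(), cfg = cfg)$step, "A")
  # two upstream candidates: A falls through to C, which declines here
  # because neither candidate has target support
  pred <- predict_start(step_a_fixture(two_candidates = TRUE), cfg = cfg)
  expect_equal(pred$step, "none")
  # multi-candidate family with target support: C selects
  pred <- predict_start(step_c_fixture(u_support = 3, d_support = 5), cfg = cfg)
  expect_equal(pred$step, "C")
  expect_equal(pred$query_offset, 12L)
  # too few targets: declined with a reason
  small <- msa_from_codon_matrix(junk_matrix(3, 8))
  pred <- predict_start(small, cfg = scoring_config(min_targets = 10))
  expect_equal(pred$step, "none")
  expect_equal(pred$reason, "too_few_targets")
  # any predicted offset is a listed candidate of the query
  for (seed in 1:5) {
    fam <- simulate_family(family_spec(n_targets = 12, decoy_upstream_starts = 2,
                                       seed = 400 + seed))
    msa <- build_dual_msa(c(list(fam$query), fam$targets))
    pred <- predict_start(msa, cfg = scoring_config())
    expect_true(pred$step %in% c("A", "B", "C", "none"))
    if (!is.na(pred$query_offset)) {
      expect_true(pred$query_offset %in%
                    list_start_candidates(fam$query)$seq_offset)
    }
  }
})

test_that("tidy and glance expose candidate scores and the chosen start", {
  pred <- step_c(step_c_fixture(u_support = 3, d_support = 5))
  td <- generics::tidy(pred)
  expect_true(all(c("seq_offset", "s5", "n_support", "n_penalty") %in% names(td)))
  expect_equal(nrow(td), 2L)
  gl <- generics::glance(pred)
  expect_equal(gl$step, "C")
  expect_equal(gl$query_offset, pred$query_offset)
  expect_equal(gl$s5, 1)
})
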