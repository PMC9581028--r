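test_that("evolution at rate 0 is the identity and preserves length", {
  s <- "ATGGCTAAACCCGGGTTTTAA"
  expect_identical(evolve_k80(s, 0), s)
  set.seed(1)
  m <- evolve_k80(s, 0.3)
  expect_equal(nchar(m), nchar(s))
})

test_that("observed transition/transversion fractions match the K80 model", {
  set.seed(2718)
  n <- 10000
  anc <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  for (case in list(c(0.2, 2), c(0.4, 0.5), c(0.1, 4))) {
    rate <- case[1]; R <- case[2]
    mut <- evolve_k80(anc, rate, ts_tv_ratio = R)
    st <- transition_transversion_fractions(anc, mut)
    want <- oracle_k80_pq(rate, R)
    se_p <- sqrt(want$P * (1 - want$P) / n)
    se_q <- sqrt(want$Q * (1 - want$Q) / n)
    expect_lt(abs(st$p - want$P), 3 * se_p)
    expect_lt(abs(st$q - want$Q), 3 * se_q)
  }
})

test_that("the distance estimator recovers the simulated rate", {
  set.seed(404)
  n <- 20000
  anc <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  for (i in 1:10) {
    r <- runif(1, 0.05, 0.3)
    d <- startfinder:::pairwise_kimura(anc, evolve_k80(anc, r))
    expect_equal(d, r, tolerance = 0.08)
  }
})

test_that("frame protection keeps truth intact at high rates", {
  set.seed(55)
  fam <- simulate_family(family_spec(n_targets = 15, sub_rate_coding = 0.4,
                                     sub_rate_upstream = 0.7, seed = 99))
  S <- fam$truth$start_offset
  for (t in fam$targets) {
    cods <- startfinder:::codons_of(t$nt)
    # no internal in-frame stop, terminal stop preserved
    expect_false(any(cods[-length(cods)] %in% c("TAA", "TAG", "TGA")))
    expect_true(cods[length(cods)] %in% c("TAA", "TAG", "TGA"))
    # the true start survives as a start-capable codon
    expect_true(substr(t$nt, S + 1, S + 3) %in% c("ATG", "GTG", "TTG"))
  }
})

test_that("families are byte-identical under a fixed seed", {
  spec <- family_spec(n_targets = 20, decoy_upstream_starts = 2,
                      overlap_mode = "minus4", overlap_jitter_sd = 1, seed = 7)
  f1 <- simulate_family(spec)
  f2 <- simulate_family(spec)
  expect_identical(f1$query$nt, f2$query$nt)
  expect_identical(purrr::map_chr(f1$targets, "nt"),
                   purrr::map_chr(f2$targets, "nt"))
  expect_identical(f1$truth, f2$truth)
  # a different seed gives a different family
  f3 <- simulate_family(family_spec(n_targets = 20, decoy_upstream_starts = 2,
                                    overlap_mode = "minus4",
                                    overlap_jitter_sd = 1, seed = 8))
  expect_false(identical(f1$query$nt, f3$query$nt))
})

test_that("realized query-target distances respect the declared interval", {
  set.seed(1)
  frac_in <- vapply(1:100, function(i) {
    fam <- simulate_family(family_spec(n_targets = 10, coding_len_aa = 100,
                                       seed = 5000 + i))
    d <- fam$truth$targets$kimura_to_query
    mean(d >= 0.1 - 0.05 & d <= 0.5 + 0.05)
  }, numeric(1))
  expect_gte(mean(frac_in), 0.95)
})

test_that("decoys and overlap context are planted as requested", {
  fam <- simulate_family(family_spec(decoy_upstream_starts = 2, seed = 21))
  cand <- list_start_candidates(fam$query)
  expect_gte(nrow(cand), 3L)
  expect_true(all(fam$truth$decoy_offsets %in% cand$seq_offset))
  expect_true(all(fam$truth$decoy_offsets < fam$truth$start_offset))

  # -4 overlap: upstream gene 3' end 4 nt downstream of the true start,
  # sequence context ATGA, and D(n) centred on -4
  f4 <- simulate_family(family_spec(overlap_mode = "minus4",
                                    overlap_jitter_sd = 1, seed = 22))
  S <- f4$truth$start_offset
  expect_equal(f4$truth$d_query, -4L)
  expect_equal(f4$query$upstream_gene_end_offset, S + 4L)
  expect_equal(substr(f4$query$nt, S + 1, S + 4), "ATGA")
  expect_true(all((f4$truth$targets$d_n - (-4)) %% 3 == 0))
  st <- intergenic_conservation_dc(f4$truth$targets$d_n, f = 3)
  expect_equal(st$mode_x, -4L)
  expect_gte(st$dc, 0.9)

  # -1 overlap: stop TGA straddles the start (…TGATG…)
  f1 <- simulate_family(family_spec(overlap_mode = "minus1", seed = 23))
  S1 <- f1$truth$start_offset
  expect_equal(f1$truth$d_query, -1L)
  expect_equal(substr(f1$query$nt, S1 - 1, S1 + 3), "TGATG")
})

test_that("fixture bundles round-trip through disk", {
  dir <- file.path(tempdir(), "bundle_test")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  fam <- simulate_family(family_spec(n_targets = 12, decoy_upstream_starts = 1,
                                     overlap_mode = "minus4", seed = 31))
  write_fixture_bundle(fam, dir)
  b <- read_fixture_bundle(dir)
  expect_identical(b$query$nt, fam$query$nt)
  expect_identical(purrr::map_chr(b$targets, "nt"),
                   purrr::map_chr(fam$targets, "nt"))
  expect_identical(b$relations$aln_target, fam$relations$aln_target)
  expect_equal(b$query$gene_start_offset, fam$truth$start_offset)
  # truth GFF3 carries the 1-based true start on the query LORF
  expect_equal(b$truth_calls$start, fam$truth$start_offset + 1L)
  expect_equal(b$truth_calls$end, fam$truth$lorf_length)
  # the bundle is directly consumable by the pipeline
  res <- run_prediction_bundle(dir)
  expect_s3_class(res$prediction, "start_prediction")
})

test_that("infeasible specs are rejected with a reason", {
  expect_error(simulate_family(family_spec(upstream_len_nt = 6,
                                           decoy_upstream_starts = 5,
                                           seed = 1)),
               "too short")
  expect_error(family_spec(sub_rate_coding = 0.8), "sub_rate_coding")
})
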