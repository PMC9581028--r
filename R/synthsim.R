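ALL_CODONS <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                    paste0), c("A", "C", "G", "T"), paste0))
# upstream codon pool: no stops (would truncate the LORF) and no start codons
# (query candidates must be exactly the true start plus planted decoys)
SAFE_CODONS <- setdiff(ALL_CODONS, c(STOP_CODONS, START_CODONS))

#' Specification of a synthetic homologous LORF family
#'
#' Families are generated by star-topology evolution from an ancestral query
#' under the Kimura two-parameter substitution model, with a faster-evolving
#' upstream region (conservation contrast), optional planted decoy start
#' codons upstream of the true start, and optional upstream-gene overlap
#' configurations (-4 / -1 nt, the configurations favored at operon
#' junctions).
#'
#' Per-target substitution rates are drawn as `Uniform(0.5, 1.5) *
#' sub_rate_coding` so that realized query-target Kimura distances span the
#' informative selection window; the upstream rate scales with the same
#' per-target factor and is capped at 0.745 (the K2P estimator's domain).
#'
#' @param n_targets Number of target sequences (default 20).
#' @param coding_len_aa Gene length in codons, start codon included, stop
#'   excluded (default 100).
#' @param upstream_len_nt Length of the LORF upstream of the true start, a
#'   multiple of 3 (default 60).
#' @param sub_rate_coding Mean expected substitutions/site on the gene side
#'   (default 0.24).
#' @param sub_rate_upstream Mean rate upstream of the true start (default
#'   0.72, i.e. a 3x conservation contrast).
#' @param ts_tv_ratio Transition/transversion rate ratio (default 2).
#' @param decoy_upstream_starts Number of in-frame ATG/GTG/TTG codons planted
#'   upstream of the true start (default 0).
#' @param overlap_mode `"none"`, `"minus4"`, `"minus1"`, or an integer custom
#'   intergenic distance (negative = overlap; annotation only).
#' @param overlap_jitter_sd Standard deviation (nt) of the per-target,
#'   frame-preserving (multiple of 3) jitter applied to the annotated
#'   upstream-gene 3' end (default 0).
#' @param target_distance_range Interval the realized query-target Kimura
#'   distance (over the gene region) must fall in; targets outside it are
#'   re-drawn a bounded number of times (default `c(0.1, 0.5)`).
#' @param seed Integer seed; families are byte-reproducible under it.
#' @return An object of class `family_spec`.
#' @export
family_spec <- function(n_targets = 20L,
                        coding_len_aa = 100L,
                        upstream_len_nt = 60L,
                        sub_rate_coding = 0.24,
                        sub_rate_upstream = 0.72,
                        ts_tv_ratio = 2,
                        decoy_upstream_starts = 0L,
                        overlap_mode = "none",
                        overlap_jitter_sd = 0,
                        target_distance_range = c(0.1, 0.5),
                        seed = 1L) {
  spec <- list(
    n_targets = as.integer(n_targets),
    coding_len_aa = as.integer(coding_len_aa),
    upstream_len_nt = as.integer(upstream_len_nt),
    sub_rate_coding = sub_rate_coding,
    sub_rate_upstream = sub_rate_upstream,
    ts_tv_ratio = ts_tv_ratio,
    decoy_upstream_starts = as.integer(decoy_upstream_starts),
    overlap_mode = overlap_mode,
    overlap_jitter_sd = overlap_jitter_sd,
    target_distance_range = target_distance_range,
    seed = as.integer(seed)
  )
  stopifnot(
    spec$n_targets >= 1L,
    spec$coding_len_aa >= 12L,
    spec$upstream_len_nt %% 3L == 0L, spec$upstream_len_nt >= 0L,
    spec$sub_rate_coding > 0, spec$sub_rate_coding < 0.75,
    spec$sub_rate_upstream > 0, spec$sub_rate_upstream < 0.75,
    spec$ts_tv_ratio > 0,
    spec$decoy_upstream_starts >= 0L,
    spec$overlap_jitter_sd >= 0
  )
  if (is.character(spec$overlap_mode))
    spec$overlap_mode <- match.arg(spec$overlap_mode, c("none", "minus4", "minus1"))
  structure(spec, class = "family_spec")
}

# K80 per-site change probabilities after expected distance d with ts/tv rate
# ratio R: transition rate a = dR/(R+2), each transversion rate b = d/(R+2).
k80_change_probs <- function(rate, ts_tv_ratio) {
  a <- rate * ts_tv_ratio / (ts_tv_ratio + 2)
  b <- rate / (ts_tv_ratio + 2)
  list(
    ts = 0.25 + 0.25 * exp(-4 * b) - 0.5 * exp(-2 * (a + b)),
    tv = 0.5 - 0.5 * exp(-4 * b) # both transversion targets together
  )
}

TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSION_1 <- c(A = "C", G = "C", C = "A", T = "A")
TRANSVERSION_2 <- c(A = "T", G = "T", C = "G", T = "G")

mutate_sites <- function(chars, rate, ts_tv_ratio) {
  pr <- k80_change_probs(rate, ts_tv_ratio)
  u <- runif(length(chars))
  out <- chars
  is_ts <- u < pr$ts
  is_tv <- !is_ts & u < pr$ts + pr$tv
  if (any(is_ts)) out[is_ts] <- TRANSITION_OF[chars[is_ts]]
  if (any(is_tv)) {
    pick <- runif(sum(is_tv)) < 0.5
    out[is_tv] <- ifelse(pick, TRANSVERSION_1[chars[is_tv]],
                         TRANSVERSION_2[chars[is_tv]])
  }
  out
}

#' Evolve a sequence under the Kimura two-parameter model
#'
#' Sites mutate independently; the per-site probabilities of observing a
#' transition or a transversion are the exact K80 transition probabilities for
#' the requested expected distance, so the K2P distance estimator applied to
#' (ancestor, descendant) is consistent for `rate`. No indels are introduced.
#'
#' With `protect_frame = TRUE` the sequence is treated as a frame-0 LORF:
#' codons that would become an in-frame stop (anywhere before the final
#' codon), a non-stop final codon (when the ancestor ends in a stop), or a
#' non-start codon at `protect_start_offset`, are re-drawn from the ancestral
#' codon (up to 100 attempts, then reverted), preserving the ground truth.
#'
#' @param seq Nucleotide string (A/C/G/T).
#' @param rate Expected substitutions per site; a scalar or a per-site vector,
#'   each element in `[0, 0.75)`.
#' @param ts_tv_ratio Transition/transversion rate ratio (default 2).
#' @param protect_frame Apply frame-0 stop/start protection (default FALSE).
#' @param protect_start_offset Optional 0-based frame-0 offset whose codon
#'   must remain ATG/GTG/TTG.
#' @return The mutated sequence (same length).
#' @export
evolve_k80 <- function(seq, rate, ts_tv_ratio = 2, protect_frame = FALSE,
                       protect_start_offset = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "")[[1]]
  stopifnot(all(chars %in% c("A", "C", "G", "T")))
  n <- length(chars)
  rate <- rep_len(rate, n)
  stopifnot(all(rate >= 0), all(rate < 0.75))
  out <- chars
  for (r in unique(rate)) {
    idx <- which(rate == r)
    if (r > 0) out[idx] <- mutate_sites(chars[idx], r, ts_tv_ratio)
  }
  if (!protect_frame && is.null(protect_start_offset)) {
    return(paste(out, collapse = ""))
  }
  stopifnot(n %% 3L == 0L)
  n_cod <- n %/% 3L
  anc_last_is_stop <- paste(chars[(n - 2L):n], collapse = "") %in% STOP_CODONS
  codon_ok <- function(k, codon) {
    if (!is.null(protect_start_offset) && (k - 1L) * 3L == protect_start_offset)
      return(codon %in% START_CODONS)
    if (!protect_frame) return(TRUE)
    if (k == n_cod) return(!anc_last_is_stop || codon %in% STOP_CODONS)
    !codon %in% STOP_CODONS
  }
  for (k in seq_len(n_cod)) {
    pos <- (3L * (k - 1L) + 1L):(3L * k)
    codon <- paste(out[pos], collapse = "")
    if (codon_ok(k, codon)) next
    anc <- chars[pos]
    ok <- FALSE
    for (try in seq_len(100L)) {
      prop <- mutate_sites(anc, mean(rate[pos]), ts_tv_ratio)
      if (codon_ok(k, paste(prop, collapse = ""))) {
        out[pos] <- prop; ok <- TRUE; break
      }
    }
    if (!ok) out[pos] <- anc
  }
  paste(out, collapse = "")
}

sample_codons <- function(n, pool) {
  if (n == 0L) return(character(0))
  sample(pool, n, replace = TRUE)
}

#' Simulate a homologous LORF family with a known true start
#'
#' Builds an ancestral LORF `[upstream | true start | gene body | stop]`,
#' plants decoy candidates and overlap context as requested, then evolves each
#' target independently (star topology) with frame and truth protection. The
#' query is the ancestor, so its candidate set is exactly the true start plus
#' the planted decoys. The first ten codons of the gene body contain no
#' in-frame start codon, so the benchmark probes upstream-candidate
#' discrimination rather than tandem-start ambiguity (see the methods
#' vignette).
#'
#' @param spec A [family_spec()].
#' @return An object of class `lorf_family`: `spec`, `query` and `targets`
#'   ([lorf_record()]s), `relations` (pairwise gene-region alignments for
#'   [select_targets()]), `gold_aa` (colinear protein alignment rows),
#'   and `truth` (true start offset, decoy offsets, per-target rates, realized
#'   distances and intergenic distances `D(n)`).
#' @export
simulate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  rng <- local_rng(spec$seed)
  on.exit(restore_rng(rng), add = TRUE)

  S <- spec$upstream_len_nt
  n_up <- S %/% 3L
  overlap <- spec$overlap_mode

  # decoys need free upstream codon slots (minus1 reserves the final slot)
  reserved <- if (identical(overlap, "minus1")) n_up else integer(0)
  free_slots <- setdiff(seq_len(n_up), reserved)
  if (spec$decoy_upstream_starts > length(free_slots))
    stop("simulate_family: upstream region too short for the requested decoys")

  up <- sample_codons(n_up, SAFE_CODONS)
  if (identical(overlap, "minus1")) up[n_up] <- "CTG" # ...TG|ATG -1 overlap
  decoy_slots <- sort(sample(free_slots, spec$decoy_upstream_starts))
  up[decoy_slots] <- sample(START_CODONS, spec$decoy_upstream_starts, replace = TRUE)

  start_codon <- if (identical(overlap, "minus4") || identical(overlap, "minus1"))
    "ATG" else sample(START_CODONS, 1, prob = c(0.80, 0.15, 0.05))

  n_body <- spec$coding_len_aa - 1L
  body_pool_early <- SAFE_CODONS
  body_pool_late <- setdiff(ALL_CODONS, STOP_CODONS)
  n_early <- min(10L, n_body)
  body <- c(sample_codons(n_early, body_pool_early),
            sample_codons(n_body - n_early, body_pool_late))
  if (identical(overlap, "minus4")) {
    # -4 overlap needs ...A TGA... i.e. nt[S..S+3] == "ATGA": first body codon
    # starts with A (and is itself neither stop nor start by pool choice)
    pool_a <- grep("^A", body_pool_early, value = TRUE)
    body[1] <- sample(pool_a, 1)
  }
  stop_codon <- sample(STOP_CODONS, 1)

  anc <- paste(c(up, start_codon, body, stop_codon), collapse = "")
  L <- nchar(anc)

  up_end <- switch(
    as.character(overlap),
    none = NA_integer_,
    minus4 = S + 4L,
    minus1 = S + 1L,
    S - as.integer(overlap) # custom integer intergenic distance
  )

  d_query <- if (is.na(up_end)) NA_integer_ else S - up_end

  query <- lorf_record("query", anc, gene_start_offset = S,
                       upstream_gene_end_offset = if (is.na(up_end)) NULL else up_end,
                       source = "simulate_family")

  gene_region <- function(nt) substr(nt, S + 1L, L)
  q_gene <- gene_region(anc)

  targets <- vector("list", spec$n_targets)
  truth_rows <- vector("list", spec$n_targets)
  rel_rows <- vector("list", spec$n_targets)
  rate_vec <- numeric(L)

  for (t in seq_len(spec$n_targets)) {
    res <- NULL
    for (try in seq_len(20L)) {
      mult <- runif(1, 0.5, 1.5)
      r_c <- min(mult * spec$sub_rate_coding, 0.745)
      r_u <- min(mult * spec$sub_rate_upstream, 0.745)
      rate_vec[] <- r_c
      if (S > 0) rate_vec[seq_len(S)] <- r_u
      mut <- evolve_k80(anc, rate_vec, spec$ts_tv_ratio,
                        protect_frame = TRUE, protect_start_offset = S)
      d_real <- pairwise_kimura(q_gene, gene_region(mut))
      if (!is.na(d_real) &&
          d_real >= spec$target_distance_range[1] &&
          d_real <= spec$target_distance_range[2]) {
        res <- list(mut = mut, r_c = r_c, r_u = r_u, d_real = d_real)
        break
      }
      if (is.null(res) && try == 20L)
        res <- list(mut = mut, r_c = r_c, r_u = r_u, d_real = d_real)
    }
    jit <- if (spec$overlap_jitter_sd > 0)
      3L * as.integer(round(rnorm(1, 0, spec$overlap_jitter_sd) / 3)) else 0L
    d_n <- if (is.na(d_query)) NA_integer_ else d_query + jit
    t_up_end <- if (is.na(d_n)) NULL else S - d_n
    id <- sprintf("t%02d", t)
    targets[[t]] <- lorf_record(id, res$mut, gene_start_offset = S,
                                upstream_gene_end_offset = t_up_end,
                                source = "simulate_family")
    truth_rows[[t]] <- tibble(
      target_id = id, rate_coding = res$r_c, rate_upstream = res$r_u,
      kimura_to_query = res$d_real, d_n = d_n
    )
    rel_rows[[t]] <- tibble(
      target_id = id,
      aln_query = q_gene,
      aln_target = gene_region(res$mut),
      coverage_query = 1, coverage_target = 1
    )
  }

  records <- c(list(query), targets)
  gold_aa <- setNames(purrr::map_chr(records, "aa"),
                      purrr::map_chr(records, "id"))

  structure(
    list(
      spec = spec,
      query = query,
      targets = targets,
      relations = bind_rows(rel_rows),
      gold_aa = gold_aa,
      truth = list(
        start_offset = S,
        start_codon = start_codon,
        decoy_offsets = (decoy_slots - 1L) * 3L,
        upstream_gene_end_offset = up_end,
        d_query = d_query,
        lorf_length = L,
        targets = bind_rows(truth_rows)
      )
    ),
    class = "lorf_family"
  )
}

#' @export
print.lorf_family <- function(x, ...) {
  cat(sprintf("<lorf_family> %d targets, LORF %d nt, true start at %d (%s), %d decoys\n",
              length(x$targets), x$truth$lorf_length, x$truth$start_offset,
              x$truth$start_codon, length(x$truth$decoy_offsets)))
  invisible(x)
}

#' Write a family as an on-disk fixture bundle
#'
#' Emits plain-text files directly consumable by the prediction pipeline:
#' `query.fasta`, `targets.fasta`, `aligned_aa.fasta` / `aligned_nt.fasta`
#' (gold dual-layer alignment), `relations.tsv` (pairwise gene-region
#' alignments + coverages), `meta.tsv` (per-record offsets and truth), and
#' `truth.gff3` (the true gene coordinates on the query LORF, 1-based).
#'
#' @param family A `lorf_family`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_fixture_bundle <- function(family, dir) {
  stopifnot(inherits(family, "lorf_family"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(...) file.path(dir, ...)

  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(family$query$nt, family$query$id)),
    f("query.fasta"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(purrr::map_chr(family$targets, "nt"),
                                      purrr::map_chr(family$targets, "id"))),
    f("targets.fasta"))

  dmsa <- build_dual_msa(c(list(family$query), family$targets),
                         aligner = aligner_gold(family$gold_aa))
  write_dual_msa(dmsa, f("aligned_aa.fasta"), f("aligned_nt.fasta"))

  write.table(family$relations, f("relations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  recs <- c(list(family$query), family$targets)
  meta <- purrr::map_dfr(recs, function(r) tibble(
    id = r$id,
    role = if (r$id == family$query$id) "query" else "target",
    gene_start_offset = r$gene_start_offset,
    upstream_gene_end_offset = r$upstream_gene_end_offset
  ))
  meta <- left_join(meta, family$truth$targets,
                    by = c(id = "target_id"))
  write.table(meta, f("meta.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  truth_call <- gene_calls(
    seq_id = family$query$id, strand = "+",
    start = family$truth$start_offset + 1L,
    end = family$truth$lorf_length
  )
  write_gene_calls_gff3(truth_call, f("truth.gff3"), source = "simulate_family")
  invisible(dir)
}

#' Read a fixture bundle back into memory
#'
#' @param dir Directory written by [write_fixture_bundle()].
#' @return A list with `query`, `targets`, `relations`, `gold_aa`, `meta`,
#'   `truth_calls` mirroring the in-memory family.
#' @export
read_fixture_bundle <- function(dir) {
  f <- function(...) file.path(dir, ...)
  meta <- as_tibble(read.delim(f("meta.tsv"), sep = "\t",
                               stringsAsFactors = FALSE))
  qs <- Biostrings::readDNAStringSet(f("query.fasta"))
  ts <- Biostrings::readDNAStringSet(f("targets.fasta"))
  if (anyDuplicated(c(names(qs), names(ts))))
    stop("read_fixture_bundle: sequence ids are not unique")
  mk <- function(id, nt) {
    m <- meta[meta$id == id, ]
    lorf_record(
      id, nt,
      gene_start_offset = if (nrow(m) && !is.na(m$gene_start_offset))
        m$gene_start_offset else NULL,
      upstream_gene_end_offset = if (nrow(m) && !is.na(m$upstream_gene_end_offset))
        m$upstream_gene_end_offset else NULL,
      source = dir
    )
  }
  query <- mk(names(qs)[1], as.character(qs[[1]]))
  targets <- purrr::map(seq_along(ts),
                        function(i) mk(names(ts)[i], as.character(ts[[i]])))
  aa <- Biostrings::readBStringSet(f("aligned_aa.fasta"))
  gold_aa <- setNames(as.character(aa), names(aa))
  list(
    query = query,
    targets = targets,
    relations = as_tibble(read.delim(f("relations.tsv"), sep = "\t",
                                     stringsAsFactors = FALSE)),
    gold_aa = gold_aa,
    meta = meta,
    truth_calls = read_gene_calls_gff3(f("truth.gff3"))
  )
}
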