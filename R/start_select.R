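# Number of ordered row pairs (m != n) sharing the same non-gap residue, per
# amino-acid column. Residues rendered as X (ambiguity) never match.
column_match_counts <- function(msa) {
  apply(msa$aa_mat, 2, function(col) {
    col <- col[!is.na(col) & col != "X"]
    if (length(col) < 2L) return(0)
    tab <- table(col)
    sum(tab * (tab - 1))
  })
}

blk_denominator <- function(r, n, blk_norm) {
  if (blk_norm == "printed") r * (n - 1)^2 else r * n * (n - 1)
}

# The r query-ungapped aa columns at/after aa_col, or NULL if fewer remain.
block_columns <- function(msa, aa_col, r) {
  qrow <- msa$aa_mat[msa$query_index, ]
  cols <- which(!is.na(qrow))
  cols <- cols[cols >= aa_col]
  if (length(cols) < r) return(NULL)
  cols[seq_len(r)]
}

#' Block conservation (identity) score
#'
#' Over the `r` query-ungapped amino-acid columns at/after `aa_col`, sums
#' matches over ordered row pairs and normalizes by `r * (N-1)^2` (the
#' published form; maximum about `N/(N-1)`) or by `r * N * (N-1)` when
#' `cfg$blk_norm = "pair_count"`. A block is conserved when the score strictly
#' exceeds `cfg$t_blk`.
#'
#' @param msa A `dual_msa`.
#' @param aa_col 1-based amino-acid column at which the block starts.
#' @param r Block length in amino acids (default `cfg$block_len_aa`).
#' @param cfg A [scoring_config()].
#' @return One-row tibble (`aa_col`, `r`, `score`, `conserved`), or a zero-row
#'   tibble when fewer than `r` query-ungapped columns remain.
#' @export
block_conservation_score <- function(msa, aa_col, r = NULL, cfg = scoring_config()) {
  stopifnot(inherits(msa, "dual_msa"))
  if (is.null(r)) r <- cfg$block_len_aa
  cols <- block_columns(msa, aa_col, r)
  if (is.null(cols)) {
    return(tibble(aa_col = integer(), r = integer(),
                  score = double(), conserved = logical()))
  }
  cm <- column_match_counts(msa)
  s <- sum(cm[cols]) / blk_denominator(r, msa$n, cfg$blk_norm)
  tibble(aa_col = as.integer(aa_col), r = as.integer(r),
         score = s, conserved = s > cfg$t_blk)
}

#' Left-most conserved block of the alignment
#'
#' Scans amino-acid columns left to right, starting from the first
#' query-ungapped column, and returns the first block of length
#' `cfg$block_len_aa` whose identity score exceeds `cfg$t_blk`.
#'
#' Because blocks are used to separate start candidates, a "possible
#' N-terminal" — any query start-candidate column — is never part of a
#' block's `r` scored positions. The reported boundary is the first column of
#' the qualifying window that is itself conserved (per-column identity above
#' the threshold; a window whose average exceeds the threshold always contains
#' one): a conserved block cannot begin on an unconserved column, and without
#' this rule the window average lets the boundary overshoot one or two
#' columns upstream of the actual conserved run, which matters when counting
#' candidates upstream of the block.
#'
#' @param msa A `dual_msa`.
#' @param cfg A [scoring_config()].
#' @param from_col Scan start column (default 1).
#' @return One-row tibble as in [block_conservation_score()], or `NULL` when
#'   no column qualifies.
#' @export
find_leftmost_conserved_block <- function(msa, cfg = scoring_config(), from_col = 1L) {
  stopifnot(inherits(msa, "dual_msa"))
  r <- cfg$block_len_aa
  qcols <- which(!is.na(msa$aa_mat[msa$query_index, ]))
  qcols <- qcols[qcols >= from_col & !qcols %in% msa$query_candidates$aa_col]
  if (length(qcols) < r) return(NULL)
  cm <- column_match_counts(msa)
  denom <- blk_denominator(r, msa$n, cfg$blk_norm)
  run <- cm[qcols]
  # rolling sum of r consecutive scored (query-ungapped, non-candidate) columns
  cs <- cumsum(run)
  starts <- seq_len(length(qcols) - r + 1L)
  scores <- (cs[starts + r - 1L] - c(0, cs)[starts]) / denom
  hit <- which(scores > cfg$t_blk)
  if (!length(hit)) return(NULL)
  i <- hit[[1]]
  # boundary: first member column that is conserved on its own
  members <- qcols[i:(i + r - 1L)]
  col_ok <- cm[members] / blk_denominator(1L, msa$n, cfg$blk_norm) > cfg$t_blk
  start_col <- members[which(col_ok)[1]]
  tibble(aa_col = start_col, r = as.integer(r),
         score = scores[i], conserved = TRUE)
}

# Does a conserved block of any length 1..r lie strictly between two query
# candidate columns? Block columns must be query-ungapped, fall strictly
# inside (lo_col, hi_col), and never include a candidate column itself.
conserved_block_between <- function(msa, lo_col, hi_col, cfg) {
  r_max <- cfg$block_len_aa
  qrow <- msa$aa_mat[msa$query_index, ]
  cand_cols <- msa$query_candidates$aa_col
  cols <- which(!is.na(qrow))
  cols <- cols[cols > lo_col & cols < hi_col & !cols %in% cand_cols]
  if (!length(cols)) return(FALSE)
  cm <- column_match_counts(msa)
  vals <- cm[cols]
  for (l in seq_len(min(r_max, length(cols)))) {
    denom <- blk_denominator(l, msa$n, cfg$blk_norm)
    if (length(vals) < l) break
    cs <- cumsum(vals)
    starts <- seq_len(length(vals) - l + 1L)
    # blocks must be runs of consecutive eligible columns
    contiguous <- cols[starts + l - 1L] - cols[starts] == l - 1L
    sc <- (cs[starts + l - 1L] - c(0, cs)[starts]) / denom
    if (any(contiguous & sc > cfg$t_blk)) return(TRUE)
  }
  FALSE
}

#' Candidate conservation score S5'
#'
#' For one query start-codon candidate, computes over the target rows (query
#' excluded, `N` = number of targets): support `G = 1` when at least one
#' ATG/GTG/TTG occurs among the row's codons within `cfg$neigh_codons` codon
#' columns of the candidate column; penalty `P = 1` when the row's codon at
#' the candidate column encodes valine or leucine via a non-start codon.
#' `s5 = sum(G - P) / N`. Rows whose window is all gaps contribute 0 to both.
#'
#' @param msa A `dual_msa`.
#' @param candidate One row of `msa$query_candidates` (or a list with
#'   `seq_offset`, `aa_col`, `nt_col`, `codon`).
#' @param cfg A [scoring_config()].
#' @return One-row tibble: `seq_offset`, `codon`, `aa_col`, `s5`,
#'   `n_support`, `n_penalty`.
#' @export
candidate_score_s5 <- function(msa, candidate, cfg = scoring_config()) {
  stopifnot(inherits(msa, "dual_msa"))
  a <- as.integer(candidate$aa_col)
  stopifnot(!is.na(a), a >= 1L, a <= msa$L)
  targets <- setdiff(seq_len(msa$n), msa$query_index)
  n_t <- length(targets)
  win <- column_window(msa, 3L * (a - 1L) + 1L, 3L * cfg$neigh_codons)
  g <- vapply(targets, function(i) any(win[[i]] %in% START_CODONS), logical(1))
  at_col <- msa$codon_mat[targets, a]
  p <- !is.na(at_col) & at_col %in% NONSTART_VL_CODONS
  tibble(
    seq_offset = as.integer(candidate$seq_offset),
    codon = as.character(candidate$codon),
    aa_col = a,
    s5 = if (n_t > 0) (sum(g) - sum(p)) / n_t else NA_real_,
    n_support = sum(g),
    n_penalty = sum(p)
  )
}

score_all_candidates <- function(msa, cfg) {
  cand <- msa$query_candidates
  if (!nrow(cand)) {
    return(tibble(seq_offset = integer(), codon = character(),
                  aa_col = integer(), s5 = double(),
                  n_support = integer(), n_penalty = integer()))
  }
  purrr::map_dfr(seq_len(nrow(cand)), function(i)
    candidate_score_s5(msa, cand[i, ], cfg))
}

new_prediction <- function(msa, step, offset = NA_integer_, codon = NA_character_,
                           scores = NULL, block = NULL, reason = NA_character_) {
  structure(
    list(
      query_id = msa$ids[msa$query_index],
      query_offset = as.integer(offset),
      codon = codon,
      step = step,
      n_targets = msa$n - 1L,
      scores = scores,
      block = block,
      reason = reason
    ),
    class = "start_prediction"
  )
}

#' @export
print.start_prediction <- function(x, ...) {
  if (x$step == "none") {
    cat(sprintf("<start_prediction> %s: no start selected (%s)\n",
                x$query_id, x$reason))
  } else {
    cat(sprintf("<start_prediction> %s: offset %d (%s), step %s, %d targets\n",
                x$query_id, x$query_offset, x$codon, x$step, x$n_targets))
  }
  invisible(x)
}

#' Step A: single candidate upstream of the left-most conserved block
#'
#' If a left-most conserved block exists and exactly one query start candidate
#' lies strictly upstream of the block's first column, that candidate is the
#' prediction. The candidate itself need not be conserved. With zero or two or
#' more upstream candidates the step falls through (`NULL`).
#'
#' @param msa A `dual_msa`.
#' @param cfg A [scoring_config()].
#' @return A `start_prediction` with `step = "A"`, or `NULL`.
#' @export
step_a <- function(msa, cfg = scoring_config()) {
  blk <- find_leftmost_conserved_block(msa, cfg)
  if (is.null(blk)) return(NULL)
  cand <- msa$query_candidates
  up <- cand[!is.na(cand$aa_col) & cand$aa_col < blk$aa_col, ]
  if (nrow(up) != 1L) return(NULL)
  new_prediction(msa, "A", up$seq_offset, up$codon, block = blk)
}

#' Step B: overlap-aware candidate selection near an upstream gene 3' end
#'
#' Evaluates every query candidate whose start lies within
#' `cfg$overlap_window_nt` of the upstream gene's 3' end and predicts the
#' best-scoring one if its S5' exceeds `cfg$t_5prime` (ties resolve to the
#' most upstream candidate). Falls through otherwise, or when no context is
#' supplied.
#'
#' @param msa A `dual_msa`.
#' @param upstream_gene_end_offset 0-based exclusive 3'-end offset of the
#'   nearest same-strand upstream gene, relative to the query LORF start
#'   (negative values lie upstream of the LORF).
#' @param cfg A [scoring_config()].
#' @return A `start_prediction` with `step = "B"`, or `NULL`.
#' @export
step_b <- function(msa, upstream_gene_end_offset, cfg = scoring_config()) {
  if (is.null(upstream_gene_end_offset) || is.na(upstream_gene_end_offset))
    return(NULL)
  cand <- msa$query_candidates
  if (!nrow(cand)) return(NULL)
  near <- abs(cand$seq_offset - upstream_gene_end_offset) <= cfg$overlap_window_nt
  cand <- cand[near, ]
  if (!nrow(cand)) return(NULL)
  sc <- purrr::map_dfr(seq_len(nrow(cand)), function(i)
    candidate_score_s5(msa, cand[i, ], cfg))
  best <- sc |> arrange(dplyr::desc(.data$s5), .data$seq_offset) |> head(1)
  if (best$s5 <= cfg$t_5prime) return(NULL)
  new_prediction(msa, "B", best$seq_offset, best$codon, scores = sc)
}

#' Step C: screened candidate selection with downstream re-check
#'
#' C-1 scans the query candidates 5' to 3' for the first one whose S5' score
#' exceeds `cfg$t_5prime` (the provisional candidate `u`; if none exists the
#' prediction is declined). C-2 then looks at candidates within
#' `cfg$downstream_recheck_nt` nt downstream of `u`; among them the one with
#' the highest score, `d`, replaces `u` if its score exceeds the threshold and
#' no conserved block (any start column, any length up to `cfg$block_len_aa`)
#' lies strictly between the two candidates; with such a block, or with no
#' qualifying `d`, the prediction is `u`.
#'
#' @param msa A `dual_msa`.
#' @param cfg A [scoring_config()].
#' @return A `start_prediction` with `step = "C"` (or `step = "none"` when no
#'   candidate passes C-1).
#' @export
step_c <- function(msa, cfg = scoring_config()) {
  sc <- score_all_candidates(msa, cfg)
  if (!nrow(sc))
    return(new_prediction(msa, "none", reason = "no_candidates"))
  sc <- arrange(sc, .data$seq_offset)
  pass <- which(sc$s5 > cfg$t_5prime)
  if (!length(pass))
    return(new_prediction(msa, "none", reason = "no_candidate_above_threshold"))
  u <- sc[pass[[1]], ]
  down <- sc[sc$seq_offset > u$seq_offset &
             sc$seq_offset - u$seq_offset <= cfg$downstream_recheck_nt, ]
  if (!nrow(down))
    return(new_prediction(msa, "C", u$seq_offset, u$codon, scores = sc))
  d <- down |> arrange(dplyr::desc(.data$s5), .data$seq_offset) |> head(1)
  if (d$s5 > cfg$t_5prime &&
      !conserved_block_between(msa, u$aa_col, d$aa_col, cfg)) {
    return(new_prediction(msa, "C", d$seq_offset, d$codon, scores = sc))
  }
  new_prediction(msa, "C", u$seq_offset, u$codon, scores = sc)
}

#' Conservation of the intergenic distance within a component
#'
#' Given per-sequence signed distances `D(n)` from the upstream gene's 3' end
#' to the gene start (negative = overlap), finds the modal distance `x` (ties
#' resolve to the smallest absolute value, then the most negative) and the
#' fraction of sequences whose distance falls within `x - f .. x + f`.
#'
#' @param distances Integer vector of signed intergenic distances.
#' @param f Margin in nucleotides (default 3).
#' @return An object of class `overlap_stats`: a one-row tibble with `n`,
#'   `mode_x`, `f`, `dc`, carrying the distances as attribute `distances`.
#' @examples
#' intergenic_conservation_dc(c(-4, -4, -4, -1, 7), f = 3)
#' @export
intergenic_conservation_dc <- function(distances, f = 3L) {
  stopifnot(length(distances) >= 1L, is.numeric(distances))
  distances <- as.integer(distances)
  tab <- table(distances)
  vals <- as.integer(names(tab))
  best <- max(tab)
  tied <- vals[tab == best]
  mode_x <- tied[order(abs(tied), tied)][1]
  dc <- mean(distances >= mode_x - f & distances <= mode_x + f)
  out <- tibble(n = length(distances), mode_x = mode_x,
                f = as.integer(f), dc = dc)
  attr(out, "distances") <- distances
  class(out) <- c("overlap_stats", class(out))
  out
}

#' Predict the gene start of a query from its dual-layer alignment
#'
#' Dispatches the three selection steps: with upstream-gene context indicating
#' an overlap or near-abutment (3' end downstream of, or within
#' `cfg$overlap_trigger_nt` nt upstream of, the LORF 5' end), step B is tried
#' before step C; otherwise step A is tried before step C. With fewer than
#' `cfg$min_targets` targets the prediction is declined.
#'
#' @param msa A `dual_msa`.
#' @param upstream_gene_end_offset Optional upstream-gene 3'-end offset as in
#'   [step_b()]; `NULL`/`NA` means no context.
#' @param cfg A [scoring_config()].
#' @return A `start_prediction`; `step` is one of `"A"`, `"B"`, `"C"`,
#'   `"none"`. Use [tidy()] for per-candidate scores and [glance()] for a
#'   one-row summary.
#' @export
predict_start <- function(msa, upstream_gene_end_offset = NULL,
                          cfg = scoring_config()) {
  stopifnot(inherits(msa, "dual_msa"))
  if (msa$n - 1L < cfg$min_targets)
    return(new_prediction(msa, "none", reason = "too_few_targets"))
  has_context <- !is.null(upstream_gene_end_offset) &&
    !is.na(upstream_gene_end_offset)
  overlapish <- has_context &&
    upstream_gene_end_offset >= -cfg$overlap_trigger_nt
  if (overlapish) {
    pred <- step_b(msa, upstream_gene_end_offset, cfg)
    if (!is.null(pred)) return(pred)
  } else {
    pred <- step_a(msa, cfg)
    if (!is.null(pred)) return(pred)
  }
  step_c(msa, cfg)
}

#' @rdname predict_start
#' @param x A `start_prediction`.
#' @param ... Unused.
#' @method tidy start_prediction
#' @export
tidy.start_prediction <- function(x, ...) {
  if (is.null(x$scores)) {
    return(tibble(seq_offset = integer(), codon = character(),
                  aa_col = integer(), s5 = double(),
                  n_support = integer(), n_penalty = integer()))
  }
  as_tibble(x$scores)
}

#' @rdname predict_start
#' @method glance start_prediction
#' @export
glance.start_prediction <- function(x, ...) {
  s5 <- NA_real_
  if (!is.null(x$scores) && !is.na(x$query_offset)) {
    hit <- x$scores$s5[x$scores$seq_offset == x$query_offset]
    if (length(hit)) s5 <- hit[[1]]
  }
  tibble(
    query_id = x$query_id,
    query_offset = x$query_offset,
    codon = x$codon,
    step = x$step,
    s5 = s5,
    s_blk = if (!is.null(x$block)) x$block$score else NA_real_,
    n_targets = x$n_targets,
    reason = x$reason
  )
}
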