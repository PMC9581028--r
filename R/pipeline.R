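#' Run the full start-prediction pipeline on one family
#'
#' Orchestrates target selection, dual-layer alignment construction and the
#' three-step start selection for a query with a raw homolog set: filters the
#' relation table with [select_targets()], aligns the query with the kept
#' targets, and calls [predict_start()] with the query's upstream-gene context
#' (when annotated). A family with fewer than `cfg$min_targets` kept targets
#' yields a declined prediction (`step = "none"`), which is a first-class
#' outcome, not an error.
#'
#' @param query A [lorf_record()].
#' @param targets List of target [lorf_record()]s.
#' @param relations Pairwise relation table (see [select_targets()]).
#' @param cfg A [scoring_config()].
#' @param aligner Protein aligner adapter; default [aligner_colinear()], use
#'   [aligner_gold()] with a stored alignment for gapped fixtures.
#' @return A list of class `pipeline_result`: `prediction`
#'   (a `start_prediction`), `audit` (the target-selection audit tibble),
#'   `msa` (the `dual_msa`, or `NULL` when declined), and `call` (a one-row
#'   [gene_calls()] tibble in 1-based LORF coordinates, or a zero-row tibble
#'   when declined).
#' @export
run_prediction <- function(query, targets, relations, cfg = scoring_config(),
                           aligner = aligner_colinear()) {
  stopifnot(inherits(query, "lorf_record"))
  audit <- select_targets(query, relations, cfg)
  kept_ids <- audit$target_id[audit$kept]
  target_ids <- purrr::map_chr(targets, "id")

  if (length(kept_ids) < cfg$min_targets) {
    dummy <- structure(list(ids = query$id, n = 1L + length(kept_ids),
                            query_index = 1L), class = "dual_msa")
    pred <- new_prediction(dummy, "none", reason = "too_few_targets")
    return(structure(list(prediction = pred, audit = audit, msa = NULL,
                          call = prediction_calls(pred, query)),
                     class = "pipeline_result"))
  }

  kept <- targets[match(kept_ids, target_ids)]
  msa <- build_dual_msa(c(list(query), kept), aligner = aligner)
  up <- query$upstream_gene_end_offset
  pred <- predict_start(msa, if (is.na(up)) NULL else up, cfg)
  structure(list(prediction = pred, audit = audit, msa = msa,
                 call = prediction_calls(pred, query)),
            class = "pipeline_result")
}

#' Run the pipeline on an on-disk fixture bundle
#'
#' @param dir Directory written by [write_fixture_bundle()].
#' @inheritParams run_prediction
#' @return A `pipeline_result` (see [run_prediction()]).
#' @export
run_prediction_bundle <- function(dir, cfg = scoring_config()) {
  b <- read_fixture_bundle(dir)
  run_prediction(b$query, b$targets, b$relations, cfg,
                 aligner = aligner_gold(b$gold_aa))
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$prediction)
  cat(sprintf("  targets kept: %d / %d\n",
              sum(x$audit$kept), nrow(x$audit)))
  invisible(x)
}

#' Convert predictions to a gene-call table
#'
#' Expresses a start prediction in 1-based coordinates on the query LORF
#' (plus strand), ready for [write_gene_calls_gff3()], [combine_agreement()]
#' or [evaluate_starts()]. Declined predictions yield no row, so declines show
#' up as coverage loss, never as silent drops of the 3' end.
#'
#' @param pred A `start_prediction`.
#' @param query The query [lorf_record()].
#' @return A [gene_calls()] tibble with 0 or 1 row and columns `step`, `s5`,
#'   `s_blk` carried as attributes-to-be in GFF3 output.
#' @export
prediction_calls <- function(pred, query) {
  stopifnot(inherits(pred, "start_prediction"), inherits(query, "lorf_record"))
  g <- glance(pred)
  if (pred$step == "none") {
    return(gene_calls(seq_id = character(), strand = character(),
                      start = integer(), end = integer(),
                      step = character(), s5 = double(), s_blk = double()))
  }
  gene_calls(
    seq_id = query$id, strand = "+",
    start = pred$query_offset + 1L, end = nchar(query$nt),
    step = pred$step, s5 = g$s5, s_blk = g$s_blk
  )
}
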