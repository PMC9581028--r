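#' Scoring and filtering configuration
#'
#' Bundles every tunable parameter of the start-selection procedure. Defaults
#' follow the published method: 10-aa conservation blocks with identity
#' threshold 0.5, candidate-conservation threshold 0.5 with a +/-2 codon
#' neighborhood, a 9 nt search window near an upstream gene 3' end, a 30 nt
#' downstream re-check window, a Kimura distance window of [0.1, 0.5] with 80%
#' pairwise coverage, and at most 50 (at least 10) targets per alignment.
#'
#' @param block_len_aa Block length `r` in amino acids for the block identity
#'   score (default 10).
#' @param t_blk Threshold above which a block counts as conserved (default 0.5).
#' @param t_5prime Threshold on the candidate conservation score `S5'`
#'   (default 0.5).
#' @param neigh_codons Neighborhood half-width, in codons, used when asking
#'   whether a target carries a start codon near a candidate column (default 2,
#'   i.e. 6 nt).
#' @param overlap_window_nt Search window (nt) around an upstream gene 3' end
#'   for overlap-aware selection (default 9).
#' @param downstream_recheck_nt Window (nt) downstream of a provisional
#'   candidate that is re-checked for a better-supported start (default 30).
#' @param dc_margin Margin `f` (nt) of the intergenic-distance conservation
#'   measure (default 3).
#' @param kimura_min,kimura_max Kimura distance window for target selection
#'   (defaults 0.1 and 0.5). `kimura_min` doubles as the target-target
#'   redundancy threshold.
#' @param coverage_min Minimum fraction of either protein that the pairwise
#'   alignment must cover (default 0.8; the filter requires strictly more).
#' @param max_targets Cap on the number of targets entering the alignment
#'   (default 50).
#' @param min_targets Minimum number of targets required to attempt a
#'   prediction (default 10).
#' @param blk_norm Normalization of the block identity score: `"printed"` uses
#'   1/(r (N-1)^2) over ordered row pairs (maximum about N/(N-1));
#'   `"pair_count"` uses 1/(r N (N-1)), for sensitivity analysis.
#' @param overlap_trigger_nt Overlap-aware selection is attempted when the
#'   upstream gene 3' end lies downstream of, or within this many nt upstream
#'   of, the query LORF 5' end (default 10).
#' @param sample_first If `TRUE`, sample down to `max_targets` before distance
#'   filtering instead of after (default `FALSE`: filter first, then sample).
#' @param rng_seed Integer seed used for target subsampling.
#'
#' @return An object of class `scoring_config` (a named list).
#' @examples
#' cfg <- scoring_config()
#' cfg$t_blk
#' @export
scoring_config <- function(block_len_aa = 10L,
                           t_blk = 0.5,
                           t_5prime = 0.5,
                           neigh_codons = 2L,
                           overlap_window_nt = 9L,
                           downstream_recheck_nt = 30L,
                           dc_margin = 3L,
                           kimura_min = 0.1,
                           kimura_max = 0.5,
                           coverage_min = 0.8,
                           max_targets = 50L,
                           min_targets = 10L,
                           blk_norm = c("printed", "pair_count"),
                           overlap_trigger_nt = 10L,
                           sample_first = FALSE,
                           rng_seed = 1L) {
  blk_norm <- match.arg(blk_norm)
  cfg <- list(
    block_len_aa = as.integer(block_len_aa),
    t_blk = t_blk,
    t_5prime = t_5prime,
    neigh_codons = as.integer(neigh_codons),
    overlap_window_nt = as.integer(overlap_window_nt),
    downstream_recheck_nt = as.integer(downstream_recheck_nt),
    dc_margin = as.integer(dc_margin),
    kimura_min = kimura_min,
    kimura_max = kimura_max,
    coverage_min = coverage_min,
    max_targets = as.integer(max_targets),
    min_targets = as.integer(min_targets),
    blk_norm = blk_norm,
    overlap_trigger_nt = as.integer(overlap_trigger_nt),
    sample_first = isTRUE(sample_first),
    rng_seed = as.integer(rng_seed)
  )
  stopifnot(
    cfg$block_len_aa >= 1L,
    cfg$t_blk > 0, cfg$t_blk <= 1,
    cfg$t_5prime > 0, cfg$t_5prime <= 1,
    cfg$neigh_codons >= 0L,
    cfg$overlap_window_nt > 0L,
    cfg$downstream_recheck_nt > 0L,
    cfg$dc_margin >= 0L,
    cfg$kimura_min < cfg$kimura_max,
    cfg$coverage_min > 0, cfg$coverage_min < 1,
    cfg$min_targets <= cfg$max_targets,
    cfg$min_targets >= 1L
  )
  structure(cfg, class = "scoring_config")
}

#' @export
print.scoring_config <- function(x, ...) {
  cat("<scoring_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
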