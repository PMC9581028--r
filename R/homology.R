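#' Filter raw homologs into the target set used for alignment
#'
#' Applies the published selection pipeline to a table of pairwise
#' query-target alignments: (1) drop targets whose protein alignment does not
#' cover more than `coverage_min` of both the query and the target; (2)
#' compute the Kimura two-parameter distance to the query from the
#' codon-backmapped nucleotide pairwise alignment; (3) drop targets closer
#' than `kimura_min`, farther than `kimura_max`, or with undefined distance;
#' (4) remove redundancy by a greedy scan in ascending distance-to-query
#' order, dropping any target within `kimura_min` of an already kept target
#' (target-target distances are composed through query coordinates); (5) if
#' more than `max_targets` survive, sample `max_targets` uniformly using
#' `cfg$rng_seed`. Every input target receives exactly one rejection reason or
#' is kept.
#'
#' @param query A [lorf_record()] for the query (used for validation only; the
#'   pairwise rows in `relations` carry the aligned sequence content).
#' @param relations A tibble with one row per raw target and columns
#'   `target_id`, `aln_query`, `aln_target` (gapped nucleotide rows of the
#'   pairwise alignment over the gene region), `coverage_query`,
#'   `coverage_target`.
#' @param cfg A [scoring_config()].
#' @return A tibble (the audit) with one row per input target: coverages,
#'   `aligned_positions`, `p`, `q`, `d_ab`, logical `kept`, and `reason`
#'   (`NA` when kept; otherwise one of `low_coverage`, `undefined_distance`,
#'   `too_close`, `too_far`, `redundant`, `sampled_out`).
#' @export
select_targets <- function(query, relations, cfg = scoring_config()) {
  stopifnot(inherits(cfg, "scoring_config"))
  relations <- as_tibble(relations)
  need <- c("target_id", "aln_query", "aln_target",
            "coverage_query", "coverage_target")
  if (!all(need %in% names(relations)))
    stop("select_targets: relations must have columns ",
         paste(need, collapse = ", "))
  if (anyDuplicated(relations$target_id))
    stop("select_targets: duplicate target_id in relations")
  n <- nrow(relations)
  if (n == 0L) {
    return(tibble(target_id = character(), coverage_query = double(),
                  coverage_target = double(), aligned_positions = integer(),
                  p = double(), q = double(), d_ab = double(),
                  kept = logical(), reason = character()))
  }

  stats <- purrr::map2_dfr(relations$aln_query, relations$aln_target,
                           transition_transversion_fractions)
  audit <- relations |>
    select("target_id", "coverage_query", "coverage_target") |>
    mutate(
      aligned_positions = stats$aligned_positions,
      p = stats$p,
      q = stats$q,
      d_ab = kimura_distance(stats$p, stats$q),
      kept = FALSE,
      reason = NA_character_
    )

  low_cov <- !(audit$coverage_query > cfg$coverage_min &
               audit$coverage_target > cfg$coverage_min)
  audit$reason[low_cov] <- "low_coverage"
  undef <- is.na(audit$reason) & is.na(audit$d_ab)
  audit$reason[undef] <- "undefined_distance"
  close <- is.na(audit$reason) & audit$d_ab < cfg$kimura_min
  audit$reason[close] <- "too_close"
  far <- is.na(audit$reason) & audit$d_ab > cfg$kimura_max
  audit$reason[far] <- "too_far"

  sample_down <- function(aud, pool) {
    # uniform subsample to max_targets, deterministic under cfg$rng_seed
    if (length(pool) > cfg$max_targets) {
      rng <- local_rng(cfg$rng_seed)
      drop <- setdiff(pool, sample(pool, cfg$max_targets))
      restore_rng(rng)
      aud$reason[match(drop, aud$target_id)] <- "sampled_out"
    }
    aud
  }

  if (cfg$sample_first) {
    audit <- sample_down(audit, audit$target_id[is.na(audit$reason)])
  }

  # redundancy pass: ascending distance to query, greedy
  cand <- audit |>
    filter(is.na(.data$reason)) |>
    arrange(.data$d_ab, .data$target_id)
  if (nrow(cand) > 0L) {
    prof <- lapply(match(cand$target_id, relations$target_id), function(i) {
      target_profile(relations$aln_query[i], relations$aln_target[i])
    })
    kept_idx <- integer(0)
    for (i in seq_len(nrow(cand))) {
      redundant <- FALSE
      for (k in kept_idx) {
        d <- profile_kimura(prof[[i]], prof[[k]])
        if (!is.na(d) && d < cfg$kimura_min) { redundant <- TRUE; break }
      }
      if (redundant) {
        audit$reason[audit$target_id == cand$target_id[i]] <- "redundant"
      } else {
        kept_idx <- c(kept_idx, i)
      }
    }
  }

  if (!cfg$sample_first) {
    audit <- sample_down(audit, audit$target_id[is.na(audit$reason)])
  }

  audit$kept <- is.na(audit$reason)
  audit
}

# Per-query-position target base profile: character vector indexed by the
# ungapped query position, NA where the target has a gap/ambiguity.
target_profile <- function(aln_query, aln_target) {
  a <- strsplit(toupper(aln_query), "")[[1]]
  b <- strsplit(toupper(aln_target), "")[[1]]
  if (length(a) != length(b))
    stop("target_profile: pairwise rows differ in length")
  qpos <- a %in% c(PURINES, PYRIMIDINES)
  out <- b[qpos]
  out[!out %in% c(PURINES, PYRIMIDINES)] <- NA_character_
  out
}

# Kimura distance between two targets through shared query coordinates.
profile_kimura <- function(pa, pb) {
  m <- min(length(pa), length(pb))
  a <- pa[seq_len(m)]; b <- pb[seq_len(m)]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  mism <- a != b
  ts <- mism & ((a %in% PURINES & b %in% PURINES) |
                (a %in% PYRIMIDINES & b %in% PYRIMIDINES))
  kimura_distance(sum(ts) / length(a), sum(mism & !ts) / length(a))
}

# Save/seed and restore the global RNG so that subsampling is deterministic
# without disturbing the caller's random stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
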