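#' Build a validated table of gene calls
#'
#' A gene call is identified by its 3' end: on the plus strand the 3' end is
#' `end`, on the minus strand it is `start` (coordinates are 1-based genomic,
#' `start <= end`). All comparisons in this package are anchored on the
#' strand-aware 3' key, since reading frames (3' ends) are treated as solved.
#'
#' @param seq_id,strand,start,end Vectors of equal length; `strand` in
#'   `"+"`/`"-"`.
#' @param ... Further columns carried along (e.g. `step`, `gc`).
#' @return A tibble of class `gene_calls` with the input columns plus
#'   `three_prime` and `five_prime` coordinates.
#' @export
gene_calls <- function(seq_id, strand, start, end, ...) {
  out <- tibble(seq_id = as.character(seq_id), strand = as.character(strand),
                start = as.integer(start), end = as.integer(end), ...)
  stopifnot(all(out$strand %in% c("+", "-")), all(out$start <= out$end))
  out$three_prime <- ifelse(out$strand == "+", out$end, out$start)
  out$five_prime <- ifelse(out$strand == "+", out$start, out$end)
  class(out) <- c("gene_calls", class(out))
  out
}

as_gene_calls <- function(df) {
  if (inherits(df, "gene_calls")) return(df)
  need <- c("seq_id", "strand", "start", "end")
  stopifnot(all(need %in% names(df)))
  do.call(gene_calls, c(as.list(df[need]),
                        as.list(df[setdiff(names(df), c(need, "three_prime", "five_prime"))])))
}

key_of <- function(calls) {
  paste(calls$seq_id, calls$strand, calls$three_prime, sep = "\r")
}

check_unique_keys <- function(calls, label) {
  if (anyDuplicated(key_of(calls)))
    stop("duplicate 3'-end keys in ", label,
         ": each gene must appear once per (seq_id, strand, 3' end)")
}

#' Exact-agreement combination of two prediction streams
#'
#' Returns the gene calls present in both sets (matched by strand-aware 3'
#' end) whose 5' starts are identical. Genes present in only one set, or with
#' differing starts, are excluded; the coverage loss is by design, and the
#' expected error of the intersection is proportional to the product of the
#' two tools' error probabilities.
#'
#' @param pred_a,pred_b Gene-call tables (see [gene_calls()]).
#' @return A `gene_calls` tibble (columns of `pred_a` for the agreeing genes).
#' @export
combine_agreement <- function(pred_a, pred_b) {
  pred_a <- as_gene_calls(pred_a); pred_b <- as_gene_calls(pred_b)
  check_unique_keys(pred_a, "pred_a"); check_unique_keys(pred_b, "pred_b")
  ka <- key_of(pred_a); kb <- key_of(pred_b)
  m <- match(ka, kb)
  shared <- !is.na(m)
  agree <- shared & pred_a$five_prime == pred_b$five_prime[m]
  pred_a[agree, ]
}

#' Accuracy, error rate and coverage of start predictions
#'
#' `M3` counts predictions whose 3' key occurs in the reference; `M5` counts
#' those that also match the reference 5' start. `Acc = 100 * M5 / M3`,
#' `Err = 100 - Acc`, `Covr = 100 * M3 / |G|`. With `M3 = 0`, accuracy and
#' error are reported as `NA` and coverage as 0.
#'
#' @param pred Predicted gene calls.
#' @param reference Reference gene calls (non-empty).
#' @return One-row tibble: `n_reference`, `n_predicted`, `m3`, `m5`, `acc`,
#'   `err`, `covr` (percentages at full precision).
#' @export
evaluate_starts <- function(pred, reference) {
  pred <- as_gene_calls(pred); reference <- as_gene_calls(reference)
  if (nrow(reference) == 0L) stop("evaluate_starts: empty reference set")
  check_unique_keys(pred, "pred"); check_unique_keys(reference, "reference")
  m <- match(key_of(pred), key_of(reference))
  m3 <- sum(!is.na(m))
  m5 <- sum(!is.na(m) & pred$five_prime == reference$five_prime[m])
  acc <- if (m3 > 0) 100 * m5 / m3 else NA_real_
  tibble(
    n_reference = nrow(reference),
    n_predicted = nrow(pred),
    m3 = m3, m5 = m5,
    acc = acc,
    err = if (m3 > 0) 100 - acc else NA_real_,
    covr = 100 * m3 / nrow(reference)
  )
}

#' Stratified disagreement report between two annotations
#'
#' For the genes shared by 3' key, reports per stratum the number with
#' differing 5' starts and the corresponding percentage. Strata are columns of
#' `set_a` (e.g. the producing step, or a GC-content bin).
#'
#' @param set_a,set_b Gene-call tables.
#' @param strata Character vector of column names of `set_a` to stratify by
#'   (default: none, a single overall row).
#' @return Tibble with the strata columns, `n_shared`, `n_diff`, `pct_diff`
#'   (`NA` where a stratum is empty).
#' @export
difference_report <- function(set_a, set_b, strata = character()) {
  set_a <- as_gene_calls(set_a); set_b <- as_gene_calls(set_b)
  check_unique_keys(set_a, "set_a"); check_unique_keys(set_b, "set_b")
  stopifnot(all(strata %in% names(set_a)))
  m <- match(key_of(set_a), key_of(set_b))
  df <- as_tibble(set_a)[!is.na(m), , drop = FALSE]
  df$.diff <- df$five_prime != set_b$five_prime[m[!is.na(m)]]
  if (length(strata) == 0L) {
    return(tibble(n_shared = nrow(df), n_diff = sum(df$.diff),
                  pct_diff = if (nrow(df)) 100 * mean(df$.diff) else NA_real_))
  }
  df |>
    group_by(dplyr::across(dplyr::all_of(strata))) |>
    summarise(n_shared = dplyr::n(), n_diff = sum(.data$.diff),
              pct_diff = 100 * mean(.data$.diff), .groups = "drop")
}
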