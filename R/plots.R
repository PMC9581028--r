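#' Conservation profile of a dual-layer alignment
#'
#' Plots the per-column pairwise identity (ordered-pair matches normalized by
#' `N(N-1)`) along the protein layer, with the query's start-codon candidate
#' columns marked; if a prediction is supplied its column is highlighted.
#'
#' @param object A `dual_msa`.
#' @param prediction Optional `start_prediction` to highlight.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dual_msa
#' @export
autoplot.dual_msa <- function(object, prediction = NULL, ...) {
  cm <- column_match_counts(object)
  df <- tibble(
    aa_col = seq_len(object$L),
    identity = cm / (object$n * (object$n - 1))
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$aa_col, y = .data$identity)) +
    ggplot2::geom_line(color = "grey30") +
    ggplot2::labs(x = "alignment column (aa)", y = "pairwise identity",
                  title = "Column conservation profile") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  cand <- object$query_candidates
  if (nrow(cand)) {
    p <- p + ggplot2::geom_vline(xintercept = cand$aa_col,
                                 linetype = "dotted", color = "steelblue")
  }
  if (!is.null(prediction) && !is.na(prediction$query_offset)) {
    hit <- cand$aa_col[cand$seq_offset == prediction$query_offset]
    if (length(hit))
      p <- p + ggplot2::geom_vline(xintercept = hit, color = "firebrick")
  }
  p
}

#' Histogram of intergenic distances within a component
#'
#' The distribution of per-sequence signed distances from the upstream gene's
#' 3' end to the gene start (negative values are overlaps), with the modal
#' distance and the `x +/- f` conservation band highlighted.
#'
#' @param object An `overlap_stats` result from
#'   [intergenic_conservation_dc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot overlap_stats
#' @export
autoplot.overlap_stats <- function(object, ...) {
  d <- attr(object, "distances")
  ggplot2::ggplot(tibble(d = d), ggplot2::aes(x = .data$d)) +
    ggplot2::annotate("rect",
                      xmin = object$mode_x - object$f - 0.5,
                      xmax = object$mode_x + object$f + 0.5,
                      ymin = -Inf, ymax = Inf,
                      fill = "steelblue", alpha = 0.15) +
    ggplot2::geom_bar(fill = "grey30") +
    ggplot2::geom_vline(xintercept = object$mode_x, color = "firebrick") +
    ggplot2::labs(
      x = "intergenic distance D(n) [nt]", y = "sequences",
      title = sprintf("Intergenic-distance conservation: mode %d, DC = %.2f (f = %d)",
                      object$mode_x, object$dc, object$f)
    ) +
    ggplot2::theme_minimal()
}

#' Per-candidate conservation scores of a prediction
#'
#' Lollipop plot of the S5' score of every query start candidate, the
#' decision threshold, and the selected candidate.
#'
#' @param object A `start_prediction` with candidate scores (steps B/C).
#' @param t_5prime Threshold drawn as a reference line (default 0.5).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot start_prediction
#' @export
autoplot.start_prediction <- function(object, t_5prime = 0.5, ...) {
  sc <- tidy(object)
  if (!nrow(sc)) stop("autoplot.start_prediction: prediction carries no candidate scores")
  sc$selected <- !is.na(object$query_offset) & sc$seq_offset == object$query_offset
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$seq_offset, y = .data$s5,
                                   color = .data$selected)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$seq_offset, yend = 0)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(yintercept = t_5prime, linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
                                guide = "none") +
    ggplot2::labs(x = "candidate offset in LORF [nt]", y = "S5'",
                  title = sprintf("Candidate conservation (step %s)", object$step)) +
    ggplot2::theme_minimal()
}
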