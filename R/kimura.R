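PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Transition/transversion fractions of a pairwise nucleotide alignment
#'
#' Columns with a gap or ambiguity letter in either row are excluded. Among the
#' remaining aligned positions, `p` is the fraction with a transition
#' (A<->G or C<->T) and `q` the fraction with a transversion (any other
#' mismatch).
#'
#' @param row_a,row_b Gapped nucleotide rows of equal length (gap characters
#'   `-` or `.`).
#' @return A one-row tibble with columns `aligned_positions`, `p`, `q`.
#'   `p` and `q` are `NA` when no column is comparable.
#' @examples
#' transition_transversion_fractions("AAAAAAAAAA", "GGAAAAAAAC")
#' @export
transition_transversion_fractions <- function(row_a, row_b) {
  stopifnot(is.character(row_a), is.character(row_b),
            length(row_a) == 1L, length(row_b) == 1L)
  if (nchar(row_a) != nchar(row_b))
    stop("transition_transversion_fractions: rows differ in length")
  a <- strsplit(toupper(row_a), "")[[1]]
  b <- strsplit(toupper(row_b), "")[[1]]
  ok <- a %in% c(PURINES, PYRIMIDINES) & b %in% c(PURINES, PYRIMIDINES)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0L) {
    return(tibble(aligned_positions = 0L, p = NA_real_, q = NA_real_))
  }
  mism <- a != b
  ts <- mism & ((a %in% PURINES & b %in% PURINES) |
                (a %in% PYRIMIDINES & b %in% PYRIMIDINES))
  tibble(
    aligned_positions = n,
    p = sum(ts) / n,
    q = sum(mism & !ts) / n
  )
}

#' Kimura two-parameter distance
#'
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`, the K2P estimator of the
#' expected number of substitutions per site given transition fraction `P` and
#' transversion fraction `Q`. Outside the estimator's domain (when
#' `1 - 2P - Q <= 0` or `1 - 2Q <= 0`) the distance is undefined and `NA` is
#' returned, never 0 or `Inf`.
#'
#' @param p Transition fraction (scalar or vector).
#' @param q Transversion fraction (recycled against `p`).
#' @return Numeric vector of distances, `NA` where undefined.
#' @examples
#' kimura_distance(0.1, 0.05)
#' kimura_distance(0.5, 0) # domain boundary: NA
#' @export
kimura_distance <- function(p, q) {
  stopifnot(is.numeric(p), is.numeric(q))
  n <- max(length(p), length(q))
  p <- rep_len(p, n); q <- rep_len(q, n)
  w1 <- 1 - 2 * p - q
  w2 <- 1 - 2 * q
  d <- rep(NA_real_, n)
  ok <- !is.na(w1) & !is.na(w2) & w1 > 0 & w2 > 0
  d[ok] <- -0.5 * log(w1[ok] * sqrt(w2[ok]))
  d
}

# Kimura distance between two gapped nucleotide rows; NA when undefined.
pairwise_kimura <- function(row_a, row_b) {
  st <- transition_transversion_fractions(row_a, row_b)
  kimura_distance(st$p, st$q)
}
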