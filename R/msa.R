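#' Protein alignment adapters
#'
#' [build_protein_msa()] delegates the actual alignment to an adapter
#' function taking a named character vector of protein sequences and returning
#' a named character vector of gapped rows of equal length, in the same order.
#'
#' * `aligner_colinear()` asserts that all inputs have equal length and
#'   returns them unchanged; this is the natural aligner for indel-free
#'   families such as those produced by [simulate_family()].
#' * `aligner_gold(rows)` returns pre-computed ("gold") aligned rows after
#'   checking that ungapping them reproduces the inputs, byte for byte; use it
#'   with fixture bundles that store an alignment on disk.
#' * `aligner_mafft()` shells out to an external `mafft` executable when one
#'   is on `PATH`; intended for exploratory use on real families.
#'
#' @param rows Named character vector of gapped rows (gold alignment).
#' @param exe Name or path of the mafft executable.
#' @return An aligner function.
#' @name aligners
NULL

#' @rdname aligners
#' @export
aligner_colinear <- function() {
  function(aa) {
    if (length(unique(nchar(aa))) != 1L)
      stop("aligner_colinear: sequences differ in length; use a real aligner")
    aa
  }
}

#' @rdname aligners
#' @export
aligner_gold <- function(rows) {
  force(rows)
  function(aa) {
    if (!all(names(aa) %in% names(rows)))
      stop("aligner_gold: gold alignment is missing rows: ",
           paste(setdiff(names(aa), names(rows)), collapse = ", "))
    out <- rows[names(aa)]
    ung <- gsub("-", "", out, fixed = TRUE)
    bad <- names(aa)[ung != unname(aa)]
    if (length(bad))
      stop("aligner_gold: gold rows do not ungap to the input for: ",
           paste(bad, collapse = ", "))
    out
  }
}

#' @rdname aligners
#' @export
aligner_mafft <- function(exe = "mafft") {
  function(aa) {
    if (Sys.which(exe) == "")
      stop("aligner_mafft: '", exe, "' not found on PATH")
    fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
    on.exit(unlink(c(fin, fout)), add = TRUE)
    Biostrings::writeXStringSet(Biostrings::AAStringSet(aa), fin)
    status <- system2(exe, c("--quiet", "--anysymbol", "--auto", fin),
                      stdout = fout, stderr = tempfile())
    if (!identical(status, 0L))
      stop("aligner_mafft: mafft exited with status ", status)
    out <- Biostrings::readAAStringSet(fout)
    res <- toupper(as.character(out))
    names(res) <- names(out)
    res[names(aa)]
  }
}

#' Build a protein multiple alignment over LORF records
#'
#' @param records List of [lorf_record()]s (the query first by convention).
#' @param aligner An adapter from [aligners]; default [aligner_colinear()].
#' @return Named character vector of gapped amino-acid rows, input order
#'   preserved, all rows of equal length, each row ungapping to its record's
#'   protein.
#' @export
build_protein_msa <- function(records, aligner = aligner_colinear()) {
  stopifnot(length(records) >= 2L, all(purrr::map_lgl(records, inherits, "lorf_record")))
  ids <- purrr::map_chr(records, "id")
  if (anyDuplicated(ids)) stop("build_protein_msa: duplicate record ids")
  aa <- setNames(purrr::map_chr(records, "aa"), ids)
  rows <- aligner(aa)
  if (!identical(names(rows), ids))
    rows <- rows[ids]
  if (length(unique(nchar(rows))) != 1L)
    stop("build_protein_msa: aligner returned rows of unequal length")
  ung <- gsub("-", "", rows, fixed = TRUE)
  if (!all(ung == unname(aa)))
    stop("build_protein_msa: aligned rows do not reproduce the input proteins")
  rows
}

#' Back-map a protein alignment onto codon-resolved nucleotide rows
#'
#' Expands every amino-acid column of the alignment into the source codon of
#' each row (or three gap characters), producing the dual-layer alignment used
#' by all conservation scores. Column/offset maps and the query's start-codon
#' candidates (lifted to alignment columns) are attached.
#'
#' @param aa_msa Named character vector of gapped protein rows (from
#'   [build_protein_msa()]).
#' @param records The same list of [lorf_record()]s, in row order.
#' @param query_id Identifier of the query row (default: first record).
#' @return An object of class `dual_msa`.
#' @export
backmap_to_nucleotide <- function(aa_msa, records, query_id = NULL) {
  ids <- purrr::map_chr(records, "id")
  stopifnot(identical(sort(names(aa_msa)), sort(ids)))
  aa_msa <- aa_msa[ids]
  if (is.null(query_id)) query_id <- ids[[1]]
  qi <- match(query_id, ids)
  if (is.na(qi)) stop("backmap_to_nucleotide: query_id not among records")

  L <- unique(nchar(aa_msa))
  stopifnot(length(L) == 1L)
  n <- length(records)

  aa_mat <- matrix(NA_character_, n, L)
  codon_mat <- matrix(NA_character_, n, L)
  col_map <- vector("list", n)
  nt_rows <- character(n)

  for (i in seq_len(n)) {
    rec <- records[[i]]
    if (nchar(rec$nt) != 3L * nchar(rec$aa))
      stop("backmap_to_nucleotide: nt/aa length mismatch in row ", rec$id)
    chars <- strsplit(aa_msa[[i]], "")[[1]]
    gap <- chars == "-"
    if (sum(!gap) != nchar(rec$aa))
      stop("backmap_to_nucleotide: row ", rec$id, " does not ungap to its protein")
    cods <- codons_of(rec$nt)
    cm <- rep(NA_integer_, L)
    cm[!gap] <- seq_len(nchar(rec$aa)) - 1L # 0-based aa offsets
    col_map[[i]] <- cm
    aa_row <- chars
    aa_row[gap] <- NA_character_
    aa_mat[i, ] <- aa_row
    cr <- rep("---", L)
    cr[!gap] <- cods
    codon_mat[i, !gap] <- cods
    nt_rows[i] <- paste(cr, collapse = "")
  }
  names(nt_rows) <- ids

  cand <- list_start_candidates(records[[qi]])
  if (nrow(cand)) {
    qmap <- col_map[[qi]]
    aa_col <- match(cand$seq_offset %/% 3L, qmap)
    cand$aa_col <- aa_col
    cand$nt_col <- 3L * (aa_col - 1L) + 1L
  } else {
    cand$aa_col <- integer(0)
    cand$nt_col <- integer(0)
  }

  structure(
    list(
      ids = ids, n = n, L = L, query_index = qi,
      aa = aa_msa, nt = nt_rows,
      aa_mat = aa_mat, codon_mat = codon_mat,
      col_map = col_map,
      query_candidates = cand,
      records = records
    ),
    class = "dual_msa"
  )
}

#' Build a dual-layer alignment in one call
#'
#' Convenience wrapper: [build_protein_msa()] then [backmap_to_nucleotide()].
#'
#' @inheritParams build_protein_msa
#' @inheritParams backmap_to_nucleotide
#' @return A `dual_msa`.
#' @export
build_dual_msa <- function(records, aligner = aligner_colinear(), query_id = NULL) {
  backmap_to_nucleotide(build_protein_msa(records, aligner), records, query_id)
}

#' @export
print.dual_msa <- function(x, ...) {
  cat(sprintf("<dual_msa> %d sequences x %d aa columns (query: %s)\n",
              x$n, x$L, x$ids[x$query_index]))
  cat(sprintf("  query start candidates: %d\n", nrow(x$query_candidates)))
  invisible(x)
}

#' Codon content of an alignment window
#'
#' Returns, for every row, the frame-0 codons whose first nucleotide column
#' lies within `half_width_nt` of `center_col`, skipping gap codons. Rows
#' whose window is all gaps contribute an empty vector.
#'
#' @param msa A `dual_msa`.
#' @param center_col 1-based nucleotide-layer column; must be the first
#'   nucleotide of a query-row codon (frame 0, query non-gap).
#' @param half_width_nt Window half-width in nucleotides.
#' @return Named list (one element per row) of character vectors of codons.
#' @export
column_window <- function(msa, center_col, half_width_nt) {
  stopifnot(inherits(msa, "dual_msa"))
  center_col <- as.integer(center_col)
  if (center_col < 1L || center_col > 3L * msa$L)
    stop("column_window: center_col out of range")
  if ((center_col - 1L) %% 3L != 0L)
    stop("column_window: center_col is not the first nucleotide of a codon column")
  a0 <- (center_col - 1L) %/% 3L + 1L
  if (is.na(msa$aa_mat[msa$query_index, a0]))
    stop("column_window: query row has a gap at center_col")
  first_nt <- 3L * (seq_len(msa$L) - 1L) + 1L
  cols <- which(abs(first_nt - center_col) <= half_width_nt)
  out <- lapply(seq_len(msa$n), function(i) {
    v <- msa$codon_mat[i, cols]
    v[!is.na(v)]
  })
  names(out) <- msa$ids
  out
}

#' Per-column gap fraction diagnostic
#'
#' @param msa A `dual_msa`.
#' @return Tibble with `aa_col` and `gap_fraction` across rows.
#' @export
gap_fraction_profile <- function(msa) {
  stopifnot(inherits(msa, "dual_msa"))
  tibble(
    aa_col = seq_len(msa$L),
    gap_fraction = colMeans(is.na(msa$aa_mat))
  )
}

#' Render an alignment view with start-capable codon notation
#'
#' Produces a text view of the protein layer in which codons able to initiate
#' translation (ATG/GTG/TTG) appear as uppercase M/V/L while valine/leucine
#' encoded by non-start codons appear as lowercase v/l. Optional `#ref` and
#' `#selected` marker rows flag an annotated and a predicted start column.
#'
#' @param msa A `dual_msa`.
#' @param selected_col,ref_col Optional 1-based amino-acid column indices.
#' @param file Optional path; when given, lines are written there.
#' @return Character vector of lines, invisibly when `file` is given.
#' @export
format_msa_view <- function(msa, selected_col = NULL, ref_col = NULL, file = NULL) {
  stopifnot(inherits(msa, "dual_msa"))
  marker <- function(col, label) {
    line <- strrep(" ", msa$L)
    substr(line, col, col) <- "*"
    paste0(formatC(label, width = 12, flag = "-"), line)
  }
  body <- vapply(seq_len(msa$n), function(i) {
    sym <- msa$aa_mat[i, ]
    cod <- msa$codon_mat[i, ]
    low <- !is.na(cod) & cod %in% NONSTART_VL_CODONS
    sym[low] <- tolower(sym[low])
    sym[is.na(sym)] <- "-"
    paste0(formatC(msa$ids[i], width = 12, flag = "-"), paste(sym, collapse = ""))
  }, character(1))
  lines <- character(0)
  if (!is.null(ref_col)) lines <- c(lines, marker(ref_col, "#ref"))
  if (!is.null(selected_col)) lines <- c(lines, marker(selected_col, "#selected"))
  lines <- c(lines, body)
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Write both alignment layers as aligned FASTA
#'
#' @param msa A `dual_msa`.
#' @param aa_file,nt_file Output paths (either may be `NULL` to skip).
#' @return Invisibly, the `dual_msa`.
#' @export
write_dual_msa <- function(msa, aa_file = NULL, nt_file = NULL) {
  stopifnot(inherits(msa, "dual_msa"))
  if (!is.null(aa_file))
    Biostrings::writeXStringSet(Biostrings::BStringSet(msa$aa), aa_file)
  if (!is.null(nt_file))
    Biostrings::writeXStringSet(Biostrings::BStringSet(msa$nt), nt_file)
  invisible(msa)
}
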