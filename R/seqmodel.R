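#' Translate a LORF nucleotide sequence
#'
#' Codon-by-codon translation under NCBI table 11. No N-terminal methionine
#' substitution is applied: a GTG start codon is rendered as V and a TTG start
#' as L, so the protein row reflects the codon content (display helpers mark
#' start-capable codons separately). Codons containing ambiguity letters
#' translate to `X`.
#'
#' @param nt Nucleotide string, length a multiple of 3.
#' @return Amino-acid string (stops as `*`).
#' @export
translate_lorf <- function(nt) {
  stopifnot(is.character(nt), length(nt) == 1L, nchar(nt) %% 3 == 0)
  if (nchar(nt) == 0L) return("")
  aa <- unname(genetic_code_11()[codons_of(nt)])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# table 11 as a codon->residue lookup, fetched from Biostrings once per session
genetic_code_11 <- local({
  code <- NULL
  function() {
    if (is.null(code)) code <<- Biostrings::getGeneticCode("11")
    code
  }
})

codons_of <- function(nt) {
  n <- nchar(nt)
  if (n < 3L) return(character(0))
  substring(nt, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}

revcomp <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

#' Construct a LORF record
#'
#' A LORF record holds the longest open reading frame of a gene on its sense
#' strand: the nucleotide sequence starts at the LORF's first codon and ends
#' with the gene's stop codon, with no in-frame stop before the final codon.
#'
#' @param id Sequence identifier (unique within a family).
#' @param nt Sense-strand nucleotide sequence (uppercase), length a multiple
#'   of 3, terminal codon a stop, no internal in-frame stop.
#' @param aa Optional translation; computed from `nt` when `NULL` and checked
#'   against it otherwise.
#' @param gene_start_offset Optional 0-based offset of the annotated (or true)
#'   gene start within `nt`; must be frame 0 and an ATG/GTG/TTG codon.
#' @param upstream_gene_end_offset Optional 0-based offset (possibly negative
#'   or beyond the start) of the exclusive 3' end of the nearest same-strand
#'   upstream gene, relative to the first base of `nt`.
#' @param source Free-text provenance.
#' @return An object of class `lorf_record`.
#' @examples
#' lorf_record("q", "ATGGCTTAA")
#' @export
lorf_record <- function(id, nt, aa = NULL, gene_start_offset = NULL,
                        upstream_gene_end_offset = NULL, source = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(nt), length(nt) == 1L)
  nt <- toupper(nt)
  if (nchar(nt) %% 3 != 0 || nchar(nt) < 3L)
    stop("lorf_record: 'nt' must be a non-empty multiple of 3 (", id, ")")
  cods <- codons_of(nt)
  internal <- cods[-length(cods)]
  if (any(internal %in% STOP_CODONS))
    stop("lorf_record: in-frame stop codon before the final codon (", id, ")")
  trans <- translate_lorf(nt)
  if (is.null(aa)) {
    aa <- trans
  } else if (!identical(toupper(aa), trans)) {
    stop("lorf_record: 'aa' does not match the translation of 'nt' (", id, ")")
  }
  if (!is.null(gene_start_offset)) {
    gene_start_offset <- as.integer(gene_start_offset)
    if (gene_start_offset %% 3L != 0L ||
        gene_start_offset < 0L || gene_start_offset > nchar(nt) - 3L)
      stop("lorf_record: gene_start_offset must be an in-range frame-0 offset (", id, ")")
    cod <- substr(nt, gene_start_offset + 1L, gene_start_offset + 3L)
    if (!cod %in% START_CODONS)
      stop("lorf_record: codon at gene_start_offset is ", cod,
           ", not ATG/GTG/TTG (", id, ")")
  }
  structure(
    list(
      id = id, nt = nt, aa = aa,
      gene_start_offset = if (is.null(gene_start_offset)) NA_integer_ else gene_start_offset,
      upstream_gene_end_offset = if (is.null(upstream_gene_end_offset)) NA_integer_
                                 else as.integer(upstream_gene_end_offset),
      source = source
    ),
    class = "lorf_record"
  )
}

#' @export
print.lorf_record <- function(x, ...) {
  cat(sprintf("<lorf_record> %s: %d nt (%d codons)\n", x$id, nchar(x$nt), nchar(x$nt) / 3))
  if (!is.na(x$gene_start_offset))
    cat(sprintf("  gene start offset: %d (%s)\n", x$gene_start_offset,
                substr(x$nt, x$gene_start_offset + 1, x$gene_start_offset + 3)))
  if (!is.na(x$upstream_gene_end_offset))
    cat(sprintf("  upstream gene 3' end offset: %d\n", x$upstream_gene_end_offset))
  invisible(x)
}

#' Extract the longest open reading frame ending at a gene 3' end
#'
#' Starting from the stop codon that terminates a gene, walks upstream in
#' frame until the first in-frame stop codon (exclusive) or the sequence edge,
#' and returns the resulting LORF on the gene's sense strand.
#'
#' @param seq Genomic nucleotide string.
#' @param gene_end For `strand = "+"`, the 0-based exclusive 3' coordinate of
#'   the gene (one past the last base of the stop codon). For `strand = "-"`,
#'   the 0-based inclusive genomic coordinate of the leftmost base of the gene
#'   (i.e. the 3'-most base on the minus strand); internally the sequence is
#'   reverse-complemented and the same walk is performed.
#' @param strand `"+"` or `"-"`.
#' @param id Identifier for the resulting record.
#' @param annotated_start Optional 0-based genomic offset (sense-strand
#'   coordinates after orientation, i.e. offset within the oriented sequence)
#'   of an annotated gene start; stored as `gene_start_offset` relative to the
#'   LORF.
#' @return A [lorf_record()]; the attribute `lorf_bounds` carries the 0-based
#'   half-open interval of the LORF in oriented-sequence coordinates.
#' @examples
#' s <- paste0("CCTAA", "ATGAAACCC", "TAA") # upstream stop, gene, stop
#' extract_lorf(s, nchar(s), "+", id = "g")
#' @export
extract_lorf <- function(seq, gene_end, strand = c("+", "-"), id = "query",
                         annotated_start = NULL) {
  strand <- match.arg(strand)
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  L <- nchar(seq)
  gene_end <- as.integer(gene_end)
  if (strand == "-") {
    stopifnot(gene_end >= 0L, gene_end < L)
    seq <- revcomp(seq)
    gene_end <- L - gene_end
  }
  if (gene_end < 3L || gene_end > L)
    stop("extract_lorf: gene_end out of range")
  stop_cod <- substr(seq, gene_end - 2L, gene_end)
  if (!stop_cod %in% STOP_CODONS)
    stop("extract_lorf: no stop codon ends at gene_end (found ", stop_cod, ")")
  # walk upstream in frame; LORF begins after the first upstream in-frame stop
  lorf_start <- gene_end - 3L # 0-based offset of the terminal stop codon
  p <- lorf_start - 3L
  while (p >= 0L && !substr(seq, p + 1L, p + 3L) %in% STOP_CODONS) {
    lorf_start <- p
    p <- p - 3L
  }
  nt <- substr(seq, lorf_start + 1L, gene_end)
  if (nchar(nt) < 6L)
    stop("extract_lorf: LORF shorter than one codon plus stop")
  gso <- NULL
  if (!is.null(annotated_start)) {
    gso <- as.integer(annotated_start) - lorf_start
    if (gso < 0L) stop("extract_lorf: annotated_start upstream of the LORF")
  }
  rec <- lorf_record(id, nt, gene_start_offset = gso,
                     source = paste0("extract_lorf:", strand))
  attr(rec, "lorf_bounds") <- c(lorf_start, gene_end)
  rec
}

#' List start-codon candidates of a LORF
#'
#' All frame-0 occurrences of ATG, GTG or TTG in the record's nucleotide
#' sequence, in 5' to 3' order. The terminal stop codon cannot be a candidate;
#' codons containing ambiguity letters never qualify.
#'
#' @param lorf A [lorf_record()].
#' @return A tibble with columns `seq_offset` (0-based, frame 0) and `codon`.
#' @examples
#' list_start_candidates(lorf_record("q", "ATGGTGTAA"))
#' @export
list_start_candidates <- function(lorf) {
  stopifnot(inherits(lorf, "lorf_record"))
  cods <- codons_of(lorf$nt)
  hit <- cods %in% START_CODONS
  tibble(
    seq_offset = (which(hit) - 1L) * 3L,
    codon = cods[hit]
  )
}

#' Render a protein row with start-capable codon notation
#'
#' Uppercase M/V/L mark codons that can initiate translation (ATG/GTG/TTG);
#' lowercase `v`/`l` mark valine/leucine encoded by non-start codons. All other
#' residues are uppercase.
#'
#' @param nt Nucleotide string (multiple of 3, may be the ungapped row of an
#'   alignment).
#' @return A character scalar of per-codon symbols.
#' @export
display_protein <- function(nt) {
  cods <- codons_of(nt)
  aa <- strsplit(translate_lorf(nt), "")[[1]]
  aa[cods %in% NONSTART_VL_CODONS] <- tolower(aa[cods %in% NONSTART_VL_CODONS])
  paste(aa, collapse = "")
}
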