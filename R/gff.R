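#' Read gene calls from a GFF3 file
#'
#' Imports CDS (or other) features and converts them to a [gene_calls()]
#' table. Coordinates stay 1-based inclusive as in GFF3.
#'
#' @param path GFF3 file.
#' @param feature_type Feature types to keep (default `"CDS"`; `NULL` keeps
#'   everything).
#' @return A `gene_calls` tibble; extra attribute columns `step`, `s5`,
#'   `s_blk` are carried along when present.
#' @export
read_gene_calls_gff3 <- function(path, feature_type = "CDS") {
  gr <- rtracklayer::import(path, format = "gff3")
  if (!is.null(feature_type)) {
    gr <- gr[as.character(gr$type) %in% feature_type]
  }
  md <- as.data.frame(S4Vectors::mcols(gr))
  extra <- list()
  for (col in c("step", "s5", "s_blk")) {
    if (col %in% names(md)) extra[[col]] <- md[[col]]
  }
  do.call(gene_calls, c(
    list(
      seq_id = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr)
    ),
    extra
  ))
}

#' Write gene calls to a GFF3 file
#'
#' Emits one CDS feature per call; columns `step`, `s5`, `s_blk` (when
#' present) become GFF3 attributes so that the producing selection step and
#' its scores travel with each prediction.
#'
#' @param calls A gene-call table.
#' @param path Output file.
#' @param source Value of the GFF3 source column.
#' @return Invisibly, `path`.
#' @export
write_gene_calls_gff3 <- function(calls, path, source = "startfinder") {
  calls <- as_gene_calls(calls)
  gr <- GenomicRanges::GRanges(
    seqnames = calls$seq_id,
    ranges = IRanges::IRanges(start = calls$start, end = calls$end),
    strand = calls$strand
  )
  gr$source <- source
  gr$type <- "CDS"
  gr$phase <- 0L # calls start at a codon boundary by construction
  for (col in c("step", "s5", "s_blk")) {
    # all-NA attributes (e.g. s5 for a step-A prediction) are omitted
    if (col %in% names(calls) && !all(is.na(calls[[col]])))
      S4Vectors::mcols(gr)[[col]] <- calls[[col]]
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
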