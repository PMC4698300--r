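#' Read a gene annotation (BED12 or tabular)
#'
#' Gene models carry the gene span, a type (coding, pseudogene, miRNA,
#' lncRNA), exon intervals and a transcript length in kb. For BED12 input the
#' exons come from the block fields and the transcript length is the summed
#' exon length; for tabular input without exon columns the exons default to
#' the full span (with a warning).
#'
#' Tabular format (TSV with header):
#' `symbol chrom start end gene_type exon_starts exon_ends` with
#' comma-separated absolute 0-based exon coordinates; an optional `tx_kb`
#' column overrides the computed transcript length.
#'
#' @param source File path.
#' @param format `"auto"` (by extension), `"bed12"` or `"tsv"`.
#' @return data.frame of class `gene_annotation`: `symbol`, `chrom`, `start`,
#'   `end`, `gene_type`, list-columns `exon_start`/`exon_end`, and `tx_kb`.
#' @export
read_annotation <- function(source, format = c("auto", "bed12", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", source, ignore.case = TRUE)) "bed12" else "tsv"
  }
  if (format == "bed12") {
    gr <- rtracklayer::import(source, format = "bed")
    if (!length(gr)) return(.empty_annotation())
    blocks <- rtracklayer::blocks(gr)  # absolute, 1-based closed
    ann <- data.frame(
      symbol = if (!is.null(gr$name)) gr$name else paste0("gene", seq_along(gr)),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,
      end = GenomicRanges::end(gr),
      gene_type = "coding",
      stringsAsFactors = FALSE
    )
    ann$exon_start <- lapply(blocks, function(b) GenomicRanges::start(b) - 1)
    ann$exon_end <- lapply(blocks, function(b) GenomicRanges::end(b))
  } else {
    raw <- utils::read.delim(source, stringsAsFactors = FALSE)
    if (nrow(raw) == 0) return(.empty_annotation())
    required <- c("symbol", "chrom", "start", "end")
    missing_cols <- setdiff(required, names(raw))
    if (length(missing_cols)) {
      .stopf("annotation missing columns: %s", paste(missing_cols, collapse = ", "))
    }
    ann <- data.frame(
      symbol = raw$symbol, chrom = raw$chrom,
      start = as.numeric(raw$start), end = as.numeric(raw$end),
      gene_type = if ("gene_type" %in% names(raw)) raw$gene_type else "coding",
      stringsAsFactors = FALSE
    )
    if (all(c("exon_starts", "exon_ends") %in% names(raw))) {
      ann$exon_start <- lapply(strsplit(as.character(raw$exon_starts), ","),
                               as.numeric)
      ann$exon_end <- lapply(strsplit(as.character(raw$exon_ends), ","),
                             as.numeric)
    } else {
      warning("annotation has no exon columns; exons default to the full gene span")
      ann$exon_start <- as.list(ann$start)
      ann$exon_end <- as.list(ann$end)
    }
    if ("tx_kb" %in% names(raw)) ann$tx_kb <- as.numeric(raw$tx_kb)
  }
  # validate exon structure against the span
  for (i in seq_len(nrow(ann))) {
    es <- ann$exon_start[[i]]; ee <- ann$exon_end[[i]]
    if (length(es) != length(ee) || any(es >= ee) ||
        any(es < ann$start[i]) || any(ee > ann$end[i])) {
      .stopf("gene '%s': exon structure inconsistent with gene span",
             ann$symbol[i])
    }
  }
  if (is.null(ann$tx_kb)) {
    ann$tx_kb <- vapply(seq_len(nrow(ann)), function(i) {
      sum(ann$exon_end[[i]] - ann$exon_start[[i]]) / 1000
    }, 0)
  }
  if (any(ann$tx_kb <= 0)) {
    .stopf("non-positive transcript length for gene(s): %s",
           paste(ann$symbol[ann$tx_kb <= 0], collapse = ", "))
  }
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

.empty_annotation <- function() {
  ann <- data.frame(symbol = character(), chrom = character(),
                    start = numeric(), end = numeric(),
                    gene_type = character(), stringsAsFactors = FALSE)
  ann$exon_start <- list()
  ann$exon_end <- list()
  ann$tx_kb <- numeric()
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Write a gene annotation in the package's tabular format
#'
#' @param annotation A `gene_annotation` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  out <- data.frame(
    symbol = annotation$symbol, chrom = annotation$chrom,
    start = annotation$start, end = annotation$end,
    gene_type = annotation$gene_type,
    exon_starts = vapply(annotation$exon_start,
                         function(v) paste(.fmt_int(v), collapse = ","), ""),
    exon_ends = vapply(annotation$exon_end,
                       function(v) paste(.fmt_int(v), collapse = ","), ""),
    tx_kb = annotation$tx_kb,
    stringsAsFactors = FALSE
  )
  .write_tsv(out, path)
}
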