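# Internal helpers shared across modules.

# Convert a 0-based half-open interval data.frame (chrom/start/end) into a
# GRanges (1-based closed). The inverse shift happens only in writers.
.as_gr <- function(df, genome = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end)
  )
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- names(genome$chrom_sizes)
    GenomeInfoDb::seqlengths(gr) <- unname(genome$chrom_sizes)
  }
  gr
}

.gr_as_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

# Non-scientific integer formatting for deterministic text output.
.fmt_int <- function(x) format(x, scientific = FALSE, trim = TRUE)

.write_tsv <- function(df, path) {
  for (nm in names(df)) {
    if (is.list(df[[nm]])) {
      df[[nm]] <- vapply(df[[nm]], function(v) paste(v, collapse = ";"), "")
    }
    if (is.numeric(df[[nm]]) && all(df[[nm]] == round(df[[nm]]), na.rm = TRUE)) {
      df[[nm]] <- .fmt_int(df[[nm]])
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
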