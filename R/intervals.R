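#' Segment CNV intervals into maximal constant-depth regions
#'
#' Partitions the union of the input intervals into maximal segments on which
#' both the coverage depth and the set of covering intervals are constant
#' (the `disjoin` semantics). Depth counts intervals, not distinct patients:
#' a patient with two tandem CNVs over a segment contributes 2 to its depth
#' but appears once among contributors (see [collapse_contributors()]).
#' Segments with depth 0 (gaps between CNVs) are not emitted.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open); typically the `cnvs` table of a cohort.
#' @param genome Optional [genome_build()] used to validate chromosomes.
#' @return data.frame `chrom`, `start`, `end`, `depth`, sorted by genome (or
#'   lexicographic) chromosome order then start.
#' @export
coverage_segments <- function(intervals, genome = NULL) {
  if (nrow(intervals) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      depth = integer(), stringsAsFactors = FALSE))
  }
  if (!is.null(genome)) {
    bad <- setdiff(unique(intervals$chrom), names(genome$chrom_sizes))
    if (length(bad)) {
      .stopf("intervals on chromosomes absent from genome: %s",
             paste(bad, collapse = ", "))
    }
  }
  gr <- .as_gr(intervals)
  seg <- GenomicRanges::disjoin(gr)
  depth <- GenomicRanges::countOverlaps(seg, gr)
  out <- .gr_as_df(seg)
  out$depth <- depth
  ord <- if (is.null(genome)) order(out$chrom, out$start) else
    order(match(out$chrom, names(genome$chrom_sizes)), out$start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate overlap regions with contributing patient ids
#'
#' For each region, collects the distinct `patient_id`s of input intervals
#' overlapping it. A patient contributing two intervals over one region is
#' listed once (depth still counts both intervals).
#'
#' @param regions Output of [coverage_segments()].
#' @param intervals The interval table the regions were derived from; must
#'   carry a `patient_id` column.
#' @return `regions` with a `patient_ids` list-column of character vectors.
#' @export
collapse_contributors <- function(regions, intervals) {
  stopifnot("patient_id" %in% names(intervals))
  if (nrow(regions) == 0) {
    regions$patient_ids <- list()
    return(regions)
  }
  if (length(setdiff(unique(regions$chrom), unique(intervals$chrom)))) {
    .stopf("region chromosome absent from the interval set")
  }
  hits <- GenomicRanges::findOverlaps(.as_gr(regions), .as_gr(intervals))
  ids <- split(intervals$patient_id[S4Vectors::subjectHits(hits)],
               factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(regions))))
  regions$patient_ids <- unname(lapply(ids, function(v) sort(unique(v))))
  regions
}

#' Tile a genome into fixed-size windows
#'
#' Windows are tiled per chromosome from position 0; the last window of a
#' chromosome may be shorter than `window_size` (remainder kept). Windows
#' overlapping any excluded interval of the genome (assembly gaps etc.) are
#' removed to avoid biased variant counts. `index` numbers the retained
#' windows consecutively in genome scan order.
#'
#' @param genome A [genome_build()].
#' @param window_size Window width in bp (default 1 Mb).
#' @return data.frame `chrom`, `start`, `end`, `index`.
#' @export
make_windows <- function(genome, window_size = 1e6) {
  stopifnot(window_size > 0)
  per_chrom <- lapply(names(genome$chrom_sizes), function(ch) {
    len <- genome$chrom_sizes[[ch]]
    starts <- seq(0, len - 1, by = window_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_size, len),
               stringsAsFactors = FALSE)
  })
  win <- do.call(rbind, per_chrom)
  if (nrow(genome$excluded)) {
    drop <- IRanges::overlapsAny(.as_gr(win), .as_gr(genome$excluded))
    win <- win[!drop, , drop = FALSE]
  }
  win$index <- seq_len(nrow(win))
  rownames(win) <- NULL
  win
}

#' Count features overlapping each window
#'
#' Any-overlap convention: a feature overlapping a window by >= 1 bp is
#' counted; a feature spanning two windows increments both.
#'
#' @param windows Output of [make_windows()] (or any interval data.frame).
#' @param features data.frame with `chrom`, `start`, `end`.
#' @return `windows` with an integer `count` column.
#' @export
count_window_overlaps <- function(windows, features) {
  if (nrow(windows) == 0) {
    windows$count <- integer()
    return(windows)
  }
  windows$count <- if (nrow(features) == 0) 0L else
    GenomicRanges::countOverlaps(.as_gr(windows), .as_gr(features))
  windows
}

#' Genes overlapping a genomic interval
#'
#' @param interval Single-row data.frame (or list) with `chrom`, `start`,
#'   `end`, 0-based half-open.
#' @param annotation A `gene_annotation` from [read_annotation()].
#' @param mode `"any"` (default; >= 1 bp overlap counts, matching region
#'   queries of genome-browser tables) or `"contained"` (gene fully inside
#'   the interval).
#' @return The matching annotation rows in genomic order.
#' @export
genes_in_interval <- function(interval, annotation, mode = c("any", "contained")) {
  mode <- match.arg(mode)
  if (nrow(annotation) == 0) return(annotation)
  iv <- as.data.frame(interval)[1, c("chrom", "start", "end")]
  hit <- annotation$chrom == iv$chrom &
    (if (mode == "any") annotation$start < iv$end & annotation$end > iv$start
     else annotation$start >= iv$start & annotation$end <= iv$end)
  out <- annotation[hit, , drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}
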