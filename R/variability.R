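#' Read a structural-variant catalog
#'
#' TSV with header `chrom  start  end  variant_type` (a DGV-export compatible
#' column subset); coordinates 0-based half-open. `loss` rows are deletions,
#' `gain` rows duplications; rows with any other type (inversions etc.) are
#' dropped with a message.
#'
#' @param path File path.
#' @return data.frame `chrom`, `start`, `end`, `variant_type` (loss/gain
#'   only); attribute `n_dropped` counts discarded rows.
#' @export
read_sv_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("chrom", "start", "end", "variant_type")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    .stopf("catalog missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  keep <- df$variant_type %in% c("loss", "gain")
  n_dropped <- sum(!keep)
  if (n_dropped) {
    message(sprintf("dropping %d catalog rows with variant types other than loss/gain",
                    n_dropped))
  }
  out <- df[keep, required]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Windowed variant-density z-scores
#'
#' The genomic variability score of a window is the z-score of the base-10
#' logarithm of its variant count: with retained windows (count > 0) indexed
#' by i, `mu = mean(log10(c_i))`, `sigma` the sample SD (n - 1 denominator)
#' and `z_i = (log10(c_i) - mu) / sigma`. Zero-count windows carry no log
#' and are excluded from the retained set with a recorded count; the log
#' conversion approximates a normal-like distribution of counts.
#'
#' @param windows_with_counts Output of [count_window_overlaps()] on
#'   gap-filtered windows.
#' @return data.frame of retained windows with `log_count` and `z` columns;
#'   attributes `mu`, `sigma`, `n_zero_dropped`.
#' @export
window_zscores <- function(windows_with_counts) {
  stopifnot("count" %in% names(windows_with_counts))
  zero <- windows_with_counts$count == 0
  keep <- windows_with_counts[!zero, , drop = FALSE]
  if (nrow(keep) < 2) .stopf("fewer than 2 windows with variants; cannot standardize")
  keep$log_count <- log10(keep$count)
  mu <- mean(keep$log_count)
  sigma <- stats::sd(keep$log_count)
  if (sigma == 0) .stopf("degenerate catalog: all window counts identical")
  keep$z <- (keep$log_count - mu) / sigma
  rownames(keep) <- NULL
  attr(keep, "mu") <- mu
  attr(keep, "sigma") <- sigma
  attr(keep, "n_zero_dropped") <- sum(zero)
  keep
}

#' Variability z-score of regions or genes
#'
#' For each query interval, averages the raw variant counts of the retained
#' windows it overlaps, then standardizes `log10(mean count)` with the
#' genome-wide `mu` and `sigma` of [window_zscores()]. A query overlapping
#' no retained window (e.g. a candidate in an excluded telomeric window) is
#' not assessable and scores `NA`.
#'
#' @param query data.frame with `chrom`, `start`, `end` (one or more rows).
#' @param scored_windows Output of [window_zscores()].
#' @return Numeric vector of z-scores (NA where not assessable).
#' @export
region_variability <- function(query, scored_windows) {
  mu <- attr(scored_windows, "mu"); sigma <- attr(scored_windows, "sigma")
  stopifnot(!is.null(mu), !is.null(sigma))
  if (nrow(query) == 0) return(numeric())
  hits <- GenomicRanges::findOverlaps(.as_gr(query), .as_gr(scored_windows))
  counts <- split(scored_windows$count[S4Vectors::subjectHits(hits)],
                  factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(query))))
  unname(vapply(counts, function(v) {
    if (!length(v)) return(NA_real_)
    (log10(mean(v)) - mu) / sigma
  }, 0))
}

#' Genic and exonic CNV burden of genes in a variant catalog
#'
#' Counts catalog variants overlapping each gene span (genic) and overlapping
#' any of its exons (exonic), separately for losses (deletions) and gains
#' (duplications). A variant lying entirely in introns increments the genic
#' but not the exonic count.
#'
#' @param annotation A `gene_annotation`.
#' @param catalog data.frame from [read_sv_catalog()].
#' @return data.frame `gene`, `n_genic_del`, `n_exonic_del`, `n_genic_dup`,
#'   `n_exonic_dup`.
#' @export
gene_cnv_burden <- function(annotation, catalog) {
  n <- nrow(annotation)
  out <- data.frame(gene = annotation$symbol,
                    n_genic_del = integer(n), n_exonic_del = integer(n),
                    n_genic_dup = integer(n), n_exonic_dup = integer(n),
                    stringsAsFactors = FALSE)
  if (n == 0 || nrow(catalog) == 0) return(out)
  exon_df <- data.frame(
    chrom = rep(annotation$chrom, lengths(annotation$exon_start)),
    start = unlist(annotation$exon_start),
    end = unlist(annotation$exon_end),
    gene_idx = rep(seq_len(n), lengths(annotation$exon_start)),
    stringsAsFactors = FALSE
  )
  for (vt in c("loss", "gain")) {
    vars <- catalog[catalog$variant_type == vt, , drop = FALSE]
    genic <- if (nrow(vars)) GenomicRanges::countOverlaps(.as_gr(annotation),
                                                          .as_gr(vars)) else integer(n)
    exonic <- integer(n)
    if (nrow(vars) && nrow(exon_df)) {
      hits <- GenomicRanges::findOverlaps(.as_gr(exon_df), .as_gr(vars))
      # a variant touching several exons of one gene counts once
      pairs <- unique(data.frame(
        gene = exon_df$gene_idx[S4Vectors::queryHits(hits)],
        var = S4Vectors::subjectHits(hits)))
      tab <- table(factor(pairs$gene, levels = seq_len(n)))
      exonic <- as.integer(tab)
    }
    if (vt == "loss") {
      out$n_genic_del <- as.integer(genic); out$n_exonic_del <- exonic
    } else {
      out$n_genic_dup <- as.integer(genic); out$n_exonic_dup <- exonic
    }
  }
  out
}

#' Flag hypervariable windows
#'
#' Hypervariable regions are windows of exceptionally high population
#' variant density. No universal numeric z cutoff exists, so the flag is
#' quantile-based: windows whose z-score strictly exceeds the given quantile
#' of the z distribution are flagged.
#'
#' @param z Numeric vector of window z-scores.
#' @param quantile Probability defining the flag threshold (default 0.999).
#' @return Logical vector parallel to `z`.
#' @export
hypervariable_flag <- function(z, quantile = 0.999) {
  stopifnot(quantile > 0, quantile < 1)
  z > stats::quantile(z, quantile, na.rm = TRUE, names = FALSE)
}
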