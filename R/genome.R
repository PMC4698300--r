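#' Construct a genome build
#'
#' A genome build is the coordinate frame of the analysis: an ordered set of
#' chromosomes with lengths, plus a merged set of excluded intervals (assembly
#' gaps, alternative haplotypes, random contigs) that interval shuffling and
#' window tiling must avoid.
#'
#' @param name Text label, e.g. `"GRCh37"`.
#' @param chromosomes Named numeric vector of chromosome lengths in bp, or a
#'   two-column data.frame (`name`, `length`).
#' @param excluded Optional data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) of intervals to exclude. Overlapping or adjacent
#'   intervals are merged.
#' @return An object of class `genome_build` with elements `name`,
#'   `chrom_sizes` (named numeric) and `excluded` (merged data.frame).
#' @export
genome_build <- function(name, chromosomes, excluded = NULL) {
  if (is.data.frame(chromosomes)) {
    chrom_sizes <- stats::setNames(as.numeric(chromosomes[[2]]),
                                   as.character(chromosomes[[1]]))
  } else {
    chrom_sizes <- chromosomes
  }
  if (is.null(names(chrom_sizes)) || anyNA(chrom_sizes)) {
    .stopf("chromosomes must be a named numeric vector or two-column table")
  }
  if (any(chrom_sizes <= 0)) {
    .stopf("chromosome lengths must be > 0 (offending: %s)",
           paste(names(chrom_sizes)[chrom_sizes <= 0], collapse = ", "))
  }
  if (anyDuplicated(names(chrom_sizes))) {
    .stopf("duplicated chromosome names")
  }
  if (is.null(excluded) || nrow(excluded) == 0) {
    excluded <- data.frame(chrom = character(), start = numeric(),
                           end = numeric(), stringsAsFactors = FALSE)
  } else {
    bad_chrom <- setdiff(unique(excluded$chrom), names(chrom_sizes))
    if (length(bad_chrom)) {
      .stopf("excluded intervals on chromosomes absent from the genome: %s",
             paste(bad_chrom, collapse = ", "))
    }
    out_of_bounds <- excluded$start < 0 |
      excluded$end > chrom_sizes[as.character(excluded$chrom)]
    if (any(out_of_bounds)) {
      .stopf("excluded interval outside chromosome bounds: %s",
             paste(sprintf("%s:%s-%s", excluded$chrom[out_of_bounds],
                           .fmt_int(excluded$start[out_of_bounds]),
                           .fmt_int(excluded$end[out_of_bounds])),
                   collapse = ", "))
    }
    if (any(excluded$start >= excluded$end)) {
      .stopf("excluded interval with start >= end")
    }
    merged <- GenomicRanges::reduce(.as_gr(excluded))
    excluded <- .gr_as_df(merged)
    excluded <- excluded[order(match(excluded$chrom, names(chrom_sizes)),
                               excluded$start), , drop = FALSE]
    rownames(excluded) <- NULL
  }
  structure(
    list(name = name, chrom_sizes = chrom_sizes, excluded = excluded),
    class = "genome_build"
  )
}

#' Read a genome definition from chrom.sizes and exclusion BED files
#'
#' @param chrom_sizes_source Path to a two-column whitespace-delimited file
#'   (chromosome name, length in bp), UCSC `chrom.sizes` style.
#' @param exclusions_source Optional path to a BED3 file of excluded intervals
#'   (assembly gaps, haplotype contigs, ...), 0-based half-open.
#' @param name Label for the build.
#' @return A [genome_build()] object.
#' @export
read_genome <- function(chrom_sizes_source, exclusions_source = NULL,
                        name = "custom") {
  lines <- readLines(chrom_sizes_source)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(fields, length, 0L) < 2 |
                 is.na(suppressWarnings(
                   as.numeric(vapply(fields, function(f) f[2], "")))))
  if (length(bad)) {
    .stopf("malformed chrom.sizes line %d: '%s'", bad[1], lines[bad[1]])
  }
  chrom_sizes <- stats::setNames(
    as.numeric(vapply(fields, function(f) f[2], "")),
    vapply(fields, function(f) f[1], "")
  )
  excluded <- NULL
  if (!is.null(exclusions_source)) {
    excluded <- read_bed3(exclusions_source)
  }
  genome_build(name, chrom_sizes, excluded)
}

#' Read a BED3 file
#'
#' @param path BED file path (0-based half-open, at least 3 columns).
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
read_bed3 <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "track") &
    !startsWith(lines, "#")
  lines <- lines[keep]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\\s+")
  n_ok <- vapply(fields, length, 0L) >= 3
  if (!all(n_ok)) {
    .stopf("malformed BED line %d: '%s'", which(!n_ok)[1], lines[!n_ok][1])
  }
  df <- data.frame(
    chrom = vapply(fields, `[`, "", 1),
    start = suppressWarnings(as.numeric(vapply(fields, `[`, "", 2))),
    end = suppressWarnings(as.numeric(vapply(fields, `[`, "", 3))),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$start) || anyNA(df$end)) {
    bad <- which(is.na(df$start) | is.na(df$end))[1]
    .stopf("malformed BED line %d: non-numeric coordinates", bad)
  }
  df
}

#' Gap-free placeable stretches of a genome
#'
#' Returns the complement of the excluded intervals within chromosome bounds:
#' the space where shuffled or simulated CNVs may be placed.
#'
#' @param genome A [genome_build()].
#' @return data.frame `chrom`, `start`, `end` (0-based half-open), genome order.
#' @export
legal_space <- function(genome) {
  stopifnot(inherits(genome, "genome_build"))
  out <- lapply(names(genome$chrom_sizes), function(ch) {
    len <- genome$chrom_sizes[[ch]]
    exc <- genome$excluded[genome$excluded$chrom == ch, , drop = FALSE]
    if (nrow(exc) == 0) {
      return(data.frame(chrom = ch, start = 0, end = len,
                        stringsAsFactors = FALSE))
    }
    # merged and sorted by construction in genome_build
    starts <- c(0, exc$end)
    ends <- c(exc$start, len)
    keep <- starts < ends
    data.frame(chrom = ch, start = starts[keep], end = ends[keep],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.genome_build <- function(x, ...) {
  cat(sprintf("genome build '%s': %d chromosomes, %s bp, %d excluded intervals\n",
              x$name, length(x$chrom_sizes),
              .fmt_int(sum(x$chrom_sizes)), nrow(x$excluded)))
  invisible(x)
}
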