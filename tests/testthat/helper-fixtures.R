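# Fixture builders and independent brute-force oracles used across tests.

toy_genome <- function(lengths = c(chrA = 1e6, chrB = 5e5), excluded = NULL) {
  genome_build("toy", lengths, excluded)
}

# random interval set on a small genome, 0-based half-open
random_intervals <- function(n, chrom_len = 1e4, chroms = "chrA",
                             max_len = 500) {
  chrom <- sample(chroms, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i)
    sample.int(chrom_len - len[i], 1) - 1, 0)
  data.frame(patient_id = sprintf("P%02d", sample.int(max(3, n %/% 2), n,
                                                      replace = TRUE)),
             cnv_type = "deletion", chrom = chrom,
             start = as.numeric(start), end = as.numeric(start + len),
             stringsAsFactors = FALSE)
}

# oracle: per-base depth array of an interval set on one chromosome
depth_by_base <- function(intervals, chrom, chrom_len) {
  depth <- integer(chrom_len)
  sel <- intervals[intervals$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(sel))) {
    idx <- (sel$start[i] + 1):sel$end[i]
    depth[idx] <- depth[idx] + 1L
  }
  depth
}

# oracle: expand segment table back to a per-base depth array
segments_to_bases <- function(regions, chrom, chrom_len) {
  depth <- integer(chrom_len)
  sel <- regions[regions$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(sel))) {
    idx <- (sel$start[i] + 1):sel$end[i]
    depth[idx] <- depth[idx] + sel$depth[i]
  }
  depth
}

overlaps_0based <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

# oracle: all-pairs membership of patients per region
contributors_oracle <- function(regions, intervals) {
  lapply(seq_len(nrow(regions)), function(r) {
    hit <- vapply(seq_len(nrow(intervals)), function(i) {
      intervals$chrom[i] == regions$chrom[r] &&
        overlaps_0based(intervals$start[i], intervals$end[i],
                        regions$start[r], regions$end[r])
    }, TRUE)
    sort(unique(intervals$patient_id[hit]))
  })
}

# oracle: naive double-loop window overlap counts
count_oracle <- function(windows, features) {
  vapply(seq_len(nrow(windows)), function(w) {
    sum(vapply(seq_len(nrow(features)), function(f) {
      features$chrom[f] == windows$chrom[w] &&
        overlaps_0based(features$start[f], features$end[f],
                        windows$start[w], windows$end[w])
    }, TRUE))
  }, 0L)
}

# oracle: exhaustive hypergeometric tail by enumerating all C(N, n) draws
hyper_enum <- function(N, K, n, k, strict = FALSE) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # panel = elements 1..K
  if (strict) mean(hits > k) else mean(hits >= k)
}

# oracle: recursive ancestor closure in a parent-list DAG
ancestors_oracle <- function(term, parents) {
  direct <- parents[[term]]
  if (is.null(direct)) return(term)
  unique(c(term, unlist(lapply(direct, ancestors_oracle, parents = parents))))
}

# one small expression table
toy_expression <- function() {
  data.frame(
    gene = c("A", "A", "B", "C"),
    transcript_id = c("A_T1", "A_T2", "B_T1", "C_T1"),
    length_kb = c(2, 1, 4, 0.5),
    stage = c("E10", "E10", "E12", "E14"),
    normalized_count = c(118, 30, 0, 25),
    stringsAsFactors = FALSE
  )
}

# annotation data.frame from simple vectors (single exon = full span unless given)
toy_annotation <- function(symbol, chrom, start, end,
                           exon_start = NULL, exon_end = NULL) {
  ann <- data.frame(symbol = symbol, chrom = chrom, start = start, end = end,
                    gene_type = "coding", stringsAsFactors = FALSE)
  ann$exon_start <- if (is.null(exon_start)) as.list(start) else exon_start
  ann$exon_end <- if (is.null(exon_end)) as.list(end) else exon_end
  ann$tx_kb <- vapply(seq_len(nrow(ann)), function(i)
    sum(ann$exon_end[[i]] - ann$exon_start[[i]]) / 1000, 0)
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

# shared synthetic bundle, generated once per test run
shared_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "cnvrecur-bundle")
      cache <<- generate_all(synthetic_spec(), dir, seed = 42)
    }
    cache
  }
})
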