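#' Read a normalized expression table
#'
#' TSV with header `gene  transcript_id  length_kb  stage  normalized_count`:
#' one row per transcript and developmental stage, carrying the normalized
#' count (e.g. from a count-based normalization upstream) and the transcript
#' length in kb.
#'
#' @param path File path.
#' @return data.frame with those columns.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene", "transcript_id", "length_kb", "stage", "normalized_count")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    .stopf("expression table missing columns: %s",
           paste(missing_cols, collapse = ", "))
  }
  df$length_kb <- as.numeric(df$length_kb)
  df$normalized_count <- as.numeric(df$normalized_count)
  df
}

#' Convert normalized counts to nRPK
#'
#' nRPK (normalized counts per kilobase of transcript) is the expression unit
#' of the prioritization cutoff: each transcript's normalized count divided
#' by its length in kb. Gene-level per-stage values aggregate transcripts by
#' maximum (the permissive reading of a `>= cutoff` test against any
#' isoform).
#'
#' @param expression data.frame from [read_expression()].
#' @return `expression` with an added `nrpk` column.
#' @export
compute_nrpk <- function(expression) {
  bad <- is.na(expression$length_kb) | expression$length_kb <= 0
  if (any(bad)) {
    .stopf("missing or non-positive transcript length for gene(s): %s",
           paste(unique(expression$gene[bad]), collapse = ", "))
  }
  expression$nrpk <- expression$normalized_count / expression$length_kb
  expression
}

#' Per-gene maximum nRPK across stages and transcripts
#'
#' @param expression data.frame with an `nrpk` column ([compute_nrpk()]).
#' @return Named numeric vector, gene -> max nRPK over all stages/transcripts.
#' @export
gene_max_nrpk <- function(expression) {
  stopifnot("nrpk" %in% names(expression))
  vapply(split(expression$nrpk, expression$gene), max, 0)
}

#' Expression cutoff: mean nRPK of expressed genes
#'
#' The prioritization cutoff is the mean nRPK over all records with nRPK > 0,
#' pooled across stages and transcripts (zero-expression records excluded).
#'
#' @param expression data.frame with `nrpk` ([compute_nrpk()]).
#' @return The cutoff value.
#' @export
expression_cutoff <- function(expression) {
  stopifnot("nrpk" %in% names(expression))
  pos <- expression$nrpk[expression$nrpk > 0]
  if (!length(pos)) .stopf("no expressed records (nrpk > 0); cannot derive a cutoff")
  mean(pos)
}

#' Count distinct patients whose CNVs overlap each gene
#'
#' @param cnvs CNV table (cohort `cnvs` data.frame).
#' @param annotation A `gene_annotation`.
#' @param cnv_type `"deletion"` or `"duplication"`.
#' @return Named integer vector over all annotation genes (0 when untouched).
#' @export
gene_patient_counts <- function(cnvs, annotation, cnv_type) {
  stopifnot(cnv_type %in% c("deletion", "duplication"))
  sel <- cnvs[cnvs$cnv_type == cnv_type, , drop = FALSE]
  counts <- stats::setNames(integer(nrow(annotation)), annotation$symbol)
  if (nrow(sel) == 0 || nrow(annotation) == 0) return(counts)
  hits <- GenomicRanges::findOverlaps(.as_gr(annotation), .as_gr(sel))
  by_gene <- split(sel$patient_id[S4Vectors::subjectHits(hits)],
                   S4Vectors::queryHits(hits))
  n <- vapply(by_gene, function(v) length(unique(v)), 0L)
  counts[as.integer(names(n))] <- n
  counts
}

#' Prioritization thresholds
#'
#' @param min_patients Minimum distinct patients whose CNVs overlap a gene
#'   (recurrence criterion; default 2).
#' @param max_genes_per_region Maximum number of genes in a supporting shared
#'   region (default 5).
#' @param nrpk_cutoff Expression cutoff; `NULL` (default) recomputes it from
#'   the supplied table via [expression_cutoff()]. The published analysis
#'   value is 59.00.
#' @param region_rule `"any"` (default): a gene passes the gene-count
#'   criterion if any supporting shared region containing it has at most
#'   `max_genes_per_region` genes; `"all"` requires every supporting region
#'   to.
#' @return A list of class `prioritization_config`.
#' @export
prioritization_config <- function(min_patients = 2, max_genes_per_region = 5,
                                  nrpk_cutoff = NULL,
                                  region_rule = c("any", "all")) {
  stopifnot(min_patients > 0, max_genes_per_region > 0,
            is.null(nrpk_cutoff) || nrpk_cutoff > 0)
  structure(list(min_patients = min_patients,
                 max_genes_per_region = max_genes_per_region,
                 nrpk_cutoff = nrpk_cutoff,
                 region_rule = match.arg(region_rule)),
            class = "prioritization_config")
}

#' Three-criterion candidate gene prioritization
#'
#' Starting from the universe of genes overlapped by at least one CNV of the
#' given type, applies in order: (1) recurrence — the gene is deleted or
#' duplicated in at least `min_patients` distinct patients; (2) regional gene
#' count — some shared overlap region (coverage depth >= 2) containing the
#' gene holds at most `max_genes_per_region` genes; (3) expression — the
#' gene's maximum nRPK across stages reaches the cutoff. Per-criterion flags
#' are retained for every universe gene so filter attrition is reportable.
#'
#' @param cnvs Cohort CNV table.
#' @param annotation A `gene_annotation`.
#' @param expression Expression table with `nrpk` ([compute_nrpk()]); genes
#'   absent from the table fail the expression criterion.
#' @param cnv_type `"deletion"` or `"duplication"`.
#' @param config A [prioritization_config()].
#' @return data.frame of class `candidate_table` with one row per universe
#'   gene: `gene`, `cnv_type`, `n_patients`, `min_region_gene_count`,
#'   `max_nrpk`, `pass_recurrence`, `pass_region`, `pass_expression`,
#'   `candidate`; attribute `attrition` carries the stepwise counts and
#'   attribute `nrpk_cutoff` the cutoff used.
#' @export
prioritize <- function(cnvs, annotation, expression, cnv_type,
                       config = prioritization_config()) {
  stopifnot(inherits(config, "prioritization_config"))
  sel <- cnvs[cnvs$cnv_type == cnv_type, , drop = FALSE]
  n_patients <- gene_patient_counts(cnvs, annotation, cnv_type)
  in_universe <- n_patients >= 1
  universe <- annotation[in_universe, , drop = FALSE]

  regions <- coverage_segments(sel)
  shared <- regions[regions$depth >= 2, , drop = FALSE]
  # genes per shared region, and per gene the supporting-region gene counts
  if (nrow(shared) && nrow(universe)) {
    region_gene_n <- GenomicRanges::countOverlaps(.as_gr(shared), .as_gr(universe))
    hits <- GenomicRanges::findOverlaps(.as_gr(universe), .as_gr(shared))
    per_gene <- split(region_gene_n[S4Vectors::subjectHits(hits)],
                      factor(S4Vectors::queryHits(hits),
                             levels = seq_len(nrow(universe))))
    min_region <- vapply(per_gene, function(v)
      if (length(v)) min(v) else NA_real_, 0)
    pass_region_fun <- if (config$region_rule == "any") min else max
    region_stat <- vapply(per_gene, function(v)
      if (length(v)) pass_region_fun(v) else NA_real_, 0)
  } else {
    min_region <- rep(NA_real_, nrow(universe))
    region_stat <- min_region
  }

  cutoff <- if (is.null(config$nrpk_cutoff)) expression_cutoff(expression)
            else config$nrpk_cutoff
  max_nrpk_all <- gene_max_nrpk(expression)
  max_nrpk <- unname(max_nrpk_all[universe$symbol])

  out <- data.frame(
    gene = universe$symbol,
    cnv_type = rep(cnv_type, nrow(universe)),
    n_patients = unname(n_patients[in_universe]),
    min_region_gene_count = unname(min_region),
    max_nrpk = max_nrpk,
    stringsAsFactors = FALSE
  )
  out$pass_recurrence <- out$n_patients >= config$min_patients
  out$pass_region <- !is.na(region_stat) &
    region_stat <= config$max_genes_per_region
  out$pass_expression <- !is.na(out$max_nrpk) & out$max_nrpk >= cutoff
  out$candidate <- out$pass_recurrence & out$pass_region & out$pass_expression
  out <- out[order(-out$candidate, -out$n_patients, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "attrition") <- c(
    universe = nrow(out),
    after_recurrence = sum(out$pass_recurrence),
    after_region = sum(out$pass_recurrence & out$pass_region),
    candidates = sum(out$candidate)
  )
  attr(out, "nrpk_cutoff") <- cutoff
  class(out) <- c("candidate_table", "data.frame")
  out
}
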