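#' Read a patient CNV cohort table
#'
#' Parses a TSV with columns `patient_id`, `cnv_type`, `chrom`, `start`,
#' `end`, `phenotypes` (an optional `source` column is kept if present).
#' Coordinates are normalized to the package-internal 0-based half-open
#' convention; tables exported from genome-browser style sources are usually
#' 1-based inclusive and must be read with
#' `coordinate_dialect = "ucsc_1_inclusive"`.
#'
#' @param table_source Path to the TSV (header required).
#' @param genome A [genome_build()]; records on unknown chromosomes are an
#'   error.
#' @param coordinate_dialect `"bed_0_half_open"` (default) or
#'   `"ucsc_1_inclusive"`.
#' @param ofc_term_classes Named character vector mapping phenotype term ids
#'   to orofacial-cleft classes, used to assign each patient's `ofc_class`.
#'   Defaults to [default_ofc_terms()].
#' @return List with `cnvs` (one row per CNV, sorted by chrom/start/end) and
#'   `patients` (one row per distinct patient id, with a `phenotype_terms`
#'   list-column and an `ofc_class`).
#' @export
read_cnv_cohort <- function(table_source, genome,
                            coordinate_dialect = c("bed_0_half_open",
                                                   "ucsc_1_inclusive"),
                            ofc_term_classes = default_ofc_terms()) {
  coordinate_dialect <- match.arg(coordinate_dialect)
  df <- utils::read.delim(table_source, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("patient_id", "cnv_type", "chrom", "start", "end", "phenotypes")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    .stopf("cohort table missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (coordinate_dialect == "ucsc_1_inclusive") {
    df$start <- df$start - 1
  }
  bad_type <- !df$cnv_type %in% c("deletion", "duplication")
  if (any(bad_type)) {
    .stopf("unknown cnv_type '%s' (record %d); expected deletion/duplication",
           df$cnv_type[bad_type][1], which(bad_type)[1])
  }
  bad_chrom <- !df$chrom %in% names(genome$chrom_sizes)
  if (any(bad_chrom)) {
    .stopf("records on chromosomes absent from genome '%s': %s",
           genome$name,
           paste(sprintf("%s@%s:%s-%s", df$patient_id[bad_chrom],
                         df$chrom[bad_chrom], .fmt_int(df$start[bad_chrom]),
                         .fmt_int(df$end[bad_chrom])), collapse = ", "))
  }
  degenerate <- df$start >= df$end
  if (any(degenerate)) {
    .stopf("record %d has start >= end after normalization (%s:%s-%s)",
           which(degenerate)[1], df$chrom[degenerate][1],
           .fmt_int(df$start[degenerate][1]), .fmt_int(df$end[degenerate][1]))
  }
  if (!"source" %in% names(df)) df$source <- "synthetic"
  cnvs <- df[order(match(df$chrom, names(genome$chrom_sizes)),
                   df$start, df$end),
             c("patient_id", "cnv_type", "chrom", "start", "end", "source")]
  rownames(cnvs) <- NULL

  pheno_by_patient <- split(df$phenotypes, df$patient_id)
  ids <- names(pheno_by_patient)
  terms <- lapply(pheno_by_patient, function(p) {
    t <- unlist(strsplit(p, ";", fixed = TRUE))
    unique(t[nzchar(t)])
  })
  patients <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  patients$phenotype_terms <- unname(terms)
  patients$ofc_class <- vapply(terms, classify_ofc, "",
                               ofc_term_classes = ofc_term_classes)
  patients <- patients[order(patients$patient_id), , drop = FALSE]
  rownames(patients) <- NULL
  list(cnvs = cnvs, patients = patients)
}

#' Default phenotype-term to OFC-class mapping
#'
#' Used by the synthetic ontology; studies working from a real phenotype
#' ontology supply their own mapping of term ids to the cleft classes.
#'
#' @return Named character vector, term id -> OFC class.
#' @export
default_ofc_terms <- function() {
  c("OFC:CL" = "CL", "OFC:CLP" = "CLP", "OFC:CP" = "CP",
    "OFC:BU" = "bifid_uvula", "OFC:OCU" = "oral_cleft_unspecified",
    "OFC:ARC" = "alveolar_ridge_cleft", "OFC:CLL" = "cleft_lower_lip",
    "OFC:FC" = "facial_cleft")
}

#' Assign a patient's orofacial-cleft class from phenotype terms
#'
#' Applies the main-group rule: when a minor cleft type (bifid uvula,
#' alveolar ridge cleft, cleft lower lip, facial cleft, unspecified oral
#' cleft) co-occurs with a main phenotype (CL, CP, CLP), the patient is
#' ascribed to the main group. A patient annotated with both CL and CP is
#' treated as CLP.
#'
#' @param terms Character vector of phenotype term ids.
#' @param ofc_term_classes Named mapping as in [default_ofc_terms()].
#' @return One of `CL`, `CLP`, `CP`, `bifid_uvula`, `oral_cleft_unspecified`,
#'   `alveolar_ridge_cleft`, `cleft_lower_lip`, `facial_cleft`, `none`.
#' @export
classify_ofc <- function(terms, ofc_term_classes = default_ofc_terms()) {
  classes <- unique(unname(ofc_term_classes[intersect(terms,
                                                      names(ofc_term_classes))]))
  mains <- intersect(classes, c("CLP", "CL", "CP"))
  if (all(c("CL", "CP") %in% mains)) return("CLP")
  if (length(mains)) {
    return(mains[order(match(mains, c("CLP", "CP", "CL")))][1])
  }
  minors <- c("bifid_uvula", "oral_cleft_unspecified", "alveolar_ridge_cleft",
              "cleft_lower_lip", "facial_cleft")
  present <- intersect(minors, classes)
  if (length(present)) return(present[1])
  "none"
}

#' Write a CNV cohort back to TSV (0-based half-open)
#'
#' @param cohort A list as returned by [read_cnv_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cnv_cohort <- function(cohort, path) {
  cnvs <- cohort$cnvs
  pheno <- stats::setNames(
    vapply(cohort$patients$phenotype_terms, paste, "", collapse = ";"),
    cohort$patients$patient_id
  )
  cnvs$phenotypes <- unname(pheno[cnvs$patient_id])
  .write_tsv(cnvs[, c("patient_id", "cnv_type", "chrom", "start", "end",
                      "phenotypes", "source")], path)
}

#' Tabulate patients per OFC class
#'
#' @param patients Patient table from [read_cnv_cohort()].
#' @return data.frame `ofc_class`, `n_patients`, sorted by decreasing count.
#' @export
ofc_class_counts <- function(patients) {
  tab <- table(patients$ofc_class)
  out <- data.frame(ofc_class = names(tab), n_patients = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_patients, out$ofc_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}
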