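#' Read a pipeline configuration
#'
#' A single YAML file names every input path and every analysis parameter.
#' All published thresholds are explicit keys with their reference defaults:
#' `min_patients` 2, `max_genes_per_region` 5, `nrpk_cutoff` null (recompute
#' from the expression table; pin 59.00 to reproduce the reference run),
#' `permutations` 1000, `window_size` 1e6.
#'
#' @param path YAML file path.
#' @return Config list with defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(coordinate_dialect = "bed_0_half_open", window_size = 1e6,
                   permutations = 1000, seed = 1, min_patients = 2,
                   max_genes_per_region = 5, nrpk_cutoff = NULL,
                   hvr_quantile = 0.999, ofc_category = NULL)
  cfg$params <- utils::modifyList(defaults, cfg$params %||% list())
  required <- c("genome", "cohort", "annotation", "expression", "out_dir")
  missing_keys <- setdiff(required, names(cfg))
  if (length(missing_keys)) {
    .stopf("pipeline config missing keys: %s", paste(missing_keys, collapse = ", "))
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full recurrence analysis
#'
#' Orchestrates, per CNV type: coverage segmentation and contributor
#' collapsing, the per-depth overlap summary, the genome-shuffling
#' permutation test, three-criterion gene prioritization with attrition
#' accounting, panel enrichment, and variability scoring of candidate genes;
#' plus genome-wide window z-scores, per-gene catalog burden, the
#' patient-by-category phenotype matrix and (when background carriers are
#' supplied) a penetrance summary. Every table is written as TSV/JSON under
#' `out_dir` and every number in them is recomputable by calling the
#' underlying function with the logged parameters.
#'
#' @param config A config list or a YAML path ([read_pipeline_config()]).
#' @return Invisibly, a list with all intermediate objects and result tables.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  p <- config$params
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- "genome_io"
  res <- tryCatch({
    genome <- read_genome(config$genome$chrom_sizes,
                          config$genome$exclusions,
                          name = config$genome$name %||% "custom")
    cohort <- read_cnv_cohort(config$cohort, genome,
                              coordinate_dialect = p$coordinate_dialect)
    annotation <- read_annotation(config$annotation)
    expression <- compute_nrpk(read_expression(config$expression))
    catalog <- if (!is.null(config$catalog)) read_sv_catalog(config$catalog)
    panel <- if (!is.null(config$panel)) read_gene_panel(config$panel)
    ontology <- if (!is.null(config$ontology)) load_ontology(config$ontology)
    aliases <- if (!is.null(config$aliases))
      utils::read.delim(config$aliases, stringsAsFactors = FALSE)

    ## cohort phenotype table (Table 1 twin)
    pheno_counts <- ofc_class_counts(cohort$patients)
    .write_tsv(pheno_counts, file.path(out_dir, "ofc_class_counts.tsv"))

    ## genome-wide variability ------------------------------------------
    stage <- "variability"
    scored <- NULL
    if (!is.null(catalog)) {
      windows <- make_windows(genome, p$window_size)
      counted <- count_window_overlaps(windows, catalog)
      scored <- window_zscores(counted)
      scored$hypervariable <- hypervariable_flag(scored$z, p$hvr_quantile)
      .write_tsv(scored, file.path(out_dir, "window_zscores.tsv"))
    }

    per_type <- list()
    enrich_rows <- list()
    all_candidates <- character()
    for (ct in c("deletion", "duplication")) {
      stage <- paste0("overlap_randomization:", ct)
      cnvs_t <- cohort$cnvs[cohort$cnvs$cnv_type == ct, , drop = FALSE]
      if (nrow(cnvs_t) == 0) next
      segs <- coverage_segments(cnvs_t, genome)
      regions <- collapse_contributors(segs, cnvs_t)
      summ <- summarize_overlaps(segs)
      .write_tsv(summ$per_depth,
                 file.path(out_dir, sprintf("overlap_summary_%s.tsv", ct)))
      .write_tsv(regions,
                 file.path(out_dir, sprintf("overlap_regions_%s.tsv", ct)))
      rand <- randomization_test(cnvs_t, genome, R = p$permutations,
                                 rng_seed = p$seed +
                                   ifelse(ct == "deletion", 1, 2))
      jsonlite::write_json(
        rand[c("R", "mu_bar", "sigma", "mu_real", "z_real", "empirical_p",
               "p_is_upper_bound", "normality_p")],
        file.path(out_dir, sprintf("randomization_%s.json", ct)),
        auto_unbox = TRUE, digits = NA)

      stage <- paste0("gene_prioritization:", ct)
      prio <- prioritize(cohort$cnvs, annotation, expression, ct,
                         prioritization_config(p$min_patients,
                                               p$max_genes_per_region,
                                               p$nrpk_cutoff))
      .write_tsv(prio, file.path(out_dir, sprintf("candidates_%s.tsv", ct)))
      cand <- prio$gene[prio$candidate]
      all_candidates <- union(all_candidates, cand)

      stage <- paste0("enrichment:", ct)
      enr <- NULL
      if (!is.null(panel) && length(cand)) {
        counts <- panel_intersection(cand, panel, prio$gene, aliases)
        enr <- fold_enrichment(counts$N, counts$K, counts$n, counts$k)
        enrich_rows[[ct]] <- data.frame(
          cnv_type = ct, N = enr$N, K = enr$K, n = enr$n, k = enr$k,
          fold = round(enr$fold, 2), p_value = enr$p_value,
          p_value_published = enr$p_value_published,
          panel_genes = paste(counts$panel_in_candidates, collapse = ";"),
          stringsAsFactors = FALSE)
      }

      cand_var <- NULL
      if (!is.null(scored) && length(cand)) {
        rows <- annotation[match(cand, annotation$symbol), , drop = FALSE]
        cand_var <- data.frame(gene = cand, cnv_type = ct,
                               z = region_variability(rows, scored),
                               stringsAsFactors = FALSE)
        .write_tsv(cand_var,
                   file.path(out_dir, sprintf("candidate_variability_%s.tsv", ct)))
      }
      per_type[[ct]] <- list(regions = regions, summary = summ,
                             randomization = rand, candidates = prio,
                             enrichment = enr, candidate_variability = cand_var)
    }
    if (length(enrich_rows)) {
      .write_tsv(do.call(rbind, enrich_rows),
                 file.path(out_dir, "panel_enrichment.tsv"))
    }

    stage <- "variability:burden"
    burden <- NULL
    if (!is.null(catalog) && length(all_candidates)) {
      rows <- annotation[match(all_candidates, annotation$symbol), , drop = FALSE]
      burden <- gene_cnv_burden(rows, catalog)
      .write_tsv(burden, file.path(out_dir, "candidate_gene_burden.tsv"))
    }

    stage <- "phenotype_mapping"
    pheno_matrix <- NULL
    if (!is.null(ontology)) {
      pheno_matrix <- phenotype_matrix(
        cohort$patients, ontology,
        exclude_categories = p$ofc_category %||% character())
      .write_tsv(data.frame(patient_id = rownames(pheno_matrix),
                            as.data.frame(pheno_matrix),
                            check.names = FALSE),
                 file.path(out_dir, "phenotype_matrix.tsv"))
    }
    penetrance <- NULL
    if (!is.null(config$background_carriers) && length(all_candidates)) {
      bg <- utils::read.delim(config$background_carriers,
                              stringsAsFactors = FALSE)
      penetrance <- penetrance_summary(all_candidates, annotation,
                                       cohort$cnvs, bg)
      .write_tsv(penetrance, file.path(out_dir, "penetrance_summary.tsv"))
    }

    stage <- "run_log"
    log <- list(package_version = as.character(utils::packageVersion("cnvrecur")),
                r_version = R.version.string,
                params = p,
                attrition = lapply(per_type, function(x)
                  as.list(attr(x$candidates, "attrition"))),
                nrpk_cutoff_used = lapply(per_type, function(x)
                  attr(x$candidates, "nrpk_cutoff")))
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    list(genome = genome, cohort = cohort, annotation = annotation,
         per_type = per_type, window_zscores = scored, burden = burden,
         phenotype_matrix = pheno_matrix, penetrance = penetrance,
         ofc_class_counts = pheno_counts, out_dir = out_dir)
  }, error = function(e) {
    report <- list(stage = stage, message = conditionMessage(e))
    try(jsonlite::write_json(report, file.path(out_dir, "error.json"),
                             auto_unbox = TRUE), silent = TRUE)
    .stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  invisible(res)
}
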