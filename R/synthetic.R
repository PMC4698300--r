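#' Specification for a synthetic input bundle
#'
#' Describes a synthetic study: a gapped genome, a CNV cohort with planted
#' recurrent regions of configurable depth, gene models with exons,
#' log-normally distributed expression, a variant catalog with density
#' hotspots, a disease-gene panel and a two-level mini-ontology. Defaults
#' emulate the statistical structure the analysis assumes: a handful of
#' strongly recurrent loci over a sparse uniform CNV background, heavy-tailed
#' CNV and expression size distributions, and rare hypervariable windows.
#'
#' @param n_chrom,chrom_length Number and length (bp) of chromosomes.
#' @param gap_fraction Fraction of each chromosome occupied by an interior
#'   assembly gap; chromosome 1 additionally gets a telomeric gap.
#' @param n_patients Cohort size (one CNV per patient, matching the
#'   essentially-one-CNV-per-patient structure of database cohorts).
#' @param cnv_meanlog,cnv_sdlog,cnv_min,cnv_max Log-normal CNV length
#'   distribution, truncated to `[cnv_min, cnv_max]`.
#' @param deletion_fraction Fraction of background CNVs that are deletions.
#' @param planted_regions List of planted recurrent loci; each entry is a
#'   list with `cnv_type`, `depth` (patients stacked over the core),
#'   `length` (bp of the core), `n_genes` (genes placed inside the core) and
#'   `gene_rich` (`TRUE` makes every placed gene highly expressed so the
#'   locus fails only the gene-count criterion — a filter-boundary decoy).
#' @param jitter Maximal random extension of each carrier CNV beyond the
#'   planted core, per side (bp).
#' @param n_genes Background gene count.
#' @param gene_meanlog,gene_sdlog Log-normal background gene length.
#' @param stages Developmental stage labels of the expression table.
#' @param expr_meanlog,expr_sdlog,zero_fraction Log-normal normalized-count
#'   distribution and the fraction of zero-expressed gene/stage cells.
#' @param planted_expr_fold Planted candidate expression as a multiple of the
#'   provisional cutoff (low-expression decoys sit at 5% of it).
#' @param background_per_mb,n_hotspots,hotspot_fold Variant-catalog density:
#'   Poisson background rate per Mb window and fold-elevation of the planted
#'   hotspot windows.
#' @param var_min,var_max Catalog variant length range (uniform).
#' @param n_categories,terms_per_category Mini-ontology shape (plus one OFC
#'   category holding the cleft class terms).
#' @param n_panel Panel size; the planted candidates are always included.
#' @param n_background Non-OFC background carrier individuals (penetrance
#'   input).
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_chrom = 5, chrom_length = 1e8,
                           gap_fraction = 0.02,
                           n_patients = 60,
                           cnv_meanlog = log(1.5e5), cnv_sdlog = 0.8,
                           cnv_min = 1e3, cnv_max = 2e6,
                           deletion_fraction = 0.5,
                           planted_regions = list(
                             list(cnv_type = "deletion", depth = 8,
                                  length = 4.8e5, n_genes = 3, gene_rich = FALSE),
                             list(cnv_type = "duplication", depth = 5,
                                  length = 3e5, n_genes = 2, gene_rich = FALSE),
                             list(cnv_type = "deletion", depth = 2,
                                  length = 4e5, n_genes = 7, gene_rich = TRUE)
                           ),
                           jitter = 1e5,
                           n_genes = 300,
                           gene_meanlog = log(2e4), gene_sdlog = 0.8,
                           stages = c("E10", "E11", "E12", "E13", "E14"),
                           expr_meanlog = log(100), expr_sdlog = 1.2,
                           zero_fraction = 0.2,
                           planted_expr_fold = 3,
                           background_per_mb = 5, n_hotspots = 3,
                           hotspot_fold = 15,
                           var_min = 1e3, var_max = 5e4,
                           n_categories = 6, terms_per_category = 4,
                           n_panel = 20, n_background = 30) {
  stopifnot(gap_fraction >= 0, gap_fraction < 1, zero_fraction >= 0,
            zero_fraction <= 1, n_patients > 0)
  spec <- as.list(environment())
  total_carriers <- sum(vapply(planted_regions, function(r) r$depth, 0))
  if (total_carriers + 1 > n_patients) {
    .stopf("planted regions require %d carriers (+1 singleton) but n_patients = %d",
           total_carriers, n_patients)
  }
  structure(spec, class = "synthetic_spec")
}

# Uniform placement over the legal (gap-free) genome space, the same rule as
# shuffle_intervals: build intervals of the requested lengths and shuffle.
.place_uniform <- function(lengths, genome) {
  if (!length(lengths)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  }
  df <- data.frame(chrom = names(genome$chrom_sizes)[1], start = 0,
                   end = lengths, stringsAsFactors = FALSE)
  shuffle_intervals(df, genome)
}

#' Generate a null CNV cohort by uniform placement
#'
#' Places `n` CNVs (one per synthetic patient) uniformly over the legal
#' genome space — the same placement rule the permutation null of
#' [randomization_test()] uses — with log-normally distributed lengths.
#'
#' @param genome A [genome_build()].
#' @param n Number of patients.
#' @param meanlog,sdlog,min_len,max_len Length distribution (truncated
#'   log-normal).
#' @param seed Optional RNG seed.
#' @param deletion_fraction Fraction of deletion CNVs.
#' @return data.frame in cohort `cnvs` layout plus a `phenotypes` column.
#' @export
generate_null_cohort <- function(genome, n, meanlog = log(1.5e5), sdlog = 0.8,
                                 min_len = 1e3, max_len = 2e6, seed = NULL,
                                 deletion_fraction = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) {
    return(data.frame(patient_id = character(), cnv_type = character(),
                      chrom = character(), start = numeric(), end = numeric(),
                      phenotypes = character(), stringsAsFactors = FALSE))
  }
  lens <- round(pmin(pmax(stats::rlnorm(n, meanlog, sdlog), min_len), max_len))
  placed <- .place_uniform(lens, genome)
  data.frame(
    patient_id = sprintf("N%03d", seq_len(n)),
    cnv_type = ifelse(stats::runif(n) < deletion_fraction,
                      "deletion", "duplication"),
    chrom = placed$chrom, start = placed$start, end = placed$end,
    phenotypes = sample(c("OFC:CP", "OFC:CL", "OFC:CLP"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Generate a complete synthetic input bundle
#'
#' Writes every pipeline input to `out_dir` in the exact formats the readers
#' consume, together with a ground-truth manifest (`truth.json`) listing the
#' planted recurrent regions, planted candidate genes, near-miss decoys,
#' hotspot windows and planted panel overlap, plus a ready-to-run pipeline
#' config (`pipeline.yaml`). Deterministic for a fixed seed.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed governing all randomness.
#' @return Invisibly, a list with `paths` (named file paths), `truth` (the
#'   manifest) and the in-memory objects (`genome`, `cohort`, `annotation`,
#'   ...).
#' @export
generate_all <- function(spec = synthetic_spec(), out_dir, seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ## genome -------------------------------------------------------------
  chroms <- stats::setNames(rep(spec$chrom_length, spec$n_chrom),
                            paste0("chr", seq_len(spec$n_chrom)))
  gaps <- data.frame(chrom = "chr1", start = 0, end = 5e5)
  for (ch in names(chroms)) {
    glen <- round(spec$gap_fraction * chroms[[ch]])
    if (glen > 0) {
      gs <- round(stats::runif(1, 0.3, 0.7) * chroms[[ch]])
      gaps <- rbind(gaps, data.frame(chrom = ch, start = gs, end = gs + glen))
    }
  }
  genome <- genome_build("synthetic", chroms, gaps)

  ## planted loci --------------------------------------------------------
  space <- legal_space(genome)
  margin <- spec$jitter + 5e4
  taken <- data.frame(chrom = character(), start = numeric(), end = numeric())
  place_locus <- function(len, chrom) {
    str <- space[space$chrom == chrom &
                   (space$end - space$start) > len + 2 * margin, , drop = FALSE]
    for (attempt in seq_len(1000)) {
      k <- sample.int(nrow(str), 1)
      s <- round(stats::runif(1, str$start[k] + margin,
                              str$end[k] - margin - len))
      cand <- data.frame(chrom = chrom, start = s - margin,
                         end = s + len + margin)
      clash <- nrow(taken) > 0 && any(
        taken$chrom == chrom & taken$start < cand$end & taken$end > cand$start)
      if (!clash) {
        taken <<- rbind(taken, cand)
        return(c(start = s, end = s + len))
      }
    }
    .stopf("could not place a planted locus of length %s", .fmt_int(len))
  }
  planted <- do.call(rbind, lapply(seq_along(spec$planted_regions), function(i) {
    r <- spec$planted_regions[[i]]
    ch <- paste0("chr", ((i - 1) %% spec$n_chrom) + 1)
    pos <- place_locus(r$length, ch)
    data.frame(region_id = paste0("PR", i), chrom = ch,
               start = pos[["start"]], end = pos[["end"]],
               cnv_type = r$cnv_type, depth = r$depth,
               n_genes = r$n_genes, gene_rich = r$gene_rich,
               stringsAsFactors = FALSE)
  }))
  # singleton decoy locus: one highly expressed gene hit by a single patient
  singleton_chrom <- paste0("chr", spec$n_chrom)
  singleton <- place_locus(2e5, singleton_chrom)
  singleton <- data.frame(chrom = singleton_chrom,
                          start = singleton[["start"]],
                          end = singleton[["end"]])

  ## genes ---------------------------------------------------------------
  make_gene <- function(symbol, chrom, start, end, type = "coding") {
    span <- end - start
    n_ex <- sample(1:8, 1)
    slot <- span / (2 * n_ex)
    es <- round(start + (2 * seq_len(n_ex) - 2) * slot)
    ee <- round(es + slot)
    ee[n_ex] <- min(ee[n_ex], end)
    data.frame(symbol = symbol, chrom = chrom, start = start, end = end,
               gene_type = type, exon_starts = paste(.fmt_int(es), collapse = ","),
               exon_ends = paste(.fmt_int(ee), collapse = ","),
               stringsAsFactors = FALSE)
  }
  genes <- list()
  planted_cand <- character(); low_decoys <- character(); rich_decoys <- character()
  for (i in seq_len(nrow(planted))) {
    r <- planted[i, ]
    n_g <- r$n_genes
    slot <- (r$end - r$start) / n_g
    for (g in seq_len(n_g)) {
      gs <- round(r$start + (g - 1) * slot + 0.15 * slot)
      ge <- round(gs + 0.6 * slot)
      if (r$gene_rich) {
        sym <- sprintf("RICH%d_%d", i, g); rich_decoys <- c(rich_decoys, sym)
      } else if (g == 1) {
        sym <- sprintf("CAND%s%d", toupper(substr(r$cnv_type, 1, 3)), i)
        planted_cand <- c(planted_cand, sym)
      } else {
        sym <- sprintf("LOW%d_%d", i, g); low_decoys <- c(low_decoys, sym)
      }
      genes[[length(genes) + 1]] <- make_gene(sym, r$chrom, gs, ge)
    }
  }
  genes[[length(genes) + 1]] <- make_gene(
    "SINGL1", singleton$chrom,
    round(singleton$start + 5e4), round(singleton$start + 1.2e5))
  gene_types <- c("coding", "pseudogene", "miRNA", "lncRNA")
  bg_lens <- round(pmin(pmax(stats::rlnorm(spec$n_genes, spec$gene_meanlog,
                                           spec$gene_sdlog), 2e3), 2e5))
  bg_pos <- .place_uniform(bg_lens, genome)
  keep <- !IRanges::overlapsAny(.as_gr(bg_pos), .as_gr(taken))
  bg_pos <- bg_pos[keep, , drop = FALSE]
  for (g in seq_len(nrow(bg_pos))) {
    genes[[length(genes) + 1]] <- make_gene(
      sprintf("G%04d", g), bg_pos$chrom[g], bg_pos$start[g], bg_pos$end[g],
      type = sample(gene_types, 1, prob = c(0.7, 0.1, 0.1, 0.1)))
  }
  genes_df <- do.call(rbind, genes)

  ## cohort --------------------------------------------------------------
  cohort_rows <- list()
  pid <- 0
  ofc_mains <- c("OFC:CP", "OFC:CL", "OFC:CLP")
  for (i in seq_len(nrow(planted))) {
    r <- planted[i, ]
    for (d in seq_len(r$depth)) {
      pid <- pid + 1
      ext_l <- round(stats::runif(1, 0, spec$jitter))
      ext_r <- round(stats::runif(1, 0, spec$jitter))
      terms <- sample(ofc_mains, 1, prob = c(0.6, 0.2, 0.2))
      if (stats::runif(1) < 0.2) terms <- c(terms, "OFC:BU")
      if (stats::runif(1) < 0.6) {
        terms <- c(terms, sprintf("TRM:CAT%d_%d", sample(spec$n_categories, 1),
                                  sample(spec$terms_per_category, 1)))
      }
      cohort_rows[[length(cohort_rows) + 1]] <- data.frame(
        patient_id = sprintf("P%03d", pid), cnv_type = r$cnv_type,
        chrom = r$chrom, start = r$start - ext_l, end = r$end + ext_r,
        phenotypes = paste(terms, collapse = ";"), stringsAsFactors = FALSE)
    }
  }
  pid <- pid + 1
  cohort_rows[[length(cohort_rows) + 1]] <- data.frame(
    patient_id = sprintf("P%03d", pid), cnv_type = "deletion",
    chrom = singleton$chrom, start = singleton$start, end = singleton$end,
    phenotypes = "OFC:CP", stringsAsFactors = FALSE)
  n_bg_pat <- spec$n_patients - pid
  if (n_bg_pat > 0) {
    bg <- generate_null_cohort(genome, n_bg_pat, spec$cnv_meanlog,
                               spec$cnv_sdlog, spec$cnv_min, spec$cnv_max,
                               deletion_fraction = spec$deletion_fraction)
    bg$patient_id <- sprintf("P%03d", pid + seq_len(n_bg_pat))
    cohort_rows[[length(cohort_rows) + 1]] <- bg
  }
  cohort_df <- do.call(rbind, cohort_rows)
  cohort_df$source <- "synthetic"

  ## expression ----------------------------------------------------------
  sym <- genes_df$symbol
  tx_kb <- vapply(seq_len(nrow(genes_df)), function(i) {
    es <- as.numeric(strsplit(genes_df$exon_starts[i], ",")[[1]])
    ee <- as.numeric(strsplit(genes_df$exon_ends[i], ",")[[1]])
    sum(ee - es) / 1000
  }, 0)
  n_cells <- length(sym) * length(spec$stages)
  expr <- data.frame(
    gene = rep(sym, each = length(spec$stages)),
    transcript_id = rep(paste0(sym, "_T1"), each = length(spec$stages)),
    length_kb = rep(tx_kb, each = length(spec$stages)),
    stage = rep(spec$stages, length(sym)),
    stringsAsFactors = FALSE
  )
  counts <- stats::rlnorm(n_cells, spec$expr_meanlog, spec$expr_sdlog)
  counts[stats::runif(n_cells) < spec$zero_fraction] <- 0
  expr$normalized_count <- round(counts, 2)
  provisional <- mean((expr$normalized_count / expr$length_kb)[
    expr$normalized_count > 0])
  high_genes <- c(planted_cand, rich_decoys, "SINGL1")
  is_high <- expr$gene %in% high_genes
  expr$normalized_count[is_high] <- round(
    spec$planted_expr_fold * provisional * expr$length_kb[is_high], 2)
  is_low <- expr$gene %in% low_decoys
  expr$normalized_count[is_low] <- round(
    0.05 * provisional * expr$length_kb[is_low], 2)

  ## variant catalog ------------------------------------------------------
  windows <- make_windows(genome, 1e6)
  hot_idx <- sample(nrow(windows), spec$n_hotspots)
  rate <- rep(spec$background_per_mb, nrow(windows)) *
    (windows$end - windows$start) / 1e6
  rate[hot_idx] <- rate[hot_idx] * spec$hotspot_fold
  n_per_win <- stats::rpois(nrow(windows), rate)
  cat_rows <- lapply(which(n_per_win > 0), function(w) {
    m <- n_per_win[w]
    len <- round(stats::runif(m, spec$var_min, spec$var_max))
    s <- round(stats::runif(m, windows$start[w],
                            pmax(windows$start[w], windows$end[w] - len)))
    data.frame(chrom = windows$chrom[w], start = s, end = s + len,
               variant_type = sample(c("loss", "gain"), m, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  catalog_df <- do.call(rbind, cat_rows)

  ## panel ----------------------------------------------------------------
  bg_syms <- grep("^G\\d+", sym, value = TRUE)
  panel_df <- data.frame(
    symbol = c(planted_cand,
               sample(bg_syms, max(0, spec$n_panel - length(planted_cand)))),
    stringsAsFactors = FALSE)
  panel_df$category <- sample(c("non_syndromic", "syndromic", "both"),
                              nrow(panel_df), replace = TRUE,
                              prob = c(0.4, 0.45, 0.15))

  ## ontology -------------------------------------------------------------
  ont_rows <- list(data.frame(child = "OFC", parent = "ROOT",
                              label = "abnormality of the orofacial region"))
  for (t in names(default_ofc_terms())) {
    ont_rows[[length(ont_rows) + 1]] <- data.frame(
      child = t, parent = "OFC", label = default_ofc_terms()[[t]])
  }
  for (cc in seq_len(spec$n_categories)) {
    cat_id <- sprintf("CAT%d", cc)
    ont_rows[[length(ont_rows) + 1]] <- data.frame(
      child = cat_id, parent = "ROOT", label = sprintf("category %d", cc))
    for (t in seq_len(spec$terms_per_category)) {
      ont_rows[[length(ont_rows) + 1]] <- data.frame(
        child = sprintf("TRM:CAT%d_%d", cc, t), parent = cat_id,
        label = sprintf("term %d of category %d", t, cc))
    }
  }
  ontology_df <- do.call(rbind, ont_rows)

  ## background (non-OFC) carriers ---------------------------------------
  bg_lens2 <- round(pmin(pmax(stats::rlnorm(spec$n_background - 6,
                                            spec$cnv_meanlog, spec$cnv_sdlog),
                              spec$cnv_min), spec$cnv_max))
  bg_car <- .place_uniform(bg_lens2, genome)
  pen_gene <- if (length(bg_syms)) bg_syms[1] else sym[1]
  # every planted candidate gets background carriers so penetrance ratios are
  # defined; the first candidate gets the fewest and ranks top by ratio
  cov_genes <- c(rep(pen_gene, 5), planted_cand[1],
                 rep(planted_cand[-1], each = 3))
  cov_rows <- genes_df[match(cov_genes, genes_df$symbol), ]
  extra <- data.frame(chrom = cov_rows$chrom, start = cov_rows$start - 1e4,
                      end = cov_rows$end + 1e4)
  bg_car <- rbind(bg_car, extra)
  bg_car <- data.frame(individual_id = sprintf("B%03d", seq_len(nrow(bg_car))),
                       cnv_type = "deletion", bg_car,
                       stringsAsFactors = FALSE)

  ## write ----------------------------------------------------------------
  paths <- list(
    chrom_sizes = file.path(out_dir, "genome.chrom.sizes"),
    exclusions = file.path(out_dir, "gaps.bed"),
    cohort = file.path(out_dir, "cohort.tsv"),
    annotation = file.path(out_dir, "genes.tsv"),
    expression = file.path(out_dir, "expression.tsv"),
    catalog = file.path(out_dir, "catalog.tsv"),
    panel = file.path(out_dir, "panel.tsv"),
    ontology = file.path(out_dir, "ontology.tsv"),
    background_carriers = file.path(out_dir, "background_carriers.tsv"),
    truth = file.path(out_dir, "truth.json"),
    config = file.path(out_dir, "pipeline.yaml")
  )
  writeLines(paste(names(chroms), .fmt_int(unname(chroms)), sep = "\t"),
             paths$chrom_sizes)
  writeLines(paste(genome$excluded$chrom, .fmt_int(genome$excluded$start),
                   .fmt_int(genome$excluded$end), sep = "\t"),
             paths$exclusions)
  .write_tsv(cohort_df[, c("patient_id", "cnv_type", "chrom", "start", "end",
                           "phenotypes", "source")], paths$cohort)
  .write_tsv(genes_df, paths$annotation)
  .write_tsv(expr, paths$expression)
  .write_tsv(catalog_df, paths$catalog)
  .write_tsv(panel_df, paths$panel)
  .write_tsv(ontology_df, paths$ontology)
  .write_tsv(bg_car, paths$background_carriers)

  truth <- list(
    seed = seed,
    planted_regions = planted[, c("region_id", "chrom", "start", "end",
                                  "cnv_type", "depth", "gene_rich")],
    planted_candidates = list(
      deletion = planted_cand[planted$cnv_type[!planted$gene_rich] == "deletion"],
      duplication = planted_cand[planted$cnv_type[!planted$gene_rich] == "duplication"]
    ),
    decoys = list(low_expression = low_decoys, gene_rich = rich_decoys,
                  singleton = "SINGL1"),
    hotspot_windows = windows[hot_idx, c("chrom", "start", "end", "index")],
    panel_planted = planted_cand,
    high_penetrance_gene = planted_cand[1],
    frequent_background_gene = pen_gene
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)

  config <- list(
    genome = list(chrom_sizes = paths$chrom_sizes,
                  exclusions = paths$exclusions, name = "synthetic"),
    cohort = paths$cohort,
    annotation = paths$annotation,
    expression = paths$expression,
    catalog = paths$catalog,
    panel = paths$panel,
    ontology = paths$ontology,
    background_carriers = paths$background_carriers,
    out_dir = file.path(out_dir, "results"),
    params = list(coordinate_dialect = "bed_0_half_open", window_size = 1e6,
                  permutations = 200, seed = seed, min_patients = 2,
                  max_genes_per_region = 5, nrpk_cutoff = NULL,
                  hvr_quantile = 0.999, ofc_category = "OFC")
  )
  yaml::write_yaml(config, paths$config)

  invisible(list(paths = paths, truth = truth, genome = genome,
                 cohort = cohort_df, annotation = genes_df,
                 expression = expr, catalog = catalog_df, panel = panel_df,
                 windows = windows, config = config))
}
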