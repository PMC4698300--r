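#' Load a phenotype ontology
#'
#' Accepts either an OBO file (only the `id`, `name` and `is_a` tags of
#' `[Term]` stanzas are read) or a TSV edge list with header columns `child`,
#' `parent` and optionally `label` (the child's label; a child with several
#' parents appears on several rows). The root is auto-detected as the unique
#' term that appears only as a parent; its direct children are the top-level
#' categories used for coarse phenotype summaries.
#'
#' @param source File path.
#' @return Object of class `ontology`: list with `terms` (data.frame `id`,
#'   `label`), `parents` (named list id -> parent ids), `children`, `root`,
#'   `top_level`.
#' @export
load_ontology <- function(source) {
  first <- readLines(source, n = 25)
  is_obo <- grepl("\\.obo$", source, ignore.case = TRUE) ||
    any(grepl("^\\[Term\\]", first)) || any(grepl("^format-version:", first))
  if (is_obo) {
    edges <- .parse_obo(source)
  } else {
    df <- utils::read.delim(source, stringsAsFactors = FALSE)
    if (!all(c("child", "parent") %in% names(df))) {
      .stopf("ontology TSV must have columns child, parent")
    }
    edges <- data.frame(child = df$child, parent = df$parent,
                        label = if ("label" %in% names(df)) df$label else df$child,
                        stringsAsFactors = FALSE)
  }
  ids <- unique(c(edges$child, edges$parent))
  labels <- stats::setNames(ids, ids)
  labels[edges$child] <- edges$label
  parents <- split(edges$parent, edges$child)
  parents <- lapply(parents, unique)
  roots <- setdiff(ids, names(parents))
  if (length(roots) != 1) {
    .stopf("expected exactly one root (parentless term), found %d: %s",
           length(roots), paste(utils::head(roots, 5), collapse = ", "))
  }
  root <- roots
  # cycle check by iterative DFS with coloring
  color <- stats::setNames(rep(0L, length(ids)), ids)  # 0 new, 1 open, 2 done
  visit <- function(v, path) {
    if (color[[v]] == 1L) {
      .stopf("ontology contains a cycle through: %s",
             paste(c(path, v), collapse = " -> "))
    }
    if (color[[v]] == 2L) return(invisible())
    color[[v]] <<- 1L
    for (p in parents[[v]]) visit(p, c(path, v))
    color[[v]] <<- 2L
    invisible()
  }
  for (v in ids) visit(v, character())
  # reachability of root from every term is implied: acyclic, single root
  children <- split(edges$child, edges$parent)
  children <- lapply(children, unique)
  top_level <- sort(unique(children[[root]]))
  if (!length(top_level)) .stopf("root has no children; no top-level categories")
  structure(
    list(terms = data.frame(id = ids, label = unname(labels[ids]),
                            stringsAsFactors = FALSE),
         parents = parents, children = children,
         root = root, top_level = top_level),
    class = "ontology"
  )
}

.parse_obo <- function(path) {
  lines <- readLines(path)
  in_term <- FALSE
  cur_id <- NA_character_; cur_name <- NA_character_; cur_isa <- character()
  out <- list()
  flush <- function() {
    if (!is.na(cur_id) && length(cur_isa)) {
      out[[length(out) + 1]] <<- data.frame(
        child = cur_id, parent = cur_isa,
        label = if (is.na(cur_name)) cur_id else cur_name,
        stringsAsFactors = FALSE)
    }
  }
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      flush()
      in_term <- grepl("^\\[Term\\]", ln)
      cur_id <- NA_character_; cur_name <- NA_character_; cur_isa <- character()
    } else if (in_term) {
      if (startsWith(ln, "id:")) cur_id <- trimws(sub("^id:", "", ln))
      if (startsWith(ln, "name:")) cur_name <- trimws(sub("^name:", "", ln))
      if (startsWith(ln, "is_a:")) {
        tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
        cur_isa <- c(cur_isa, tgt)
      }
    }
  }
  flush()
  if (!length(out)) .stopf("no is_a relations found in OBO file")
  do.call(rbind, out)
}

#' Map phenotype terms to top-level ontology categories
#'
#' Returns, for each input term, all top-level ancestors reachable through
#' `is_a` edges (a term under several branches contributes to all of them; a
#' top-level term maps to itself; the root maps to nothing). Unknown term
#' ids are not fatal: they map to an empty set and are listed in the
#' `unmapped` attribute.
#'
#' @param term_ids Character vector of term ids.
#' @param graph An [load_ontology()] object.
#' @return Named list of character vectors (term -> top-level category ids),
#'   with attribute `unmapped`.
#' @export
map_to_top_level <- function(term_ids, graph) {
  stopifnot(inherits(graph, "ontology"))
  known <- term_ids %in% graph$terms$id
  res <- lapply(term_ids, function(t) {
    if (!t %in% graph$terms$id) return(character())
    # BFS over ancestors, including the term itself
    seen <- character(); queue <- t
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% seen) next
      seen <- c(seen, v)
      queue <- c(queue, graph$parents[[v]])
    }
    sort(intersect(seen, graph$top_level))
  })
  names(res) <- term_ids
  attr(res, "unmapped") <- unique(term_ids[!known])
  res
}

#' Patient-by-category phenotype presence matrix
#'
#' Maps every phenotype term of every patient to top-level categories and
#' records presence/absence. The category holding the cohort's selection
#' phenotype can be excluded (it would be present for every patient by
#' construction).
#'
#' @param patients Patient table from [read_cnv_cohort()] (needs
#'   `patient_id` and the `phenotype_terms` list-column).
#' @param graph An [load_ontology()] object.
#' @param exclude_categories Character vector of top-level category ids to
#'   drop (default none).
#' @return Logical matrix, patients x top-level categories; attribute
#'   `unmapped` lists term ids absent from the ontology.
#' @export
phenotype_matrix <- function(patients, graph, exclude_categories = character()) {
  cats <- setdiff(graph$top_level, exclude_categories)
  m <- matrix(FALSE, nrow = nrow(patients), ncol = length(cats),
              dimnames = list(patients$patient_id, cats))
  unmapped <- character()
  for (i in seq_len(nrow(patients))) {
    mapped <- map_to_top_level(patients$phenotype_terms[[i]], graph)
    unmapped <- union(unmapped, attr(mapped, "unmapped"))
    hit <- intersect(unique(unlist(mapped)), cats)
    m[i, hit] <- TRUE
  }
  attr(m, "unmapped") <- unmapped
  m
}

#' Penetrance contrast for candidate genes
#'
#' For each gene, counts distinct cohort patients (affected carriers) whose
#' CNVs overlap the gene versus distinct background individuals (carriers of
#' a CNV over the gene without the selection phenotype). A high
#' affected-to-background ratio suggests a more penetrant gene.
#'
#' @param genes Character vector of gene symbols.
#' @param annotation A `gene_annotation` containing those genes.
#' @param cohort_cnvs Cohort CNV table (`patient_id`, `chrom`, `start`, `end`).
#' @param background_carriers data.frame of background CNVs with columns
#'   `individual_id`, `chrom`, `start`, `end`.
#' @return data.frame `gene`, `n_ofc_carriers`, `n_non_ofc_carriers`,
#'   `ratio` (`NA` when no background carriers), sorted by decreasing ratio.
#' @export
penetrance_summary <- function(genes, annotation, cohort_cnvs,
                               background_carriers) {
  ann <- annotation[match(genes, annotation$symbol), , drop = FALSE]
  if (anyNA(ann$symbol)) {
    .stopf("gene(s) absent from annotation: %s",
           paste(genes[is.na(ann$symbol)], collapse = ", "))
  }
  count_carriers <- function(tab, id_col) {
    if (nrow(tab) == 0) return(integer(nrow(ann)))
    hits <- GenomicRanges::findOverlaps(.as_gr(ann), .as_gr(tab))
    by_gene <- split(tab[[id_col]][S4Vectors::subjectHits(hits)],
                     factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(ann))))
    vapply(by_gene, function(v) length(unique(v)), 0L)
  }
  n_ofc <- count_carriers(cohort_cnvs, "patient_id")
  n_bg <- count_carriers(background_carriers, "individual_id")
  out <- data.frame(gene = genes, n_ofc_carriers = n_ofc,
                    n_non_ofc_carriers = n_bg,
                    ratio = ifelse(n_bg > 0, n_ofc / n_bg, NA_real_),
                    stringsAsFactors = FALSE)
  out <- out[order(-ifelse(is.na(out$ratio), ifelse(out$n_ofc_carriers > 0, Inf, -Inf),
                           out$ratio)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
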