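#' Fold enrichment and hypergeometric test of a gene panel
#'
#' With `N` genes in the universe (all genes retrieved from the CNVs of one
#' type), `K` of them in the disease panel, `n` prioritized candidates and
#' `k` panel genes among the candidates, the fold enrichment is
#' `(k/n) / (K/N)`. Significance is the hypergeometric upper tail for
#' `X ~ Hypergeometric(N, K, n)`; two tails are reported:
#' `p_value = P(X >= k)` (the conventional enrichment p) and
#' `p_value_published = P(X > k)`, the strictly-exceeding tail produced by
#' `phyper(k, ..., lower.tail = FALSE)`, which is the convention the
#' reference analysis evidently used and the one its tables print.
#'
#' @param N Universe size (> 0).
#' @param K Panel genes in the universe.
#' @param n Prioritized genes (> 0).
#' @param k Panel genes among the prioritized.
#' @return Object of class `enrichment_result`: list with `N`, `K`, `n`, `k`,
#'   `fold`, `p_value`, `p_value_published`.
#' @export
fold_enrichment <- function(N, K, n, k) {
  if (n <= 0 || n > N) .stopf("need 0 < n <= N")
  if (K < 0 || K > N) .stopf("need 0 <= K <= N")
  if (K == 0 && k > 0) .stopf("k > 0 with an empty panel (K = 0)")
  if (k < 0 || k > min(K, n)) .stopf("need 0 <= k <= min(K, n)")
  fold <- if (K == 0) 0 else (k / n) / (K / N)
  p_ge <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_gt <- stats::phyper(k, K, N - K, n, lower.tail = FALSE)
  structure(list(N = N, K = K, n = n, k = k, fold = fold,
                 p_value = p_ge, p_value_published = p_gt),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "panel enrichment: %d/%d candidates vs %d/%d universe -> fold %.2f, P(X >= k) = %.3g\n",
    x$k, x$n, x$K, x$N, x$fold, x$p_value))
  invisible(x)
}

#' Intersect candidates with a disease-gene panel
#'
#' Computes the `(N, K, n, k)` counts for [fold_enrichment()] and names the
#' intersecting genes. Symbol matching is case-insensitive; known synonyms
#' (e.g. printed alias pairs such as WHSC2/NELFA or MAPK3/ERK1) are resolved
#' through an explicit alias table rather than fuzzy matching.
#'
#' @param candidates Character vector of prioritized gene symbols.
#' @param panel Character vector of panel symbols (or a data.frame with a
#'   `symbol` column, as from [read_gene_panel()]).
#' @param universe Character vector of all genes retrieved from the relevant
#'   CNV set before prioritization; candidates must be a subset.
#' @param aliases Optional data.frame with columns `alias`, `canonical`.
#' @return List with `N`, `K`, `n`, `k`, `panel_in_candidates`,
#'   `panel_in_universe`.
#' @export
panel_intersection <- function(candidates, panel, universe, aliases = NULL) {
  if (is.data.frame(panel)) panel <- panel$symbol
  canon <- function(x) {
    x <- toupper(x)
    if (!is.null(aliases)) {
      m <- match(x, toupper(aliases$alias))
      x[!is.na(m)] <- toupper(aliases$canonical)[m[!is.na(m)]]
    }
    x
  }
  cand <- canon(candidates); pan <- unique(canon(panel)); uni <- canon(universe)
  outside <- setdiff(cand, uni)
  if (length(outside)) {
    .stopf("candidate gene(s) not in the universe (pipeline inconsistency): %s",
           paste(outside, collapse = ", "))
  }
  list(
    N = length(unique(uni)),
    K = length(intersect(pan, uni)),
    n = length(unique(cand)),
    k = length(intersect(pan, cand)),
    panel_in_candidates = sort(intersect(pan, cand)),
    panel_in_universe = sort(intersect(pan, uni))
  )
}

#' Read a disease-gene panel
#'
#' TSV with header `symbol  category`, category one of `non_syndromic`,
#' `syndromic`, `both`.
#'
#' @param path File path.
#' @return data.frame `symbol`, `category`.
#' @export
read_gene_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("symbol", "category") %in% names(df))) {
    .stopf("panel table must have columns symbol, category")
  }
  if (nrow(df) == 0) .stopf("empty gene panel")
  if (anyDuplicated(df$symbol)) .stopf("duplicated panel symbols")
  bad <- !df$category %in% c("non_syndromic", "syndromic", "both")
  if (any(bad)) {
    .stopf("unknown panel category: %s", paste(unique(df$category[bad]), collapse = ", "))
  }
  df
}
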