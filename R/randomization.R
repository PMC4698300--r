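#' Summarize overlap regions per depth
#'
#' Tabulates, for each coverage depth d >= 1, the number of regions and their
#' mean length, plus the number of shared regions (depth >= 2) and the mean
#' overlap — the arithmetic mean of depth over all regions (depth >= 1
#' included), which is the statistic standardized by the permutation test.
#'
#' @param regions Output of [coverage_segments()].
#' @return Object of class `overlap_summary`: list with `per_depth`
#'   (data.frame `depth`, `n_regions`, `mean_length`), `n_regions`,
#'   `n_shared`, `mean_overlap` (`NA` when there are no regions).
#' @export
summarize_overlaps <- function(regions) {
  if (nrow(regions) == 0) {
    out <- list(per_depth = data.frame(depth = integer(), n_regions = integer(),
                                       mean_length = numeric()),
                n_regions = 0L, n_shared = 0L, mean_overlap = NA_real_)
    class(out) <- "overlap_summary"
    return(out)
  }
  len <- regions$end - regions$start
  depths <- sort(unique(regions$depth))
  per_depth <- data.frame(
    depth = depths,
    n_regions = vapply(depths, function(d) sum(regions$depth == d), 0L),
    mean_length = vapply(depths, function(d) mean(len[regions$depth == d]), 0)
  )
  out <- list(
    per_depth = per_depth,
    n_regions = nrow(regions),
    n_shared = sum(regions$depth >= 2),
    mean_overlap = mean(regions$depth)
  )
  class(out) <- "overlap_summary"
  out
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("%d overlap regions (%d shared by >= 2 CNVs), mean overlap %.3f\n",
              x$n_regions, x$n_shared, x$mean_overlap))
  print(x$per_depth, row.names = FALSE)
  invisible(x)
}

#' Randomly relocate intervals over the placeable genome
#'
#' Each interval keeps its length and is assigned a new start position drawn
#' uniformly over all legal start positions genome-wide — i.e. positions such
#' that the interval lies within a chromosome and intersects no excluded
#' interval. Chromosomes are therefore chosen with probability proportional
#' to their legal space for that length. Placements are mutually independent;
#' shuffled intervals may overlap one another.
#'
#' The draw is exact (the legal start space is enumerated per length), so no
#' rejection sampling is involved; an interval longer than every gap-free
#' stretch is an error.
#'
#' @param intervals data.frame with `chrom`, `start`, `end`; other columns
#'   (patient ids, types) are carried through unchanged.
#' @param genome A [genome_build()].
#' @param rng_seed Optional seed for reproducibility.
#' @return `intervals` with new `chrom`, `start`, `end`.
#' @export
shuffle_intervals <- function(intervals, genome, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  stretches <- legal_space(genome)
  s_len <- stretches$end - stretches$start
  n <- nrow(intervals)
  if (n == 0) return(intervals)
  lens <- intervals$end - intervals$start
  new_chrom <- character(n)
  new_start <- numeric(n)
  for (i in seq_len(n)) {
    cap <- pmax(s_len - lens[i] + 1, 0)
    tot <- sum(cap)
    if (tot == 0) {
      .stopf("interval of length %s is unplaceable in genome '%s'",
             .fmt_int(lens[i]), genome$name)
    }
    j <- floor(stats::runif(1) * tot) + 1  # uniform in 1..tot
    if (j > tot) j <- tot
    cum <- cumsum(cap)
    k <- which(j <= cum)[1]
    offset <- j - c(0, cum)[k] - 1
    new_chrom[i] <- stretches$chrom[k]
    new_start[i] <- stretches$start[k] + offset
  }
  intervals$chrom <- new_chrom
  intervals$start <- new_start
  intervals$end <- new_start + lens
  intervals
}

# Mean coverage depth over the constant-depth segments of an interval set,
# without materializing ranges objects: segment boundaries are the sorted
# unique interval endpoints per chromosome and the depth between consecutive
# boundaries follows from the running start/end event balance. Agrees with
# mean(coverage_segments(x)$depth) by construction; used in the permutation
# loop where it is the only statistic needed.
.mean_overlap_depth <- function(intervals) {
  tot_depth <- 0; n_seg <- 0L
  for (idx in split(seq_len(nrow(intervals)), intervals$chrom)) {
    s <- intervals$start[idx]; e <- intervals$end[idx]
    pos <- sort(unique(c(s, e)))
    delta <- tabulate(match(s, pos), length(pos)) -
      tabulate(match(e, pos), length(pos))
    depth <- cumsum(delta)[-length(pos)]
    covered <- depth > 0
    tot_depth <- tot_depth + sum(depth[covered])
    n_seg <- n_seg + sum(covered)
  }
  tot_depth / n_seg
}

#' Permutation test of CNV overlap non-randomness
#'
#' Shuffles the interval list `R` times over the placeable genome, segments
#' each shuffled list into constant-depth regions and records its mean
#' overlap mu_i. The null mean `mu_bar` and SD `sigma` are taken over the R
#' permutation means, each permutation's z-score is
#' `z_i = (mu_i - mu_bar) / sigma`, and the observed list's `z_real` is
#' computed with the same formula. Because the permutation z-scores are not
#' normally distributed in general (checked by Shapiro-Wilk), significance is
#' the empirical p: the fraction of permutations with `z_i >= z_real`,
#' reported as `1/R` (an upper bound, flagged) when no permutation reaches
#' the observed score.
#'
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @param genome A [genome_build()].
#' @param R Number of permutations (>= 2; 1000 in typical use).
#' @param rng_seed Seed governing all permutations; per-permutation sub-seeds
#'   are derived deterministically so runs are reproducible.
#' @return Object of class `randomization_result`: list with `R`, `mu`
#'   (per-permutation means), `mu_bar`, `sigma`, `z` (per-permutation),
#'   `mu_real`, `z_real`, `empirical_p`, `p_is_upper_bound`, `normality_p`,
#'   `seed`.
#' @export
randomization_test <- function(intervals, genome, R = 1000, rng_seed = NULL) {
  stopifnot(R >= 2)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  sub_seeds <- sample.int(.Machine$integer.max, R)
  mu <- vapply(seq_len(R), function(i) {
    shuffled <- shuffle_intervals(intervals, genome, rng_seed = sub_seeds[i])
    .mean_overlap_depth(shuffled)
  }, 0)
  mu_bar <- mean(mu)
  sigma <- stats::sd(mu)
  if (!is.finite(sigma) || sigma == 0) {
    .stopf("degenerate null: permutation means have zero spread; increase R or use a larger genome")
  }
  z <- (mu - mu_bar) / sigma
  mu_real <- .mean_overlap_depth(intervals)
  z_real <- (mu_real - mu_bar) / sigma
  n_exceed <- sum(z >= z_real)
  normality_p <- if (R >= 3 && R <= 5000) stats::shapiro.test(z)$p.value
                 else NA_real_
  out <- list(
    R = R, mu = mu, mu_bar = mu_bar, sigma = sigma, z = z,
    mu_real = mu_real, z_real = z_real,
    empirical_p = max(n_exceed, 1) / R,
    p_is_upper_bound = n_exceed == 0,
    normality_p = normality_p,
    seed = rng_seed
  )
  class(out) <- "randomization_result"
  out
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf(
    "permutation test: R = %d, mu_bar = %.4f, sigma = %.4f\n  observed mean overlap %.4f, z_real = %.2f, empirical p %s%.4g (Shapiro-Wilk p = %.3g)\n",
    x$R, x$mu_bar, x$sigma, x$mu_real, x$z_real,
    if (x$p_is_upper_bound) "<= " else "= ", x$empirical_p, x$normality_p))
  invisible(x)
}

#' Shapiro-Wilk normality check
#'
#' Used to decide whether analytic normal-theory p-values would be defensible
#' for the permutation z-scores; the pipeline reports the empirical p
#' whenever this p-value is below 0.05 (and reports both regardless).
#'
#' @param values Numeric vector, 3 <= n <= 5000. A constant vector is an
#'   error (the test statistic is undefined).
#' @return The Shapiro-Wilk p-value.
#' @export
normality_check <- function(values) {
  n <- length(values)
  if (n < 3 || n > 5000) {
    .stopf("normality_check supports 3 <= n <= 5000 (got %d)", n)
  }
  if (length(unique(values)) == 1) {
    .stopf("normality_check: all values identical; normality is undefined")
  }
  stats::shapiro.test(values)$p.value
}
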