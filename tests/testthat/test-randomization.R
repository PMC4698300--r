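# Overlap summary, interval shuffling and the permutation test.

test_that("summarize_overlaps computes per-depth counts and the depth-weighted mean", {
  # per-depth profile of the published deletion set: mean overlap is the
  # depth-weighted mean 628/344, shared regions 146
  counts <- c(198, 73, 37, 20, 8, 4, 3, 1)
  regions <- data.frame(
    chrom = "chr1",
    start = seq(0, by = 2000, length.out = sum(counts)),
    end = seq(0, by = 2000, length.out = sum(counts)) + 1000,
    depth = rep(1:8, counts)
  )
  s <- summarize_overlaps(regions)
  expect_equal(s$n_regions, 344L)
  expect_equal(s$n_shared, 146L)
  expect_equal(s$mean_overlap, sum(counts * (1:8)) / sum(counts))
  expect_equal(s$per_depth$n_regions, counts)

  disjoint <- data.frame(chrom = "chr1", start = c(0, 10), end = c(5, 15),
                         depth = c(1, 1))
  s2 <- summarize_overlaps(disjoint)
  expect_equal(s2$n_shared, 0L)
  expect_equal(s2$mean_overlap, 1)

  s3 <- summarize_overlaps(disjoint[0, ])
  expect_equal(s3$n_regions, 0L)
  expect_true(is.na(s3$mean_overlap))
})

test_that("shuffle preserves lengths and respects the legal space", {
  g <- toy_genome(c(chrA = 1000))
  iv <- data.frame(chrom = "chrA", start = 0, end = 100)
  for (i in 1:20) {
    s <- shuffle_intervals(iv, g, rng_seed = i)
    expect_equal(s$end - s$start, 100)
    expect_true(s$start >= 0 && s$end <= 1000)
  }

  # a single legal slot forces the placement
  g_forced <- toy_genome(c(chrA = 1000),
                         excluded = data.frame(chrom = "chrA",
                                               start = 0, end = 900))
  s <- shuffle_intervals(iv, g_forced, rng_seed = 1)
  expect_equal(s$start, 900)
  expect_equal(s$end, 1000)

  # unplaceable interval
  expect_error(shuffle_intervals(data.frame(chrom = "chrA", start = 0, end = 200),
                                 g_forced, rng_seed = 1),
               "unplaceable")

  # length multiset is preserved for mixed interval sets
  set.seed(5)
  iv2 <- random_intervals(50, chrom_len = 900)
  s2 <- shuffle_intervals(iv2, g, rng_seed = 9)
  expect_equal(sort(s2$end - s2$start), sort(iv2$end - iv2$start))
  expect_equal(s2$patient_id, iv2$patient_id)  # annotations carried through
})

test_that("shuffled starts are uniform over the legal space (chi-squared, alpha 0.01)", {
  g <- toy_genome(c(chrA = 1e4),
                  excluded = data.frame(chrom = "chrA", start = 4000, end = 4500))
  iv <- data.frame(chrom = "chrA",
                   start = rep(0, 200), end = rep(100, 200))
  set.seed(123)
  starts <- unlist(lapply(1:50, function(i)
    shuffle_intervals(iv, g, rng_seed = 1000 + i)$start))
  # map starts onto a contiguous legal index: [0,3900] then [4500,9900]
  expect_true(all(starts <= 3900 | starts >= 4500))
  idx <- ifelse(starts <= 3900, starts, 3901 + (starts - 4500))
  n_legal <- 3901 + 5401
  bins <- cut(idx, breaks = seq(0, n_legal, length.out = 11),
              include.lowest = TRUE)
  p <- stats::chisq.test(table(bins))$p.value
  expect_gt(p, 0.01)
})

test_that("permutation z-scores standardize exactly and flag the p floor", {
  g <- toy_genome(c(chrA = 2e5, chrB = 1e5))
  set.seed(21)
  iv <- random_intervals(25, chrom_len = 9e4, chroms = c("chrA", "chrB"))
  r <- randomization_test(iv, g, R = 100, rng_seed = 77)
  expect_equal(mean(r$z), 0, tolerance = 1e-9)
  expect_equal(sd(r$z), 1, tolerance = 1e-9)
  expect_equal(r$z_real, (r$mu_real - r$mu_bar) / r$sigma)
  expect_true(r$empirical_p > 0 && r$empirical_p <= 1)

  # recurrent stack of identical intervals: no permutation should reach it
  stack <- data.frame(patient_id = paste0("P", 1:8), cnv_type = "deletion",
                      chrom = "chrA", start = 1e4, end = 2e4)
  filler <- random_intervals(20, chrom_len = 9e4, chroms = c("chrA", "chrB"))
  r2 <- randomization_test(rbind(stack, filler[, names(stack)]), g,
                           R = 100, rng_seed = 5)
  expect_true(r2$p_is_upper_bound)
  expect_equal(r2$empirical_p, 1 / 100)
  expect_gt(r2$z_real, max(r2$z))
})

test_that("empirical p is monotone non-increasing in z_real for fixed permutations", {
  z <- c(-1.2, -0.3, 0.1, 0.8, 1.5, 2.2)
  p_at <- function(z_real) max(sum(z >= z_real), 1) / length(z)
  zr <- seq(-2, 3, by = 0.25)
  ps <- vapply(zr, p_at, 0)
  expect_true(all(diff(ps) <= 0))
})

test_that("an observed list at the null mean has z_real 0", {
  g <- toy_genome(c(chrA = 2e5))
  set.seed(3)
  iv <- random_intervals(10, chrom_len = 1.9e5)
  r <- randomization_test(iv, g, R = 50, rng_seed = 11)
  # reconstruct z for a hypothetical observed mean equal to mu_bar
  expect_equal((r$mu_bar - r$mu_bar) / r$sigma, 0)
  # and the reported z_real follows the same formula as the permutations
  i <- which.min(abs(r$mu - r$mu_real))
  expect_equal(r$z[i], (r$mu[i] - r$mu_bar) / r$sigma)
})

test_that("normality_check behaves under H0, alternatives and degenerate input", {
  set.seed(2024)
  expect_gt(normality_check(rnorm(1000)), 0.05)
  skewed <- c(rnorm(900), rnorm(100, mean = 8))
  expect_lt(normality_check(skewed), 0.05)
  expect_error(normality_check(rep(1, 10)), "identical")
  expect_error(normality_check(c(1, 2)), "3 <= n")
  expect_error(normality_check(rnorm(6000)), "3 <= n")
})
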