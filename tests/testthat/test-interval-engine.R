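# Depth segmentation, contributor collapsing, windows, overlap counting.

test_that("coverage_segments reproduces the textbook example", {
  iv <- data.frame(patient_id = c("P1", "P2"), cnv_type = "deletion",
                   chrom = "chrA", start = c(0, 5), end = c(10, 15))
  seg <- coverage_segments(iv)
  expect_equal(seg$start, c(0, 5, 10))
  expect_equal(seg$end, c(5, 10, 15))
  expect_equal(seg$depth, c(1, 2, 1))

  one <- coverage_segments(iv[1, ])
  expect_equal(one$start, 0)
  expect_equal(one$end, 10)
  expect_equal(one$depth, 1)
})

test_that("coverage_segments equals the per-base depth oracle and conserves mass", {
  for (seed in 1:5) {
    set.seed(seed)
    iv <- random_intervals(50, chrom_len = 1e4)
    seg <- coverage_segments(iv)
    expect_equal(segments_to_bases(seg, "chrA", 1e4),
                 depth_by_base(iv, "chrA", 1e4))
    # conservation: sum(depth x length) == total interval length
    expect_equal(sum(seg$depth * (seg$end - seg$start)),
                 sum(iv$end - iv$start))
  }
})

test_that("coverage_segments on pairwise-disjoint intervals is the identity", {
  iv <- data.frame(patient_id = paste0("P", 1:4), cnv_type = "deletion",
                   chrom = "chrA",
                   start = c(0, 100, 250, 600), end = c(50, 200, 600, 700))
  seg <- coverage_segments(iv)
  expect_equal(seg$start, iv$start)
  expect_equal(seg$end, iv$end)
  expect_equal(seg$depth, rep(1L, 4))
})

test_that("fast mean-overlap path agrees with the segmentation on random inputs", {
  for (seed in 1:5) {
    set.seed(seed)
    iv <- random_intervals(40, chrom_len = 1e4,
                           chroms = c("chrA", "chrB"))
    expect_equal(cnvrecur:::.mean_overlap_depth(iv),
                 mean(coverage_segments(iv)$depth))
  }
})

test_that("collapse_contributors lists each patient once and matches the oracle", {
  iv <- data.frame(patient_id = c("P1", "P2", "P1"), cnv_type = "deletion",
                   chrom = "chrA", start = c(0, 5, 8), end = c(10, 15, 12))
  seg <- coverage_segments(iv)
  regions <- collapse_contributors(seg, iv)
  # segment [8,10) is covered by P1 twice and P2 once: depth 3, patients 2
  deep <- regions[regions$depth == 3, ]
  expect_equal(nrow(deep), 1)
  expect_equal(deep$patient_ids[[1]], c("P1", "P2"))

  for (seed in 1:3) {
    set.seed(seed)
    iv <- random_intervals(30, chrom_len = 5e3)
    regions <- collapse_contributors(coverage_segments(iv), iv)
    expect_equal(regions$patient_ids, contributors_oracle(regions, iv))
    expect_true(all(lengths(regions$patient_ids) <= regions$depth))
  }
})

test_that("make_windows tiles, keeps remainders and drops gap windows", {
  g <- toy_genome(c(chrA = 1e7))
  expect_equal(nrow(make_windows(g, 1e6)), 10)

  g_gap <- toy_genome(c(chrA = 1e7),
                      excluded = data.frame(chrom = "chrA",
                                            start = 2.5e6, end = 2.6e6))
  w <- make_windows(g_gap, 1e6)
  expect_equal(nrow(w), 9)           # window [2,3) Mb removed
  expect_false(any(w$start == 2e6))
  expect_equal(w$index, seq_len(9))

  g_rem <- toy_genome(c(chrA = 1.05e7))
  w2 <- make_windows(g_rem, 1e6)
  expect_equal(nrow(w2), 11)
  expect_equal(w2$end[11] - w2$start[11], 5e5)
})

test_that("count_window_overlaps uses any-overlap and matches the double loop", {
  g <- toy_genome(c(chrA = 5e3))
  w <- make_windows(g, 1e3)
  feat <- data.frame(chrom = "chrA", start = c(1000, 1500), end = c(2000, 2500))
  counts <- count_window_overlaps(w, feat)$count
  expect_equal(counts, c(0, 2, 1, 0, 0))  # spanning feature hits windows 2 and 3

  for (seed in 1:3) {
    set.seed(seed)
    feat <- random_intervals(40, chrom_len = 5e3)[, c("chrom", "start", "end")]
    counts <- count_window_overlaps(w, feat)$count
    expect_equal(counts, count_oracle(w, feat))
  }
})

test_that("genes_in_interval honors the any-overlap rule and gene deserts", {
  ann <- toy_annotation(c("G1", "G2", "G3"), "chrA",
                        start = c(100, 990, 5000), end = c(500, 1200, 6000))
  region <- data.frame(chrom = "chrA", start = 200, end = 1000)
  hit <- genes_in_interval(region, ann)
  expect_equal(hit$symbol, c("G1", "G2"))  # G2 overlaps by 10 bp
  edge <- genes_in_interval(data.frame(chrom = "chrA", start = 989, end = 990),
                            ann)
  expect_equal(edge$symbol, character(0))
  edge1 <- genes_in_interval(data.frame(chrom = "chrA", start = 990, end = 991),
                             ann)
  expect_equal(edge1$symbol, "G2")
  desert <- genes_in_interval(data.frame(chrom = "chrA", start = 2000, end = 3000),
                              ann)
  expect_equal(nrow(desert), 0)
  contained <- genes_in_interval(data.frame(chrom = "chrA", start = 0,
                                            end = 1000),
                                 ann, mode = "contained")
  expect_equal(contained$symbol, "G1")
})
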