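# Windowed variant-density z-scores, region/gene scoring and catalog burden.

test_that("window z-scores follow the log10 standardization analytically", {
  w <- data.frame(chrom = "chrA", start = c(0, 1, 2) * 1e6,
                  end = c(1, 2, 3) * 1e6, index = 1:3,
                  count = c(1, 10, 100))
  z <- window_zscores(w)
  expect_equal(z$log_count, c(0, 1, 2))
  expect_equal(attr(z, "mu"), 1)
  expect_equal(attr(z, "sigma"), 1)   # n-1 denominator
  expect_equal(z$z, c(-1, 0, 1))

  w$count <- c(5, 5, 5)
  expect_error(window_zscores(w), "identical")
  w$count <- c(0, 0, 3)
  expect_error(window_zscores(w), "fewer than 2")
})

test_that("z-scores equal an independent two-pass recomputation and standardize", {
  set.seed(14)
  w <- data.frame(chrom = "chrA", start = (0:199) * 1e6, end = (1:200) * 1e6,
                  index = 1:200, count = rpois(200, 8))
  z <- window_zscores(w)
  keep <- w$count > 0
  logs <- log10(w$count[keep])
  mu <- sum(logs) / length(logs)
  sigma <- sqrt(sum((logs - mu)^2) / (length(logs) - 1))
  expect_equal(z$z, (logs - mu) / sigma, tolerance = 1e-12)
  expect_equal(mean(z$z), 0, tolerance = 1e-9)
  expect_equal(sd(z$z), 1, tolerance = 1e-9)
  expect_equal(attr(z, "n_zero_dropped"), sum(!keep))
})

test_that("region variability averages raw counts before the log transform", {
  w <- data.frame(chrom = "chrA", start = c(0, 1, 2, 3) * 1e6,
                  end = c(1, 2, 3, 4) * 1e6, index = 1:4,
                  count = c(10, 1000, 1, 10))
  z <- window_zscores(w)
  mu <- attr(z, "mu"); sigma <- attr(z, "sigma")

  # a region exactly covering one window scores that window's z
  one <- data.frame(chrom = "chrA", start = 0, end = 1e6)
  expect_equal(region_variability(one, z), z$z[1])

  # spanning two windows: mean of raw counts (505), then log10, then z
  two <- data.frame(chrom = "chrA", start = 5e5, end = 1.5e6)
  expect_equal(region_variability(two, z), (log10(505) - mu) / sigma)

  # region overlapping no retained window is not assessable
  z_sub <- z[z$count > 1, ]
  attr(z_sub, "mu") <- mu; attr(z_sub, "sigma") <- sigma
  lonely <- data.frame(chrom = "chrA", start = 2.2e6, end = 2.4e6)
  expect_true(is.na(region_variability(lonely, z_sub)))
})

test_that("gene burden separates genic and exonic hits per variant type", {
  # gene with one exon covering its whole span: genic == exonic
  whole <- toy_annotation("W", "chrA", 1000, 2000)
  # gene with a single internal exon: intronic variants are genic only
  intr <- toy_annotation("I", "chrA", 5000, 9000,
                         exon_start = list(6500), exon_end = list(7000))
  ann <- rbind(whole, intr)
  class(ann) <- c("gene_annotation", "data.frame")
  catalog <- data.frame(
    chrom = "chrA",
    start = c(900, 1500, 5100, 6600, 8000),
    end = c(1100, 1600, 5300, 6800, 8200),
    variant_type = c("loss", "gain", "loss", "loss", "gain"))
  b <- gene_cnv_burden(ann, catalog)
  expect_equal(b$n_genic_del, c(1L, 2L))
  expect_equal(b$n_exonic_del, c(1L, 1L))   # 5100-5300 is intronic
  expect_equal(b$n_genic_dup, c(1L, 1L))
  expect_equal(b$n_exonic_dup, c(1L, 0L))
  expect_true(all(b$n_exonic_del <= b$n_genic_del))
  expect_true(all(b$n_exonic_dup <= b$n_genic_dup))
})

test_that("gene burden equals the brute-force membership oracle on random catalogs", {
  set.seed(77)
  ann <- toy_annotation(paste0("G", 1:5), "chrA",
                        start = seq(0, 8000, by = 2000),
                        end = seq(0, 8000, by = 2000) + 1500,
                        exon_start = lapply(seq(0, 8000, by = 2000),
                                            function(s) c(s + 100, s + 900)),
                        exon_end = lapply(seq(0, 8000, by = 2000),
                                          function(s) c(s + 400, s + 1300)))
  catalog <- random_intervals(60, chrom_len = 1e4)[, c("chrom", "start", "end")]
  catalog$variant_type <- sample(c("loss", "gain"), 60, replace = TRUE)
  b <- gene_cnv_burden(ann, catalog)
  for (i in seq_len(5)) {
    for (vt in c("loss", "gain")) {
      rows <- catalog[catalog$variant_type == vt, ]
      genic <- sum(mapply(overlaps_0based, rows$start, rows$end,
                          ann$start[i], ann$end[i]))
      exonic <- sum(vapply(seq_len(nrow(rows)), function(v) {
        any(mapply(overlaps_0based, ann$exon_start[[i]], ann$exon_end[[i]],
                   rows$start[v], rows$end[v]))
      }, TRUE))
      got <- b[i, if (vt == "loss") c("n_genic_del", "n_exonic_del")
                  else c("n_genic_dup", "n_exonic_dup")]
      expect_equal(unname(unlist(got)), c(genic, exonic))
    }
  }
})

test_that("hypervariable flags pick out extreme windows only", {
  expect_false(any(hypervariable_flag(rep(1.3, 50), 0.99)))
  z <- c(rnorm(500, sd = 0.5), 25)
  flags <- hypervariable_flag(z, 0.999)
  expect_true(flags[501])
  expect_lte(sum(flags), 2)
})
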