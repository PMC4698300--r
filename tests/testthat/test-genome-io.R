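# Readers, coordinate normalization and validation.

test_that("read_genome validates, merges exclusions and rejects bad input", {
  sizes <- tempfile(); writeLines(c("chrA\t1000000", "chrB\t500000"), sizes)

  g <- read_genome(sizes)
  expect_s3_class(g, "genome_build")
  expect_equal(length(g$chrom_sizes), 2)
  expect_equal(nrow(g$excluded), 0)

  excl <- tempfile()
  writeLines(c("chrA\t100\t200", "chrA\t150\t300"), excl)
  g2 <- read_genome(sizes, excl)
  expect_equal(nrow(g2$excluded), 1)
  expect_equal(g2$excluded$start, 100)
  expect_equal(g2$excluded$end, 300)

  writeLines("chrB\t400000\t600000", excl)
  expect_error(read_genome(sizes, excl), "outside chromosome bounds")

  writeLines("chrC\t10\t20", excl)
  expect_error(read_genome(sizes, excl), "absent from the genome")

  bad <- tempfile(); writeLines(c("chrA\t1000", "chrB"), bad)
  expect_error(read_genome(bad), "line 2")
})

test_that("legal_space is the gap complement within chromosome bounds", {
  g <- toy_genome(c(chrA = 1000),
                  excluded = data.frame(chrom = "chrA", start = 0, end = 900))
  sp <- legal_space(g)
  expect_equal(sp$start, 900)
  expect_equal(sp$end, 1000)

  g2 <- toy_genome(c(chrA = 1000),
                   excluded = data.frame(chrom = "chrA",
                                         start = c(100, 500),
                                         end = c(200, 600)))
  sp2 <- legal_space(g2)
  expect_equal(sp2$start, c(0, 200, 600))
  expect_equal(sp2$end, c(100, 500, 1000))
})

test_that("cohort reading normalizes dialects and counts patients", {
  g <- toy_genome(c(chr1 = 1e6))
  tab <- tempfile()
  writeLines(c("patient_id\tcnv_type\tchrom\tstart\tend\tphenotypes",
               "P1\tdeletion\tchr1\t101\t200\tOFC:CP",
               "P1\tduplication\tchr1\t500\t600\tOFC:CP",
               "P2\tdeletion\tchr1\t150\t260\tOFC:CL;OFC:BU",
               "P3\tdeletion\tchr1\t900\t950\tOFC:BU"), tab)

  ucsc <- read_cnv_cohort(tab, g, "ucsc_1_inclusive")
  expect_equal(nrow(ucsc$cnvs), 4)
  expect_equal(nrow(ucsc$patients), 3)
  expect_equal(ucsc$cnvs$start[1], 100)  # chr1:101-200 1-based -> [100,200)
  expect_equal(ucsc$cnvs$end[1], 200)

  bed <- read_cnv_cohort(tab, g, "bed_0_half_open")
  # dialect safety: identical physical table, lengths differ by exactly 1
  expect_equal((ucsc$cnvs$end - ucsc$cnvs$start) -
                 (bed$cnvs$end - bed$cnvs$start), rep(1, 4))

  # main-group rule: CL + bifid uvula -> CL; bifid uvula alone stays minor
  expect_equal(ucsc$patients$ofc_class[ucsc$patients$patient_id == "P2"], "CL")
  expect_equal(ucsc$patients$ofc_class[ucsc$patients$patient_id == "P3"],
               "bifid_uvula")

  writeLines(c("patient_id\tcnv_type\tchrom\tstart\tend\tphenotypes",
               "P1\tinversion\tchr1\t1\t2\tx"), tab)
  expect_error(read_cnv_cohort(tab, g), "unknown cnv_type")
  writeLines(c("patient_id\tcnv_type\tchrom\tstart\tend\tphenotypes",
               "P1\tdeletion\tchr9\t1\t2\tx"), tab)
  expect_error(read_cnv_cohort(tab, g), "absent from genome")
  writeLines(c("patient_id\tcnv_type\tchrom\tstart\tend\tphenotypes",
               "P1\tdeletion\tchr1\t5\t5\tx"), tab)
  expect_error(read_cnv_cohort(tab, g, "bed_0_half_open"), "start >= end")
})

test_that("cohorts round-trip through write and re-read", {
  g <- toy_genome(c(chr1 = 1e6, chr2 = 1e6))
  set.seed(11)
  cnvs <- random_intervals(15, chrom_len = 9e5, chroms = c("chr1", "chr2"))
  cohort <- list(cnvs = cnvs,
                 patients = data.frame(patient_id = unique(cnvs$patient_id)))
  cohort$cnvs$source <- "synthetic"
  cohort$patients$phenotype_terms <-
    rep(list(c("OFC:CP")), nrow(cohort$patients))
  path <- tempfile()
  write_cnv_cohort(cohort, path)
  back <- read_cnv_cohort(path, g, "bed_0_half_open")
  ord <- order(match(cnvs$chrom, c("chr1", "chr2")), cnvs$start, cnvs$end)
  expect_equal(back$cnvs$start, cnvs$start[ord])
  expect_equal(back$cnvs$end, cnvs$end[ord])
  expect_equal(back$cnvs$patient_id, cnvs$patient_id[ord])
  expect_equal(back$cnvs$cnv_type, cnvs$cnv_type[ord])
})

test_that("classify_ofc applies the main-group and CL+CP rules", {
  expect_equal(classify_ofc(c("OFC:CP", "OFC:BU")), "CP")
  expect_equal(classify_ofc(c("OFC:CL", "OFC:CP")), "CLP")
  expect_equal(classify_ofc(c("OFC:FC")), "facial_cleft")
  expect_equal(classify_ofc(c("TRM:X")), "none")
})

test_that("BED12 annotation yields exons and summed transcript length", {
  bed <- tempfile(fileext = ".bed")
  writeLines(paste("chr1", 1000, 3000, "GENE1", 0, "+", 1000, 3000, "0", 2,
                   "300,700", "0,1000", sep = "\t"), bed)
  ann <- read_annotation(bed)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$exon_start[[1]], c(1000, 2000))
  expect_equal(ann$exon_end[[1]], c(1300, 2700))
  expect_equal(ann$tx_kb, 1.0)
})

test_that("tabular annotation defaults exons to the span and flags bad blocks", {
  tsv <- tempfile()
  writeLines(c("symbol\tchrom\tstart\tend\tgene_type",
               "G1\tchr1\t100\t900\tcoding"), tsv)
  expect_warning(ann <- read_annotation(tsv), "full gene span")
  expect_equal(ann$exon_start[[1]], 100)
  expect_equal(ann$tx_kb, 0.8)

  writeLines(c("symbol\tchrom\tstart\tend\tgene_type\texon_starts\texon_ends",
               "G1\tchr1\t100\t900\tcoding\t50\t200"), tsv)
  expect_error(read_annotation(tsv), "inconsistent")

  empty <- tempfile()
  writeLines("symbol\tchrom\tstart\tend\tgene_type", empty)
  expect_equal(nrow(read_annotation(empty)), 0)
})
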