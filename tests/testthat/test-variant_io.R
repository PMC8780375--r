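# VCF / cohort / gene-map / panel readers and the 0/1/2 dosage coding.

test_that("GT strings map to dosage 0/1/2, missing and phase", {
  path <- write_mini_vcf(c(
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    paste(c("1", "100", "rs1", "A", "G", ".", "PASS", "EURMAF=0.01", "GT",
            "0/1", "1|1", "./."), collapse = "\t")))
  x <- read_vcf(path)
  expect_identical(unname(x$dosage[, 1L]), c(1L, 2L, NA_integer_))
  expect_identical(unname(x$hap1[, 1L]), c(NA_integer_, 1L, NA_integer_))
  expect_identical(unname(x$hap2[, 1L]), c(NA_integer_, 1L, NA_integer_))
  expect_identical(unname(x$phased[, 1L]), c(FALSE, TRUE, FALSE))
  expect_equal(x$variants$maf_external, 0.01)
  expect_equal(x$variants$rsid, "rs1")
})

test_that("multiallelic records split per alternate allele", {
  path <- write_mini_vcf(c(
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    paste(c("1", "200", ".", "A", "G,T", ".", "PASS", ".", "GT",
            "1/2", "0|1", "2/2"), collapse = "\t")))
  x <- read_vcf(path)
  expect_equal(nrow(x$variants), 2L)
  expect_identical(unname(x$dosage[, "1:200_A>G"]), c(1L, 1L, 0L))
  expect_identical(unname(x$dosage[, "1:200_A>T"]), c(1L, 0L, 2L))
  expect_identical(unname(x$hap1[, "1:200_A>G"])[2L], 0L)
  expect_identical(unname(x$hap2[, "1:200_A>G"])[2L], 1L)
})

test_that("records without GT and malformed GT strings are errors", {
  no_gt <- write_mini_vcf(c(
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1"), collapse = "\t"),
    paste(c("1", "100", ".", "A", "G", ".", "PASS", ".", "DP", "12"),
          collapse = "\t")))
  expect_error(read_vcf(no_gt), "record 1:100 has no GT field")
  bad_gt <- write_mini_vcf(c(
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2"), collapse = "\t"),
    paste(c("1", "300", ".", "A", "G", ".", "PASS", ".", "GT",
            "0/1", "x/1"), collapse = "\t")))
  expect_error(read_vcf(bad_gt), "malformed GT 'x/1' for sample S2 at 1:300")
})

test_that("dosage and phase round-trip through VCF writing", {
  cfg <- sim_config(n_cases = 15L, n_controls = c(C1 = 10L),
                    carrier_freq = c(P = 0.4, C1 = 0.1),
                    background_n = 6L, flank_n = 4L, seed = 7L)
  sim <- simulate_cohort(cfg)
  unph <- tempfile(fileext = ".vcf")
  gm <- sim$matrix
  gm$hap1 <- gm$hap2 <- gm$phased <- NULL
  write_vcf(gm, unph, phased = FALSE)
  back <- read_vcf(unph)
  expect_identical(back$dosage, sim$matrix$dosage)
  expect_identical(back$variants$id, sim$matrix$variants$id)

  ph <- tempfile(fileext = ".vcf")
  write_vcf(sim$matrix, ph, phased = TRUE)
  back2 <- read_vcf(ph)
  expect_identical(back2$hap1, sim$matrix$hap1)
  expect_identical(back2$hap2, sim$matrix$hap2)
  expect_identical(back2$dosage, sim$matrix$dosage)
})

test_that("column sums equal 2N times the allele frequency when no calls are missing", {
  cfg <- sim_config(n_cases = 30L, n_controls = c(C1 = 20L),
                    carrier_freq = c(P = 0.3, C1 = 0.05),
                    background_n = 10L, flank_n = 0L, seed = 11L)
  sim <- simulate_cohort(cfg)
  d <- sim$matrix$dosage
  n <- nrow(d)
  af <- colSums(d) / (2 * n)
  expect_equal(colSums(d), 2 * n * af)
  expect_true(all(d %in% 0:2))
})

test_that("cohort tables read with sizes; duplicates and empty files fail", {
  p <- tempfile()
  writeLines(c(sprintf("P_%02d\tP", 1:62), sprintf("C1_%02d\tC1", 1:69)), p)
  ch <- read_cohort(p)
  expect_identical(ch$sizes, c(C1 = 69L, P = 62L))
  expect_identical(unname(ch$assignment["P_01"]), "P")

  dup <- tempfile()
  writeLines(c("S1\tP", "S2\tC1", "S1\tC1"), dup)
  expect_error(read_cohort(dup), "duplicate sample")

  empty <- tempfile(); file.create(empty)
  expect_error(read_cohort(empty), "empty|cannot read")
})

test_that("samples absent from the cohort table are an error or dropped on request", {
  d <- matrix(c(0L, 1L, 2L), 3, 1,
              dimnames = list(c("S1", "S2", "S3"), NULL))
  x <- toy_matrix(d, toy_variants(1L))
  ch <- new_cohort(c(S1 = "P", S2 = "C1"))
  expect_error(match_cohort(x, ch), "S3")
  expect_warning(x2 <- match_cohort(x, ch, on_unassigned = "drop"),
                 "dropping")
  expect_identical(x2$samples, c("S1", "S2"))
})

test_that("interval gene maps assign genes; overlaps error; unmapped warn", {
  gm_path <- tempfile()
  writeLines("12\t40618813\t40763086\tLRRK2", gm_path)
  map <- read_gene_map(gm_path)
  v <- new_variant_table("12", c(40634203L, 41000000L), "A", "G",
                         rsid = c("rs11564187", "rsX"))
  d <- matrix(0L, 2, 2, dimnames = list(c("S1", "S2"), NULL))
  x <- new_genotype_matrix(d, v)
  expect_warning(x2 <- assign_genes(x, map), "not mapped")
  expect_identical(x2$variants$gene, c("LRRK2", ""))

  overlap <- tempfile()
  writeLines(c("12\t40618813\t40763086\tLRRK2", "12\t40630000\t40640000\tOTHER"),
             overlap)
  expect_error(suppressWarnings(assign_genes(x, read_gene_map(overlap))),
               "multiple genes")
})

test_that("rsid gene maps match variants by rsid", {
  gm_path <- tempfile()
  writeLines("rs33995883\tLRRK2", gm_path)
  v <- new_variant_table("12", 40740686L, "A", "G", rsid = "rs33995883")
  x <- new_genotype_matrix(matrix(0L, 1, 1, dimnames = list("S1", NULL)), v)
  x2 <- assign_genes(x, read_gene_map(gm_path))
  expect_identical(x2$variants$gene, "LRRK2")
})

test_that("phased panels load two haplotypes per sample and reject unphased GT", {
  path <- write_mini_vcf(c(
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2"), collapse = "\t"),
    paste(c("1", "100", ".", "A", "G", ".", "PASS", ".", "GT",
            "0|1", "1|1"), collapse = "\t")))
  pops <- tempfile()
  writeLines(c("S1\tEUR", "S2\tSAS"), pops)
  panel <- read_phased_panel(path, pops)
  expect_equal(nrow(panel$hap), 4L)
  expect_identical(unname(panel$hap[, 1L]), c(0L, 1L, 1L, 1L))
  expect_identical(unname(panel$populations), c("EUR", "SAS"))

  unphased <- write_mini_vcf(c(
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2"), collapse = "\t"),
    paste(c("1", "100", ".", "A", "G", ".", "PASS", ".", "GT",
            "0|1", "0/1"), collapse = "\t")))
  expect_error(read_phased_panel(unphased, pops), "unphased")
})
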