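# 2x2 carrier tables, Fisher/chi-square, RR, OR, haplotype frequencies.

test_that("carrier-based haplotype frequency is dosage sum over 2N", {
  expect_equal(haplotype_frequency(rep(1L, 10), 62), 10 / 124)
  expect_equal(haplotype_frequency(rep(1L, 7), 100), 0.035)
  expect_equal(haplotype_frequency(integer(0), 50), 0)
  expect_equal(haplotype_frequency(c(1L, 2L, 1L), 10), 4 / 20)
  expect_error(haplotype_frequency(rep(1L, 2), 0), "n_samples")
  expect_error(haplotype_frequency(c(1L, 3L), 10), "dosages")
})

test_that("two-tailed Fisher p matches hand-enumerable tables", {
  expect_equal(fisher_exact_two_tailed(contingency_2x2(1, 1, 1, 1)), 1.0)
  # margins (2,2)x(2,2): tables a=0 and a=2 each have probability 1/6
  expect_equal(fisher_exact_two_tailed(contingency_2x2(2, 0, 0, 2)), 1 / 3)
  expect_error(fisher_exact_two_tailed(contingency_2x2(0, 0, 0, 0)),
               "margin")
  expect_error(contingency_2x2(-1, 0, 0, 2), "non-negative")
})

test_that("Fisher p equals the enumeration oracle on random small tables", {
  set.seed(2024)
  for (i in 1:300) {
    tab <- random_table(60L)
    expect_equal(fisher_exact_two_tailed(tab),
                 oracle_fisher_p(tab$a, tab$b, tab$c, tab$d),
                 tolerance = 1e-10,
                 info = sprintf("table (%d,%d,%d,%d)",
                                tab$a, tab$b, tab$c, tab$d))
  }
})

test_that("chi-square p follows the closed-form Pearson statistic", {
  expect_equal(chi_square_two_tailed(contingency_2x2(5, 5, 7, 7)), 1.0)
  a <- 20; b <- 5; c <- 30; d <- 45; n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(chi_square_two_tailed(contingency_2x2(a, b, c, d)),
               stats::pchisq(stat, df = 1, lower.tail = FALSE))
  expect_error(chi_square_two_tailed(contingency_2x2(0, 0, 3, 4)),
               "zero margin")
})

test_that("chi-square and Fisher agree in the significance region at large expected counts", {
  # the asymptotic and exact tests converge where decisions are made;
  # mid-range p-values can differ by more, so agreement is asserted for
  # exact p < 0.05 with every expected count >= 10
  set.seed(7)
  checked <- 0L
  for (i in 1:400) {
    cells <- sample(20:120, 4, replace = TRUE)
    tab <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
    m <- as.matrix(tab)
    if (any(outer(rowSums(m), colSums(m)) / sum(m) < 10)) next
    p_exact <- fisher_exact_two_tailed(tab)
    if (p_exact >= 0.05) next
    checked <- checked + 1L
    expect_lt(abs(chi_square_two_tailed(tab) - p_exact), 0.02)
  }
  expect_gt(checked, 50L)
})

test_that("test selection follows the expected-count rule", {
  # C1-style table: smallest expected count is 11*62/131 = 5.21, so the
  # strict <5 rule selects chi-square (the Fisher p is always reported too)
  expect_identical(select_test(contingency_2x2(10, 1, 52, 68)), "chi-square")
  expect_identical(select_test(contingency_2x2(100, 100, 100, 100)),
                   "chi-square")
  expect_identical(select_test(contingency_2x2(1, 0, 1, 2)), "fisher")
  expect_identical(select_test(contingency_2x2(0, 0, 10, 10)), "fisher")
})

test_that("relative risk uses the case-probability-given-carrier orientation", {
  expect_equal(relative_risk(contingency_2x2(10, 1, 52, 68)),
               (10 / 11) / (52 / 120), tolerance = 1e-12)
  expect_equal(round(relative_risk(contingency_2x2(10, 1, 52, 68)), 3),
               2.098)
  expect_equal(relative_risk(contingency_2x2(10, 7, 52, 93)),
               (10 / 17) / (52 / 145))
  expect_equal(relative_risk(contingency_2x2(5, 5, 5, 5)), 1.0)
  expect_warning(rr <- relative_risk(contingency_2x2(0, 0, 3, 4)),
                 "undefined")
  expect_true(is.na(rr))
})

test_that("odds ratio is the cross product and transposition-invariant", {
  expect_equal(odds_ratio(contingency_2x2(10, 1, 52, 68)), 680 / 52)
  expect_equal(odds_ratio(contingency_2x2(10, 7, 52, 93)), 930 / 364)
  expect_equal(odds_ratio(contingency_2x2(4, 4, 4, 4)), 1.0)
  set.seed(31)
  for (i in 1:50) {
    tab <- random_table(50L)
    if (tab$b * tab$c == 0) next
    transposed <- contingency_2x2(tab$a, tab$c, tab$b, tab$d)
    expect_equal(odds_ratio(tab), odds_ratio(transposed))
  }
  expect_warning(or0 <- odds_ratio(contingency_2x2(3, 0, 2, 5)),
                 "undefined")
  expect_true(is.na(or0))
  expect_equal(odds_ratio(contingency_2x2(3, 0, 2, 5), haldane = TRUE),
               (3.5 * 5.5) / (0.5 * 2.5))
})

test_that("RR orientation is pinned by the reference table regression", {
  # the carrier-given-disease orientation would give ~11.1 here; the
  # adopted orientation gives 2.098
  rr <- relative_risk(contingency_2x2(10, 1, 52, 68))
  expect_gt(rr, 2.0); expect_lt(rr, 2.2)
})

test_that("one-sided upper Fisher p is monotone as carriers shift to cases", {
  # shifting a carrier from control to case (margins free) never raises
  # the upper-tail p for case enrichment
  p_upper <- function(a, b, c, d)
    stats::fisher.test(matrix(c(a, c, b, d), 2),
                       alternative = "greater")$p.value
  p1 <- p_upper(6, 5, 54, 64)
  p2 <- p_upper(8, 3, 52, 66)
  p3 <- p_upper(10, 1, 50, 68)
  expect_true(p1 >= p2 && p2 >= p3)
})

test_that("associate builds the carrier table against one control set", {
  v <- toy_variants(2L)
  d <- rbind(P1 = c(1L, 1L), P2 = c(1L, 1L), P3 = c(0L, 1L),
             P4 = c(NA, 1L),
             K1 = c(1L, 1L), K2 = c(0L, 0L), K3 = c(0L, 0L))
  x <- new_genotype_matrix(d, v)
  x$variants$maf <- v$maf_external
  ch <- new_cohort(setNames(c(rep("P", 4), rep("C1", 3)), rownames(d)))
  cand <- scan_gene_sets(x, ch, case_fraction = 0)[[1L]]
  res <- associate(x, ch, cand, "C1")
  # P4 has a missing member call: excluded from both margins
  expect_equal(unlist(res[c("a", "b", "c", "d")], use.names = FALSE),
               c(2L, 1L, 1L, 2L))
  expect_identical(res$test_used, "fisher")
  expect_equal(res$freq_case, 2 / 6)
  expect_equal(res$freq_control, 1 / 6)
  expect_error(associate(x, ch, cand, "C9"), "empty control set")
})

test_that("degenerate tables flow through associate without failing", {
  v <- toy_variants(2L)
  d <- rbind(P1 = c(1L, 1L), P2 = c(1L, 1L),
             K1 = c(0L, 0L), K2 = c(0L, 0L))
  x <- new_genotype_matrix(d, v)
  x$variants$maf <- v$maf_external
  ch <- new_cohort(setNames(c("P", "P", "C1", "C1"), rownames(d)))
  cand <- scan_gene_sets(x, ch, case_fraction = 0)[[1L]]
  res <- associate(x, ch, cand, "C1")
  expect_equal(unlist(res[c("a", "b", "c", "d")], use.names = FALSE),
               c(2L, 0L, 0L, 2L))
  expect_true(is.na(res$rr))   # zero non-carrier risk: undefined
  expect_true(is.na(res$or_))  # zero cell without correction
  expect_equal(res$p_fisher, 1 / 3)
})

test_that("confidence-interval extensions bracket the point estimates", {
  tab <- contingency_2x2(10, 7, 52, 93)
  ci <- odds_ratio_ci(tab)
  expect_lt(ci["lower"], odds_ratio(tab))
  expect_gt(ci["upper"], odds_ratio(tab))
  ci2 <- relative_risk_ci(tab)
  expect_lt(ci2["lower"], relative_risk(tab))
  expect_gt(ci2["upper"], relative_risk(tab))
})
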