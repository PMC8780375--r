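# Carrier-status 2x2 contingency tables per control cohort and the study
# statistics: two-tailed Fisher exact / chi-square, relative risk, odds
# ratio, carrier-based haplotype frequencies.

#' Construct a 2x2 carrier-by-status contingency table
#'
#' Orientation is fixed throughout the package: `a` = case carriers,
#' `b` = control carriers, `c` = case non-carriers, `d` = control
#' non-carriers (rows = carrier status, columns = case/control).
#'
#' @param a,b,c,d non-negative integer cell counts
#' @return a `contingency_2x2`
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  structure(lapply(cells, as.integer), class = "contingency_2x2")
}

#' @export
as.matrix.contingency_2x2 <- function(x, ...) {
  matrix(c(x$a, x$c, x$b, x$d), nrow = 2L,
         dimnames = list(carrier = c("carrier", "non-carrier"),
                         status = c("case", "control")))
}

#' @exportS3Method base::print
print.contingency_2x2 <- function(x, ...) {
  print(as.matrix(x))
  invisible(x)
}

#' Carrier-based haplotype frequency
#'
#' The haplotype allele frequency implied by carrier counts: the sum of
#' per-carrier haplotype dosages over 2N chromosomes.  With all-heterozygous
#' carriers this is n / (2N), the convention used when a table reports
#' "n carriers (N samples)".
#'
#' @param carrier_dosages integer vector of per-carrier haplotype dosages
#'   (1 = one copy, 2 = two copies); length 0 means no carriers
#' @param n_samples N, the number of samples the carriers were drawn from
#' @return frequency in \[0, 1\]
#' @export
haplotype_frequency <- function(carrier_dosages, n_samples) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (length(carrier_dosages) && !all(carrier_dosages %in% c(1L, 2L)))
    stop("carrier dosages must be 1 or 2")
  sum(carrier_dosages) / (2 * n_samples)
}

#' Two-tailed Fisher exact p-value
#'
#' The exact two-tailed p: the sum, over all tables with the observed
#' margins, of hypergeometric point probabilities no larger than the
#' observed one (with a relative tolerance of 1e-7 for floating-point
#' ties), clipped to \[0, 1\].
#'
#' @param table a `contingency_2x2`
#' @return p-value
#' @export
fisher_exact_two_tailed <- function(table) {
  m <- as.matrix(table)
  if (sum(m) == 0L || (all(rowSums(m) == 0L) || all(colSums(m) == 0L)))
    stop("table needs at least one positive margin")
  p <- stats::fisher.test(m)$p.value
  min(max(p, 0), 1)
}

#' Two-tailed chi-square p-value
#'
#' Pearson chi-square statistic on the 2x2 table with 1 degree of freedom
#' (optionally Yates-corrected), upper-tail p-value.  A zero row or column
#' margin leaves the statistic undefined and is an error.
#'
#' @param table a `contingency_2x2`
#' @param yates apply Yates continuity correction (default `FALSE`)
#' @return p-value
#' @export
chi_square_two_tailed <- function(table, yates = FALSE) {
  m <- as.matrix(table)
  if (any(rowSums(m) == 0L) || any(colSums(m) == 0L))
    stop("chi-square statistic undefined: zero margin")
  suppressWarnings(stats::chisq.test(m, correct = yates)$p.value)
}

#' Choose Fisher exact or chi-square for a table
#'
#' Cochran's rule: Fisher when any expected cell count is below
#' `threshold` (default 5, strict `<`), chi-square otherwise.  A table
#' with a zero margin always selects Fisher (chi-square is undefined).
#'
#' @param table a `contingency_2x2`
#' @param threshold expected-count threshold (default 5)
#' @return `"fisher"` or `"chi-square"`
#' @export
select_test <- function(table, threshold = 5) {
  m <- as.matrix(table)
  if (any(rowSums(m) == 0L) || any(colSums(m) == 0L)) return("fisher")
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < threshold)) "fisher" else "chi-square"
}

#' Relative risk of case status given carrier status
#'
#' RR = (a / (a + b)) / (c / (c + d)): the probability of being a case
#' among carriers over the probability of being a case among non-carriers.
#' (With table margins fixed by the study design this is a risk ratio over
#' carrier status, the orientation that matches carrier-count reporting.)
#'
#' @param table a `contingency_2x2`
#' @return relative risk; `NA` with a warning when undefined (empty
#'   carrier or non-carrier margin, or zero non-carrier risk)
#' @export
relative_risk <- function(table) {
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  if (a + b == 0L || c + d == 0L) {
    warning("relative risk undefined: empty carrier or non-carrier margin")
    return(NA_real_)
  }
  p0 <- c / (c + d)
  if (p0 == 0) {
    warning("relative risk undefined: zero non-carrier risk")
    return(NA_real_)
  }
  (a / (a + b)) / p0
}

#' Odds ratio of a 2x2 table
#'
#' OR = (a d) / (b c), the cross-product ratio; invariant under
#' transposition of the table.  With a zero off-diagonal cell the OR is
#' undefined (`NA` with a warning) unless `haldane = TRUE`, which adds 0.5
#' to every cell first.
#'
#' @param table a `contingency_2x2`
#' @param haldane apply the Haldane-Anscombe 0.5 correction
#' @return odds ratio
#' @export
odds_ratio <- function(table, haldane = FALSE) {
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  if (haldane) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  } else if (b * c == 0) {
    warning("odds ratio undefined: zero cell (consider haldane = TRUE)")
    return(NA_real_)
  }
  (a * d) / (b * c)
}

#' Wald confidence interval on the log odds ratio (extension)
#'
#' Not part of the core report (the reference workflow reports point
#' estimates only); provided as a convenience, Haldane-corrected when a
#' cell is zero.
#'
#' @param table a `contingency_2x2`
#' @param level confidence level (default 0.95)
#' @return named vector `c(lower, estimate, upper)`
#' @export
odds_ratio_ci <- function(table, level = 0.95) {
  need_h <- with(table, a * b * c * d) == 0
  or <- odds_ratio(table, haldane = need_h)
  k <- if (need_h) 0.5 else 0
  se <- sqrt(sum(1 / (unlist(table[c("a", "b", "c", "d")]) + k)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(lower = or * exp(-z * se), estimate = or, upper = or * exp(z * se))
}

#' Wald confidence interval on the log relative risk (extension)
#'
#' @inheritParams odds_ratio_ci
#' @return named vector `c(lower, estimate, upper)`
#' @export
relative_risk_ci <- function(table, level = 0.95) {
  rr <- relative_risk(table)
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(lower = rr * exp(-z * se), estimate = rr, upper = rr * exp(z * se))
}

assoc_row <- function(tab, control_label, test_threshold,
                      freq_case, freq_control) {
  test_used <- select_test(tab, threshold = test_threshold)
  p_fisher <- fisher_exact_two_tailed(tab)
  p_value <- if (test_used == "fisher") p_fisher else
    chi_square_two_tailed(tab)
  rr <- withCallingHandlers(relative_risk(tab),
                            warning = function(w) invokeRestart("muffleWarning"))
  or_ <- withCallingHandlers(odds_ratio(tab),
                             warning = function(w) invokeRestart("muffleWarning"))
  structure(
    data.frame(control_label = control_label,
               a = tab$a, b = tab$b, c = tab$c, d = tab$d,
               test_used = test_used, p_value = p_value,
               p_fisher = p_fisher, rr = rr, or_ = or_,
               freq_case = freq_case, freq_control = freq_control,
               stringsAsFactors = FALSE),
    class = c("association_result", "data.frame"))
}

#' Case-control association of a candidate haplotype
#'
#' Builds the carrier-status 2x2 table of cases versus one named control
#' group (samples with a missing call at any member are excluded from both
#' margins), chooses Fisher exact or chi-square by expected counts, and
#' reports the selected two-tailed p-value (the Fisher p is always reported
#' alongside), relative risk, odds ratio and carrier-based haplotype
#' frequencies of both groups.
#'
#' @param x a `genotype_matrix`
#' @param cohort a `cohort`
#' @param candidate a `candidate_haplotype`
#' @param control_label control group to compare against
#' @param case_label case group label (default `"P"`)
#' @param test_threshold expected-count threshold for [select_test()]
#' @return one-row data frame (`association_result`) with cells a-d,
#'   `test_used`, `p_value`, `p_fisher`, `rr`, `or_`, `freq_case`,
#'   `freq_control`
#' @export
associate <- function(x, cohort, candidate, control_label,
                      case_label = "P", test_threshold = 5) {
  groups <- cohort$assignment
  if (!control_label %in% groups) stop("empty control set: ", control_label)
  if (!case_label %in% groups) stop("no samples labelled ", case_label)
  status <- carrier_status(x, candidate$variant_ids)
  hd <- carriers_of(x, candidate$variant_ids)$haplotype_dosage
  grp <- groups[x$samples]
  case_idx <- !is.na(grp) & grp == case_label & !is.na(status)
  ctrl_idx <- !is.na(grp) & grp == control_label & !is.na(status)
  a <- sum(status[case_idx]); c_ <- sum(case_idx) - a
  b <- sum(status[ctrl_idx]); d <- sum(ctrl_idx) - b
  tab <- contingency_2x2(a, b, c_, d)
  case_carr <- intersect(names(hd), x$samples[case_idx])
  ctrl_carr <- intersect(names(hd), x$samples[ctrl_idx])
  assoc_row(tab, control_label, test_threshold,
            freq_case = haplotype_frequency(hd[case_carr], sum(case_idx)),
            freq_control = haplotype_frequency(hd[ctrl_carr], sum(ctrl_idx)))
}

#' Case association against a phased panel used as external controls
#'
#' The panel contributes carrier counts at the sample level (a carrier has
#' at least one haplotype bearing every member allele); its haplotype
#' frequency is the full-haplotype count over 2N panel chromosomes.
#'
#' @inheritParams associate
#' @param panel a `phased_panel`
#' @param control_label label for the panel column in the result
#' @return one-row `association_result` data frame
#' @export
associate_panel <- function(x, cohort, candidate, panel,
                            control_label = "C3", case_label = "P",
                            test_threshold = 5) {
  status <- carrier_status(x, candidate$variant_ids)
  hd <- carriers_of(x, candidate$variant_ids)$haplotype_dosage
  grp <- cohort$assignment[x$samples]
  case_idx <- !is.na(grp) & grp == case_label & !is.na(status)
  a <- sum(status[case_idx]); c_ <- sum(case_idx) - a
  j <- match_panel(panel, candidate$variant_ids)
  h <- panel$hap[, j, drop = FALSE]
  full_hap <- rowSums(h == 1L, na.rm = TRUE) == length(j) &
    rowSums(is.na(h)) == 0L
  carrier_sample <- tapply(full_hap, panel$hap_sample, any)
  b <- sum(carrier_sample); d <- length(panel$samples) - b
  tab <- contingency_2x2(a, b, c_, d)
  case_carr <- intersect(names(hd), x$samples[case_idx])
  assoc_row(tab, control_label, test_threshold,
            freq_case = haplotype_frequency(hd[case_carr], sum(case_idx)),
            freq_control = sum(full_hap) / (2 * length(panel$samples)))
}
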