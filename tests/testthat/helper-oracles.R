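# Independent oracles and small builders shared by the test files.

# Exact two-tailed Fisher p by explicit enumeration over all tables with
# the observed margins, using only choose(); independent of fisher.test.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  n <- r1 + r2
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x)
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1), numeric(1))
  p_obs <- probs[a - lo + 1L]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Random 2x2 table with grand total <= n_max and at least one positive
# margin in every direction needed by Fisher.
random_table <- function(n_max = 60L) {
  repeat {
    n <- sample(4:n_max, 1L)
    cells <- as.vector(stats::rmultinom(1L, n, prob = runif(4, 0.05, 1)))
    if (sum(cells[1:2]) + sum(cells[3:4]) > 0) break
  }
  contingency_2x2(cells[1L], cells[2L], cells[3L], cells[4L])
}

# Brute-force co-occurrence scan: enumerate every variant subset of size
# >= min_set_size within each gene and apply the reporting rules directly.
oracle_scan <- function(dosage, variants, groups, case_label = "P",
                        min_set_size = 2L, min_carriers = 2L,
                        case_fraction = 0.5) {
  carried <- (!is.na(dosage)) & dosage >= 1L
  miss <- is.na(dosage)
  out <- list()
  for (g in unique(variants$gene)) {
    idx <- which(variants$gene == g)
    k <- length(idx)
    if (k < min_set_size) next
    subsets <- unlist(lapply(min_set_size:k, function(s)
      utils::combn(idx, s, simplify = FALSE)), recursive = FALSE)
    for (S in subsets) {
      ok <- rowSums(carried[, S, drop = FALSE]) == length(S) &
        rowSums(miss[, S, drop = FALSE]) == 0L
      carr <- which(ok)
      if (length(carr) < min_carriers) next
      # maximality: adding any other variant of the gene shrinks carriers
      others <- setdiff(idx, S)
      closed <- all(vapply(others, function(v) {
        ok2 <- ok & carried[, v] & !miss[, v]
        sum(ok2) < length(carr)
      }, logical(1)))
      if (!closed) next
      if (!(mean(groups[carr] == case_label) > case_fraction)) next
      out[[length(out) + 1L]] <- sort(variants$id[S])
    }
  }
  out[order(vapply(out, paste, "", collapse = ","))]
}

toy_variants <- function(k, gene = "G1", maf = NULL, chrom = "1",
                         start = 1000L) {
  if (is.null(maf)) maf <- seq(0.01, 0.04, length.out = k)
  new_variant_table(chrom, start + seq_len(k) * 100L, "A", "G",
                    rsid = sprintf("rsT%s%02d", gene, seq_len(k)),
                    gene = gene, maf_external = maf)
}

toy_matrix <- function(dosage, variants) {
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("S%02d", seq_len(nrow(dosage)))
  new_genotype_matrix(dosage, variants)
}

# Tiny phased panel built directly from a haplotype matrix (2 rows per
# sample, in sample order).
toy_panel <- function(hap, variants, populations = NULL) {
  n <- nrow(hap) / 2L
  samples <- sprintf("S%02d", seq_len(n))
  h1 <- hap[seq(1L, nrow(hap), 2L), , drop = FALSE]
  h2 <- hap[seq(2L, nrow(hap), 2L), , drop = FALSE]
  rownames(h1) <- rownames(h2) <- samples
  gm <- new_genotype_matrix(h1 + h2, variants, h1, h2,
                            matrix(TRUE, n, ncol(hap),
                                   dimnames = list(samples, variants$id)))
  if (is.null(populations))
    populations <- setNames(rep("POP1", n), samples)
  as_phased_panel(gm, populations)
}

# The study fixture is used by several files; build it once per run.
fixture_cache <- new.env(parent = emptyenv())
get_fixture <- function() {
  if (is.null(fixture_cache$paths))
    fixture_cache$paths <- make_lrrk2_fixture()
  fixture_cache$paths
}
get_fixture_objects <- function() {
  if (is.null(fixture_cache$objects)) {
    fx <- get_fixture()
    x <- assign_genes(read_vcf(fx$cohort_vcf), read_gene_map(fx$gene_map))
    cohort <- read_cohort(fx$cohort_tsv)
    rare <- maf_filter(x, 0.05)
    panel <- read_phased_panel(fx$panel_vcf, fx$panel_pops)
    candidates <- scan_gene_sets(rare, cohort)
    fixture_cache$objects <- list(matrix = x, rare = rare, cohort = cohort,
                                  panel = panel, candidates = candidates)
  }
  fixture_cache$objects
}

write_mini_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##INFO=<ID=EURMAF,Number=1,Type=Float,Description=\"MAF\">",
    lines), path)
  path
}
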