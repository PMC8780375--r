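# Synthetic cohorts, phased panels and the deterministic study fixture.
# All randomness flows from the single seed in the configuration.

# Candidate-gene regions used to place simulated variants (hg19-style
# 1-based inclusive intervals).
gene_regions <- function() {
  data.frame(
    chrom = c("12", "4", "17"),
    start = c(40618813L, 90645250L, 43971748L),
    end = c(40763086L, 90759466L, 44105700L),
    gene = c("LRRK2", "SNCA", "MAPT"),
    stringsAsFactors = FALSE)
}

#' The five-variant LRRK2 risk haplotype definition
#'
#' The four intronic variants and one exonic variant (p.Asn2018Asp,
#' rs33995883 — the rarest member and therefore the anchor) that form the
#' LRRK2 candidate haplotype, at their hg19 positions with European
#' reference MAFs.  Ref/alt alleles are synthetic placeholders consistent
#' with the HGVS names (the deletion rs200829235 is written left-anchored).
#'
#' @return variant table (data frame) of the five members
#' @export
lrrk2_members <- function() {
  rbind(
    new_variant_table("12", 40634203L, "A", "G", "rs11564187", "LRRK2",
                      0.02126, "c.572-82A>G"),
    new_variant_table("12", 40677655L, "C", "T", "rs36220738", "LRRK2",
                      0.02081, "c.2242-22C>T"),
    new_variant_table("12", 40703047L, "AT", "A", "rs200829235", "LRRK2",
                      0.02146, "c.4317+12delT"),
    new_variant_table("12", 40740686L, "A", "G", "rs33995883", "LRRK2",
                      0.01917, "c.6241A>G"),
    new_variant_table("12", 40760764L, "T", "C", "rs3789329", "LRRK2",
                      0.02297, "c.7391-44T>C"))
}

#' Simulation configuration
#'
#' Defaults mirror the reference study design: 62 cases (`P`), 69 same-
#' region controls (`C1`) and 100 population controls (`C2`), with
#' group-wise carrier frequencies equal to the study's observed carrier
#' counts (10/62, 1/69, 7/100), the five LRRK2 members as the haplotype,
#' 20 background variants in linkage equilibrium and 20 flanking common
#' SNPs.  Carriers are heterozygous by default (`carrier_hom_fraction`
#' exercises the dosage-2 path).
#'
#' @param n_cases number of case samples
#' @param n_controls named integer vector of control-set sizes
#' @param members variant table of haplotype members (>= 2 rows)
#' @param carrier_freq named vector: group label -> carrier fraction
#' @param background_n number of background variants
#' @param background_maf length-2 MAF range for background variants
#' @param flank_n number of flanking common SNPs
#' @param flank_maf length-2 MAF range for flanking SNPs
#' @param recombinant_fraction fraction of panel anchor haplotypes lacking
#'   at least one non-anchor member
#' @param carrier_hom_fraction fraction of carriers homozygous for the
#'   haplotype
#' @param case_label group label of the cases
#' @param panel_pops named integer vector of panel population sizes
#' @param panel_hap_freq named vector: population -> haplotype frequency
#'   (per chromosome); populations absent from the vector get 0
#' @param seed integer seed driving all randomness
#' @return validated `sim_config` list
#' @export
sim_config <- function(n_cases = 62L,
                       n_controls = c(C1 = 69L, C2 = 100L),
                       members = lrrk2_members(),
                       carrier_freq = c(P = 10 / 62, C1 = 1 / 69,
                                        C2 = 7 / 100),
                       background_n = 20L,
                       background_maf = c(0.01, 0.4),
                       flank_n = 20L,
                       flank_maf = c(0.2, 0.5),
                       recombinant_fraction = 0,
                       carrier_hom_fraction = 0,
                       case_label = "P",
                       panel_pops = NULL,
                       panel_hap_freq = NULL,
                       seed = 42L) {
  stopifnot(nrow(members) >= 2L, n_cases >= 1L)
  if (any(carrier_freq < 0 | carrier_freq > 1))
    stop("carrier frequencies must lie in [0, 1]")
  stopifnot(recombinant_fraction >= 0, recombinant_fraction <= 1,
            carrier_hom_fraction >= 0, carrier_hom_fraction <= 1)
  groups <- c(case_label, names(n_controls))
  if (!all(groups %in% names(carrier_freq)))
    stop("carrier_freq must name every group: ",
         paste(groups, collapse = ", "))
  structure(
    list(n_cases = as.integer(n_cases), n_controls = n_controls,
         members = members, carrier_freq = carrier_freq,
         background_n = as.integer(background_n),
         background_maf = background_maf,
         flank_n = as.integer(flank_n), flank_maf = flank_maf,
         recombinant_fraction = recombinant_fraction,
         carrier_hom_fraction = carrier_hom_fraction,
         case_label = case_label,
         panel_pops = panel_pops, panel_hap_freq = panel_hap_freq,
         seed = as.integer(seed)),
    class = "sim_config")
}

# Flank SNPs: evenly spaced common SNPs inside the LRRK2 region, with
# per-SNP population frequencies drawn from the configured range.
flank_variants <- function(config) {
  if (config$flank_n == 0L) return(NULL)
  pos <- 40620001L + (seq_len(config$flank_n) - 1L) * 7000L
  freq <- runif(config$flank_n, config$flank_maf[1L], config$flank_maf[2L])
  v <- new_variant_table("12", pos, "C", "A",
                         rsid = sprintf("rsF%03d", seq_len(config$flank_n)),
                         gene = "LRRK2", maf_external = round(freq, 5))
  list(variants = v, freq = freq)
}

# Background variants in linkage equilibrium, spread round-robin over the
# candidate-gene regions.
background_variants <- function(config) {
  if (config$background_n == 0L) return(NULL)
  rg <- gene_regions()
  i <- seq_len(config$background_n)
  r <- ((i - 1L) %% nrow(rg)) + 1L
  pos <- rg$start[r] + 1500L + (i - 1L) * 911L
  freq <- runif(config$background_n, config$background_maf[1L],
                config$background_maf[2L])
  v <- new_variant_table(rg$chrom[r], pos, "G", "T",
                         rsid = sprintf("rsB%03d", i),
                         gene = rg$gene[r], maf_external = round(freq, 5))
  list(variants = v, freq = freq)
}

# The fixed flank allele pattern carried by every simulated risk haplotype.
flank_pattern <- function(n) rep(c(1L, 0L), length.out = n)

#' Simulate an unphased case-control cohort
#'
#' Each sample draws haplotype-carrier status from its group's carrier
#' frequency; carriers receive every member's alternate allele in cis on
#' one chromosome (plus the fixed flank pattern), homozygous carriers on
#' both.  Background and flanking variants are drawn independently at
#' their MAFs under Hardy-Weinberg.  Fully deterministic under the
#' configuration seed.
#'
#' @param config a [sim_config()]
#' @return list with `matrix` (a `genotype_matrix`; phase is stored
#'   internally but the cohort is meant to be written unphased), `cohort`
#'   (a `cohort`) and `truth` (named logical carrier status)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sizes <- c(setNames(config$n_cases, config$case_label), config$n_controls)
  group <- rep(names(sizes), sizes)
  samples <- unlist(lapply(names(sizes), function(g)
    sprintf("%s_%03d", g, seq_len(sizes[[g]]))))
  n <- length(samples)

  fl <- flank_variants(config)
  bg <- background_variants(config)
  variants <- rbind(config$members,
                    if (!is.null(fl)) fl$variants,
                    if (!is.null(bg)) bg$variants)
  m <- nrow(variants)
  k <- nrow(config$members)
  freqs <- c(rep(0, k), if (!is.null(fl)) fl$freq,
             if (!is.null(bg)) bg$freq)

  h1 <- vapply(freqs, function(f) rbinom(n, 1L, f), integer(n))
  h2 <- vapply(freqs, function(f) rbinom(n, 1L, f), integer(n))

  carrier <- rbinom(n, 1L, config$carrier_freq[group]) == 1L
  hom <- carrier & rbinom(n, 1L, config$carrier_hom_fraction) == 1L
  side <- sample(c(1L, 2L), n, replace = TRUE)
  risk_alleles <- c(rep(1L, k),
                    if (!is.null(fl)) flank_pattern(config$flank_n),
                    if (!is.null(bg)) rep(NA_integer_, config$background_n))
  risk_cols <- which(!is.na(risk_alleles))
  for (i in which(carrier)) {
    if (hom[i]) {
      h1[i, risk_cols] <- risk_alleles[risk_cols]
      h2[i, risk_cols] <- risk_alleles[risk_cols]
    } else if (side[i] == 1L) {
      h1[i, risk_cols] <- risk_alleles[risk_cols]
    } else {
      h2[i, risk_cols] <- risk_alleles[risk_cols]
    }
  }
  dosage <- h1 + h2
  rownames(dosage) <- rownames(h1) <- rownames(h2) <- samples
  phased <- matrix(TRUE, n, m, dimnames = list(samples, variants$id))
  gm <- new_genotype_matrix(dosage, variants, h1, h2, phased)
  list(matrix = gm, cohort = new_cohort(setNames(group, samples)),
       truth = setNames(carrier, samples))
}

#' Simulate a phased reference panel
#'
#' Each haplotype of each sample carries the anchor allele with its
#' population's haplotype frequency; of these anchor haplotypes, a
#' designed `recombinant_fraction` lack at least one non-anchor member
#' (one member is always dropped, the rest independently with probability
#' 1/2).  Full risk haplotypes carry the fixed flank pattern; all other
#' haplotypes draw flank alleles at their MAFs.
#'
#' @param config a [sim_config()] with `panel_pops` (named sizes) and
#'   `panel_hap_freq` (named per-chromosome haplotype frequencies)
#' @return list with `panel` (a `phased_panel`), `matrix` (phased
#'   `genotype_matrix`) and `populations`
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$panel_pops))
    stop("config$panel_pops (named population sizes) is required")
  set.seed(config$seed + 1L)
  pops <- config$panel_pops
  hapf <- setNames(rep(0, length(pops)), names(pops))
  if (!is.null(config$panel_hap_freq))
    hapf[names(config$panel_hap_freq)] <- config$panel_hap_freq
  if (any(hapf < 0 | hapf > 1)) stop("haplotype frequencies must be in [0, 1]")

  samples <- unlist(lapply(names(pops), function(p)
    sprintf("%s_%04d", p, seq_len(pops[[p]]))))
  populations <- setNames(rep(names(pops), pops), samples)
  n <- length(samples)

  fl <- flank_variants(config)
  variants <- rbind(config$members, if (!is.null(fl)) fl$variants)
  k <- nrow(config$members)
  maf <- config$members$maf_external
  anchor_col <- order(maf, config$members$pos)[1L]

  draw_hap <- function() {
    h <- matrix(0L, n, nrow(variants))
    if (!is.null(fl))
      h[, k + seq_len(config$flank_n)] <-
        vapply(fl$freq, function(f) rbinom(n, 1L, f), integer(n))
    anchor <- rbinom(n, 1L, hapf[populations]) == 1L
    recomb <- anchor & rbinom(n, 1L, config$recombinant_fraction) == 1L
    full <- anchor & !recomb
    h[full, seq_len(k)] <- 1L
    if (!is.null(fl))
      h[full, k + seq_len(config$flank_n)] <-
        matrix(flank_pattern(config$flank_n), sum(full), config$flank_n,
               byrow = TRUE)
    for (i in which(recomb)) {
      members <- rep(1L, k)
      others <- setdiff(seq_len(k), anchor_col)
      drop <- others[runif(length(others)) < 0.5]
      if (!length(drop)) drop <- sample(others, 1L)
      members[drop] <- 0L
      h[i, seq_len(k)] <- members
    }
    h
  }
  h1 <- draw_hap(); h2 <- draw_hap()
  dosage <- h1 + h2
  rownames(dosage) <- rownames(h1) <- rownames(h2) <- samples
  phased <- matrix(TRUE, n, nrow(variants),
                   dimnames = list(samples, variants$id))
  gm <- new_genotype_matrix(dosage, variants, h1, h2, phased)
  list(panel = as_phased_panel(gm, populations), matrix = gm,
       populations = populations)
}

# Per-population panel composition of the fixture: the thirteen
# populations that carry the haplotype, with their printed carrier counts
# and sample sizes, plus twelve zero-carrier populations whose synthetic
# sizes bring the panel to exactly 2516 samples.
fixture_panel_design <- function() {
  data.frame(
    population = c("GIH", "TSI", "STU", "IBS", "CLM", "PUR", "BEB", "PJL",
                   "MXL", "FIN", "PEL", "CEU", "ACB",
                   "ASW", "GBR", "CDX", "CHB", "CHS", "ESN", "GWD", "ITU",
                   "JPT", "KHV", "LWK", "MSL"),
    n_samples = c(103L, 107L, 102L, 107L, 94L, 104L, 86L, 96L,
                  64L, 99L, 85L, 99L, 96L,
                  107L, 107L, 106L, 106L, 106L, 106L, 106L, 106L,
                  106L, 106L, 106L, 106L),
    n_carriers = c(11L, 8L, 5L, 5L, 2L, 4L, 3L, 2L,
                   1L, 1L, 1L, 1L, 1L,
                   rep(0L, 12L)),
    stringsAsFactors = FALSE)
}

#' Deterministic fixture reproducing the reference study's carrier counts
#'
#' Writes a complete synthetic data set with exactly the carrier counts of
#' the LRRK2 endemic-parkinsonism study design: a cohort VCF of 62 cases
#' (10 all-heterozygous carriers of the five-member LRRK2 haplotype), 69
#' region controls (1 carrier) and 100 population controls (7 carriers);
#' a sample-to-group table; an interval gene map (LRRK2, SNCA, MAPT); and
#' a fully phased panel VCF of 2516 samples across 25 populations in which
#' 45 samples carry the haplotype — the printed per-population carrier
#' counts (11 GIH, 8 TSI, 5 STU, 5 IBS, 2 CLM, 4 PUR, 3 BEB, 2 PJL and one
#' each in MXL, FIN, PEL, CEU and ACB) — every carrier haplotype bearing
#' all five members in cis plus an identical 20-SNP flank pattern.  Case
#' carriers share the same flank pattern; the control carriers' patterns
#' differ at two flank SNPs each.  The cohort VCF additionally contains
#' common LRRK2 variants (removed by the MAF filter) and rare singleton
#' variants in SNCA and MAPT that never co-occur, exercising the scan's
#' negative paths.  Output is byte-identical across runs.
#'
#' @param dir output directory (created if needed; default a fresh
#'   directory under the session temp dir)
#' @return named list of file paths: `cohort_vcf`, `cohort_tsv`,
#'   `gene_map`, `panel_vcf`, `panel_pops`, `dir`
#' @export
make_lrrk2_fixture <- function(dir = tempfile("lrrk2_fixture")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(42L)
  members <- lrrk2_members()
  k <- nrow(members)
  flank_n <- 20L
  flank_pos <- 40620001L + (seq_len(flank_n) - 1L) * 7000L
  flank_freq <- round(runif(flank_n, 0.2, 0.5), 5)
  flank_v <- new_variant_table("12", flank_pos, "C", "A",
                               rsid = sprintf("rsF%03d", seq_len(flank_n)),
                               gene = "LRRK2", maf_external = flank_freq)

  # extra cohort-only variants: common LRRK2 SNPs (MAF-filtered out) and
  # rare SNCA/MAPT singletons (no co-occurrence)
  common_v <- new_variant_table("12", c(40625011L, 40688023L, 40755035L),
                                "G", "A", sprintf("rsC%03d", 1:3), "LRRK2",
                                c(0.18, 0.27, 0.44))
  rare_v <- rbind(
    new_variant_table("4", 90650777L, "T", "G", "rsR001", "SNCA", 0.012),
    new_variant_table("17", 43980111L, "C", "G", "rsR002", "MAPT", 0.008),
    new_variant_table("17", 44010222L, "A", "C", "rsR003", "MAPT", 0.015))

  sizes <- c(P = 62L, C1 = 69L, C2 = 100L)
  group <- rep(names(sizes), sizes)
  samples <- unlist(lapply(names(sizes), function(g)
    sprintf("%s_%03d", g, seq_len(sizes[[g]]))))
  n <- length(samples)
  carriers <- c(sprintf("P_%03d", c(3L, 17L, 22L, 23L, 24L, 26L,
                                    35L, 43L, 51L, 59L)),
                "C1_007",
                sprintf("C2_%03d", c(5L, 19L, 33L, 47L, 61L, 75L, 89L)))

  variants <- rbind(members, flank_v, common_v, rare_v)
  m <- nrow(variants)
  freqs <- c(rep(0, k), flank_freq, common_v$maf_external, rep(0, 3L))
  h1 <- vapply(freqs, function(f) rbinom(n, 1L, f), integer(n))
  h2 <- vapply(freqs, function(f) rbinom(n, 1L, f), integer(n))
  rownames(h1) <- rownames(h2) <- samples

  pat_case <- flank_pattern(flank_n)
  pat_c1 <- pat_case; pat_c1[c(2L, 9L)] <- 1L - pat_c1[c(2L, 9L)]
  pat_c2 <- pat_case; pat_c2[c(4L, 15L)] <- 1L - pat_c2[c(4L, 15L)]
  for (s in carriers) {
    pat <- switch(substr(s, 1L, 2L),
                  "P_" = pat_case, "C1" = pat_c1, "C2" = pat_c2)
    h1[s, seq_len(k)] <- 1L
    h1[s, k + seq_len(flank_n)] <- pat
    h2[s, seq_len(k)] <- 0L  # all carriers heterozygous
  }
  # rare singleton variants: one distinct sample each (cases), never jointly
  rare_cols <- m - 2:0
  h1[sprintf("P_%03d", 11L), rare_cols[1L]] <- 1L
  h1[sprintf("P_%03d", 13L), rare_cols[2L]] <- 1L
  h1[sprintf("P_%03d", 15L), rare_cols[3L]] <- 1L

  dosage <- h1 + h2
  gm <- new_genotype_matrix(dosage, variants)
  cohort <- new_cohort(setNames(group, samples))

  # phased panel: members + flank SNPs; carrier haplotypes identical
  design <- fixture_panel_design()
  p_samples <- unlist(lapply(seq_len(nrow(design)), function(i)
    sprintf("%s_%04d", design$population[i],
            seq_len(design$n_samples[i]))))
  populations <- setNames(rep(design$population, design$n_samples),
                          p_samples)
  np <- length(p_samples)
  pv <- rbind(members, flank_v)
  ph1 <- vapply(c(rep(0, k), flank_freq),
                function(f) rbinom(np, 1L, f), integer(np))
  ph2 <- vapply(c(rep(0, k), flank_freq),
                function(f) rbinom(np, 1L, f), integer(np))
  rownames(ph1) <- rownames(ph2) <- p_samples
  p_carriers <- unlist(lapply(seq_len(nrow(design)), function(i)
    if (design$n_carriers[i] > 0L)
      sprintf("%s_%04d", design$population[i],
              seq_len(design$n_carriers[i]))))
  for (s in p_carriers) {
    ph1[s, seq_len(k)] <- 1L
    ph1[s, k + seq_len(flank_n)] <- pat_case
    ph2[s, seq_len(k)] <- 0L
  }
  p_phased <- matrix(TRUE, np, nrow(pv), dimnames = list(p_samples, pv$id))
  pgm <- new_genotype_matrix(ph1 + ph2, pv, ph1, ph2, p_phased)

  paths <- list(
    cohort_vcf = file.path(dir, "cohort.vcf"),
    cohort_tsv = file.path(dir, "cohort_groups.tsv"),
    gene_map = file.path(dir, "genes.tsv"),
    panel_vcf = file.path(dir, "panel.vcf"),
    panel_pops = file.path(dir, "panel_populations.tsv"),
    dir = dir)
  write_vcf(gm, paths$cohort_vcf, phased = FALSE)
  write_cohort(cohort, paths$cohort_tsv)
  rg <- gene_regions()
  write.table(rg[, c("chrom", "start", "end", "gene")], paths$gene_map,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  write_vcf(pgm, paths$panel_vcf, phased = TRUE)
  write_populations(populations, paths$panel_pops)
  paths
}
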