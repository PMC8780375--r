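# Cis-phase assessment of a candidate set against a phased reference panel,
# and flanking-haplotype identity over common SNPs.

#' Fraction of anchor haplotypes carrying the whole candidate set
#'
#' Counts, over all panel haplotypes, those carrying the anchor alternate
#' allele and those carrying every member's alternate allele.  Their ratio
#' (`cis_fraction`) measures how exclusively the other members travel with
#' the rarest variant on one chromosome; 1.0 means perfect co-segregation
#' in cis.  A haplotype with a missing allele at any member is not counted
#' as a full-set haplotype.
#'
#' @param panel a `phased_panel`
#' @param candidate a `candidate_haplotype` (or list with `variant_ids` and
#'   `anchor`)
#' @return a `cis_report`: list with `anchor_hap_count`, `full_hap_count`,
#'   `cis_fraction` (0 with a warning when no panel haplotype carries the
#'   anchor) and `per_population_full`
#' @export
cis_fraction <- function(panel, candidate) {
  ids <- candidate$variant_ids
  j <- match_panel(panel, ids)
  h <- panel$hap[, j, drop = FALSE]
  anchor_col <- match(candidate$anchor, ids)
  anchor_hap <- !is.na(h[, anchor_col]) & h[, anchor_col] == 1L
  full_hap <- rowSums(h == 1L, na.rm = TRUE) == length(j) &
    rowSums(is.na(h)) == 0L
  anchor_n <- sum(anchor_hap)
  full_n <- sum(full_hap)
  frac <- if (anchor_n == 0L) {
    warning("anchor ", candidate$anchor, " absent from all panel haplotypes")
    0
  } else full_n / anchor_n
  per_pop <- tapply(full_hap, panel$populations[panel$hap_sample], sum)
  structure(
    list(anchor_hap_count = anchor_n, full_hap_count = full_n,
         cis_fraction = frac,
         per_population_full = setNames(as.integer(per_pop),
                                        names(per_pop))),
    class = "cis_report")
}

#' @exportS3Method base::print
print.cis_report <- function(x, ...) {
  cat(sprintf("cis report: %d/%d anchor haplotypes carry the full set (cis fraction %.3f)\n",
              x$full_hap_count, x$anchor_hap_count, x$cis_fraction))
  invisible(x)
}

#' Flanking-haplotype identity across carriers
#'
#' For each panel sample carrying the candidate's anchor allele, selects the
#' haplotype(s) bearing the anchor (both, flagged, when the sample is
#' anchor-homozygous) and compares their allele vectors over a set of
#' flanking common SNPs.  Carrier haplotypes are `identical` iff no SNP
#' shows two different called alleles across them.
#'
#' @param panel a `phased_panel` (or a phased study cohort converted with
#'   [as_phased_panel()])
#' @param candidate a `candidate_haplotype`
#' @param snp_ids variant ids (or rsids) of the flanking SNPs; an empty
#'   selection is vacuously identical
#' @return a `flank_identity_report`: list with `snp_ids`,
#'   `carrier_haplotypes` (matrix, one row per selected haplotype),
#'   `identical`, `mismatch_loci` and `homozygous_carriers`
#' @export
flank_identity <- function(panel, candidate, snp_ids) {
  anchor_j <- match_panel(panel, candidate$anchor)
  hap_sel <- !is.na(panel$hap[, anchor_j]) & panel$hap[, anchor_j] == 1L
  carriers <- unique(panel$hap_sample[hap_sel])
  hom <- names(which(tapply(hap_sel, panel$hap_sample, sum) == 2L))
  if (length(snp_ids) == 0L) {
    return(structure(
      list(snp_ids = character(0),
           carrier_haplotypes =
             matrix(integer(0), nrow = sum(hap_sel), ncol = 0L,
                    dimnames = list(rownames(panel$hap)[hap_sel], NULL)),
           identical = TRUE, mismatch_loci = character(0),
           homozygous_carriers = hom),
      class = "flank_identity_report"))
  }
  j <- match_panel(panel, snp_ids)
  ch <- panel$hap[hap_sel, j, drop = FALSE]
  colnames(ch) <- panel$variants$id[j]
  mismatch <- vapply(seq_along(j), function(c) {
    a <- unique(ch[, c])
    length(unique(a[!is.na(a)])) > 1L
  }, logical(1))
  structure(
    list(snp_ids = panel$variants$id[j], carrier_haplotypes = ch,
         identical = !any(mismatch),
         mismatch_loci = panel$variants$id[j][mismatch],
         homozygous_carriers = hom),
    class = "flank_identity_report")
}

#' @exportS3Method base::print
print.flank_identity_report <- function(x, ...) {
  cat(sprintf("flank identity over %d SNPs, %d carrier haplotypes: %s\n",
              length(x$snp_ids), nrow(x$carrier_haplotypes),
              if (x$identical) "identical" else
                paste0("differ at ", paste(x$mismatch_loci, collapse = ", "))))
  invisible(x)
}

#' Cis-consistency verdict for carriers of an unphased cohort
#'
#' Unphased genotypes cannot prove phase; this returns, per sample, the
#' verdict `"cis-consistent"` when the sample is a full carrier (dosage >= 1
#' at every member, no missing member) *and* the reference-panel cis
#' fraction meets the threshold, else `"ambiguous"` (a carrier-like sample
#' with a missing member call is always ambiguous).  Samples that are
#' plainly non-carriers (dosage 0 at some member) are not reported.
#'
#' @param x an (unphased) `genotype_matrix`
#' @param candidate a `candidate_haplotype`
#' @param panel_cis_fraction the `cis_fraction` measured on the reference
#'   panel (see [cis_fraction()])
#' @param cis_threshold minimum panel cis fraction for the cis-consistent
#'   verdict (default 0.9)
#' @return named character vector of verdicts
#' @export
infer_carrier_phase_unphased <- function(x, candidate, panel_cis_fraction,
                                         cis_threshold = 0.9) {
  j <- match(candidate$variant_ids, x$variants$id)
  if (anyNA(j))
    stop("unknown variant id(s): ",
         paste(candidate$variant_ids[is.na(j)], collapse = ", "))
  d <- x$dosage[, j, drop = FALSE]
  nonzero <- rowSums(d >= 1L, na.rm = TRUE)
  miss <- rowSums(is.na(d))
  full <- nonzero == length(j)
  partial_miss <- miss > 0L & nonzero + miss == length(j)
  sel <- full | partial_miss
  v <- ifelse(full[sel] & panel_cis_fraction >= cis_threshold,
              "cis-consistent", "ambiguous")
  setNames(v, x$samples[sel])
}
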