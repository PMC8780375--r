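---
title: "Scanning candidate genes for rare risk haplotypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning candidate genes for rare risk haplotypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haploscan)
```

## The problem

In small, isolated populations, a cluster of rare variants inherited
together on one chromosome — a rare haplotype — can act as a risk factor
that no single variant would reveal.  A typical study design genotypes a
panel of candidate genes in a modest case cohort and one or more control
cohorts, asks which rare variants co-occur in the same individuals within
a gene, checks on a phased reference panel whether those alleles really
travel in cis, and compares carrier frequencies between cases and
controls.  haploscan implements that workflow end to end: the motivating
setting is an endemic-parkinsonism population in which ten of 62 patients
shared a five-variant LRRK2 haplotype, and the package's deterministic
fixture reproduces exactly that design (62 cases, 69 region controls,
100 population controls, and a 2516-sample phased panel).

## Dosage coding and missing calls

Genotypes are coded as alternate-allele dosage: reference homozygote 0,
heterozygote 1, alternate homozygote 2.  Multiallelic VCF records are
split per alternate allele, the dosage counting copies of that allele
only.  Phase is retained only where the source genotype used the `|`
separator.

Missing calls become `NA` and propagate conservatively: a sample with a
missing call at *any* member of a candidate set has unknown carrier
status and is excluded from both the numerator and the denominator of
every downstream count.  Excluding such samples avoids biasing carrier
frequencies in either direction; imputing them as non-carriers would
deflate case frequencies where missingness is more common among cases.

## The rarity filter

Variants are "rare" when their minor allele frequency is strictly below
the threshold (default 0.05; a variant at exactly 0.05 is discarded).
Two MAF sources are supported and never silently mixed:

* **external** (default): an annotation frequency such as a European
  reference MAF, which is independent of the study sample;
* **cohort**: computed from the *control* samples only.  Cases are never
  used, because a true risk allele would inflate its own MAF and could
  filter itself out.

A variant lacking the chosen source is an error, not a fallback.

## The co-occurrence scan

Within each gene the scan reports every set `S` of rare variants such
that

1. `|S| >= 2` (default `min_set_size`),
2. at least `min_carriers` (default 2) samples carry every member
   (dosage >= 1 at each),
3. `S` is *closed*: adding any other rare variant of the gene strictly
   shrinks its carrier set, and
4. the carriers are mostly cases: case carriers / all carriers is
   strictly greater than `case_fraction` (default 0.5).

Criterion 4 is the package's operationalisation of "variants occurring
mostly in the patients"; 0.5 is a deliberate, configurable reading of
"mostly" since no formal definition exists for such filters.
`min_carriers = 2` keeps private singleton co-occurrences out of the
report by default; set it to 1 to see them.

Closedness makes the enumeration exact without visiting all subsets:
the closed sets are precisely the intersections of the per-sample
carried-variant sets, so the scan computes the intersection closure of
the observed carrier patterns (a fixpoint over pairwise intersections of
bitmasks) instead of iterating over `2^k` subsets.  The test suite
verifies this equivalence against a brute-force subset oracle for genes
with up to 12 rare variants.  Genes with more than `max_variants`
(default 25) rare variants are refused with an explicit error rather
than silently subsetted — at candidate-gene scale this limit is never
reached, and raising it is a conscious user decision.

Output order is deterministic: gene, then descending set size, then
ascending first-member position.  The *anchor* of a set is its
minimal-MAF member (ties broken by position) — the rarest variant is the
natural reference point for phase assessment, since haplotypes carrying
it are few and informative.

## Cis assessment

Unphased case-control genotypes cannot prove that co-occurring alleles
share a chromosome.  The package therefore assesses phase on a phased
reference panel: among all panel haplotypes carrying the anchor allele,
the `cis_fraction` is the proportion also carrying every other member.
A fraction of 1.0 means perfect co-segregation; the default threshold
for calling an unphased carrier "cis-consistent" is 0.9, a configurable
reading of "almost exclusively together".  No statistical re-phasing
(EM/HMM) of the target cohort is attempted — that would import
methodology the carrier-count analysis does not rest on, and the
package never claims proof of phase from unphased data: verdicts are
"cis-consistent" or "ambiguous", never "cis".

A second line of evidence is flank identity: carriers of a recent,
identical-by-descent haplotype should agree over flanking common SNPs.
`flank_identity()` selects, per carrier, the haplotype bearing the
anchor (both haplotypes, flagged, for anchor homozygotes) and reports
the SNPs at which carrier haplotypes differ.  Which and how many flank
SNPs to use is a user choice; the fixture uses 20.

## Contingency statistics

Association is tested on carrier-level 2x2 tables — carrier status
against case/control — matching how carrier counts `n (N)` are reported
in study tables; an allele-level table would count chromosomes instead
and is intentionally not the default.  The fixed orientation is
`a` = case carriers, `b` = control carriers, `c`/`d` the non-carriers.

* **Fisher exact, two-tailed**: the sum of hypergeometric point
  probabilities no larger than the observed one (relative tolerance
  1e-7 for floating ties).  Verified in the tests against a brute-force
  enumeration oracle over all margin-consistent tables.
* **Chi-square**: Pearson statistic, 1 df, optional Yates correction.
* **Test selection**: Fisher when any expected cell count is below 5
  (Cochran's rule, strict `<`), chi-square otherwise.  Because tables
  near the boundary are common at these sample sizes, the Fisher p is
  *always* reported alongside whichever test is selected, so results
  never hinge on the selection rule.
* **Relative risk**: `RR = (a/(a+b)) / (c/(c+d))` — the probability of
  being a case among carriers over that among non-carriers.  The
  orientation is pinned by a regression test (the reference C1-style
  table (10,1,52,68) gives 2.098); the transposed, cohort-style
  orientation would give ~11.1 and does not correspond to how RR
  accompanies carrier-count tables in this literature.
* **Odds ratio**: the cross-product `(ad)/(bc)`, transposition
  invariant; a zero cell yields `NA` unless the Haldane-Anscombe 0.5
  correction is requested.
* Haplotype frequency is the sum of per-carrier haplotype dosages over
  `2N` chromosomes; with all-heterozygous carriers this is `n/(2N)`.

No multiple-testing correction is applied by default: the scan reports
few, pre-filtered candidates and the workflow mirrors single-candidate
confirmation studies.  Wald confidence intervals on log RR / log OR are
available but clearly marked as extensions.

Display rounding truncates frequencies at 3 decimals (4 below 0.01),
the convention of published carrier tables; all files carry full
precision, and truncation is display-only.

## The synthetic-data generator

`simulate_cohort()` and `simulate_panel()` generate the study designs
the package is tested on; `make_lrrk2_fixture()` is the deterministic
instance whose counts match the motivating study exactly (10/62, 1/69
and 7/100 cohort carriers; 45 panel carrier samples spread over 13
populations of a 25-population, 2516-sample panel; 20 identical flank
SNPs on every risk haplotype).  Design choices:

* Carriers are heterozygous by default, matching the `n/(2N)`
  arithmetic of carrier tables; `carrier_hom_fraction` exercises the
  dosage-2 path.
* Background variants are drawn in linkage equilibrium under
  Hardy-Weinberg at MAFs uniform in a configured range; there is no LD
  model beyond the focal haplotype, because nothing in the analysis
  depends on background LD.
* The panel's `recombinant_fraction` controls how many anchor
  haplotypes lack at least one non-anchor member (one member always
  dropped, others with probability 1/2), so `1 - cis_fraction`
  estimates it; the tests check recovery within three binomial standard
  errors.
* All randomness flows from the single `seed`; a fixed seed yields
  byte-identical VCF output, which the tests verify by checksum.

What the simulations do **not** emulate: genotyping error, missingness
patterns, population stratification within a cohort, realistic
recombination maps, and background LD.  Passing tests therefore show
the pipeline's logic and arithmetic are correct under the designed
generative model, not that real sequencing artefacts are handled —
real data should still be quality-controlled upstream.

Problem sizes in the shipped tests were chosen to give stable
Monte-Carlo checks at interactive runtimes: the parameter-recovery
study uses 200 replicate cohorts of 500 cases + 500 controls with
carrier frequencies 0.16 / 0.015, comparing the mean estimated RR to
the analytic disease-given-carrier risk ratio of the design within
three Monte-Carlo standard errors, and the recombination-recovery check
uses a panel of 8000 samples.

## Known limitations

* Cis assessment is only as good as the reference panel: a haplotype
  absent from the panel yields `anchor_hap_count = 0` and a warning,
  not evidence of trans.
* The closed-set scan is exhaustive by design and bounded at
  `max_variants` rare variants per gene; it is a candidate-gene tool,
  not a genome-wide frequent-itemset miner.
* Carrier-level tables treat het and hom carriers alike in the 2x2;
  dosage enters only through the haplotype frequency.
* Published tables this workflow reproduces are occasionally internally
  inconsistent (rounding conventions, count typos); the package always
  reports its own computed values at full precision and leaves
  reconciliation with any printed table to the analyst.
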