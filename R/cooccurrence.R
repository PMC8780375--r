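# Rarity filter and per-gene closed-set enumeration of co-occurring rare
# variants shared by the same carriers.

#' Restrict a genotype matrix to rare variants
#'
#' Retains variants whose minor allele frequency is strictly below
#' `threshold` (default 0.05; a variant with MAF exactly at the threshold is
#' discarded).  The MAF may come from external annotation (`maf_external`,
#' e.g. European reference frequencies) or be computed from the control
#' samples of the cohort; cases are never used for cohort-computed MAF, as
#' risk alleles would inflate their own frequency.
#'
#' @param x a `genotype_matrix`
#' @param threshold rarity threshold, a fraction in (0, 1)
#' @param source `"external"` (annotation) or `"cohort"` (computed from
#'   control samples)
#' @param cohort a `cohort`; required for `source = "cohort"`
#' @param case_label group label of the cases (excluded from cohort MAF)
#' @return the subset `genotype_matrix`; the MAF used is stored in
#'   `variants$maf`
#' @export
maf_filter <- function(x, threshold = 0.05,
                       source = c("external", "cohort"),
                       cohort = NULL, case_label = "P") {
  source <- match.arg(source)
  stopifnot(threshold > 0, threshold < 1)
  if (source == "external") {
    maf <- x$variants$maf_external
    if (anyNA(maf))
      stop("variant(s) lacking external MAF: ",
           paste(x$variants$id[is.na(maf)], collapse = ", "))
  } else {
    if (is.null(cohort)) stop("cohort required for cohort-computed MAF")
    ctrl <- names(cohort$assignment)[cohort$assignment != case_label]
    ctrl <- intersect(ctrl, x$samples)
    if (!length(ctrl)) stop("no control samples available for cohort MAF")
    d <- x$dosage[ctrl, , drop = FALSE]
    called <- colSums(!is.na(d))
    if (any(called == 0L))
      stop("variant(s) with no called control genotypes: ",
           paste(x$variants$id[called == 0L], collapse = ", "))
    af <- colSums(d, na.rm = TRUE) / (2 * called)
    maf <- pmin(af, 1 - af)
  }
  out <- subset_variants(x, which(maf < threshold))
  out$variants$maf <- maf[maf < threshold]
  out
}

#' Carrier status per sample for a variant set
#'
#' A carrier holds at least one copy of every member variant (dosage >= 1
#' at each).  Returns `TRUE`/`FALSE`/`NA` per sample; a sample with a
#' missing call at any member has unknown status (`NA`) and is excluded
#' from downstream carrier counts and denominators.
#'
#' @param x a `genotype_matrix`
#' @param variant_ids character vector of member variant ids
#' @return named logical vector over samples
#' @export
carrier_status <- function(x, variant_ids) {
  stopifnot(length(variant_ids) >= 1L)
  j <- match(variant_ids, x$variants$id)
  if (anyNA(j))
    stop("unknown variant id(s): ",
         paste(variant_ids[is.na(j)], collapse = ", "))
  d <- x$dosage[, j, drop = FALSE]
  miss <- rowSums(is.na(d)) > 0L
  status <- rowSums(d >= 1L) == length(j)
  status[miss] <- NA
  setNames(status, x$samples)
}

#' Carriers of a variant set and their haplotype dosage
#'
#' The per-carrier haplotype dosage is the minimum member dosage: the number
#' of chromosome copies on which the whole set can co-reside assuming cis
#' phase (all-heterozygous carriers have dosage 1; a carrier homozygous at
#' every member has dosage 2).
#'
#' @inheritParams carrier_status
#' @return list with `carriers` (sample ids) and `haplotype_dosage`
#'   (named integer vector over carriers)
#' @export
carriers_of <- function(x, variant_ids) {
  status <- carrier_status(x, variant_ids)
  carriers <- names(status)[!is.na(status) & status]
  j <- match(variant_ids, x$variants$id)
  hd <- if (length(carriers))
    apply(x$dosage[carriers, j, drop = FALSE], 1L, min)
  else integer(0)
  list(carriers = carriers,
       haplotype_dosage = setNames(as.integer(hd), carriers))
}

popcount <- function(m) {
  n <- 0L
  while (any(m > 0L)) {
    n <- n + (m %% 2L)
    m <- m %/% 2L
  }
  n
}

bits_of <- function(m, k) which(bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)

#' Scan genes for closed sets of co-occurring rare variants
#'
#' Per gene, enumerates every *closed* set of two or more rare variants:
#' a set is reported iff it has at least `min_set_size` members and
#' `min_carriers` carriers, it is maximal for its carrier set (adding any
#' other rare variant of the gene would strictly shrink the carrier set),
#' and its carriers are mostly cases (case carriers / all carriers strictly
#' greater than `case_fraction`).  Closed sets are the intersection closure
#' of the per-sample carried-variant sets, so the enumeration is exact
#' without visiting all subsets.
#'
#' Results are sorted by gene, then descending set size, then ascending
#' first-member position, so output order is reproducible.
#'
#' @param x a `genotype_matrix` already restricted to rare variants (see
#'   [maf_filter()]); every variant must carry a gene symbol and a MAF
#'   (`variants$maf` or `variants$maf_external`), the latter defining the
#'   anchor (rarest member)
#' @param cohort a `cohort` labelling every sample
#' @param case_label group label of the cases
#' @param min_set_size minimum number of member variants (default 2)
#' @param min_carriers minimum number of carriers (default 2)
#' @param case_fraction carriers must be cases in more than this fraction
#'   (default 0.5)
#' @param max_variants refuse genes with more rare variants than this
#'   (default 25); raise deliberately for bigger genes
#' @return list of `candidate_haplotype` objects (class `candidate_list`),
#'   each with `gene`, `variant_ids`, `anchor`, `carriers`,
#'   `per_group_carriers` and `haplotype_dosage`
#' @export
scan_gene_sets <- function(x, cohort, case_label = "P",
                           min_set_size = 2L, min_carriers = 2L,
                           case_fraction = 0.5, max_variants = 25L) {
  v <- x$variants
  if (any(v$gene == ""))
    stop("unmapped variant(s): ", paste(v$id[v$gene == ""], collapse = ", "))
  maf <- v$maf %||% v$maf_external
  if (is.null(maf) || anyNA(maf))
    stop("every variant needs a MAF (run maf_filter first or supply ",
         "maf_external) to identify the anchor")
  x <- match_cohort(x, cohort)
  groups <- cohort$assignment[x$samples]
  group_levels <- names(cohort$sizes)
  out <- list()
  for (g in unique(v$gene)) {
    idx <- which(v$gene == g)
    k <- length(idx)
    if (k < min_set_size) next
    if (k > max_variants)
      stop("gene ", g, " has ", k, " rare variants; raise max_variants to ",
           "allow exhaustive closed-set enumeration")
    d <- x$dosage[, idx, drop = FALSE]
    carried <- (!is.na(d)) & d >= 1L
    masks <- as.integer(carried %*% (2^(seq_len(k) - 1L)))
    closed <- unique(masks[masks != 0L])
    repeat {
      inter <- unique(as.vector(outer(closed, closed, bitwAnd)))
      grown <- union(closed, inter[inter != 0L])
      if (length(grown) == length(closed)) break
      closed <- grown
    }
    for (m in closed) {
      member_bits <- bits_of(m, k)
      if (length(member_bits) < min_set_size) next
      carr <- which(bitwAnd(masks, m) == m)
      if (length(carr) < min_carriers) next
      frac_case <- mean(groups[carr] == case_label)
      if (!(frac_case > case_fraction)) next
      members <- idx[member_bits]
      ids <- v$id[members]
      anchor <- ids[order(maf[members], v$pos[members])][1L]
      hd <- apply(x$dosage[carr, members, drop = FALSE], 1L, min)
      pgc <- table(factor(groups[carr], levels = group_levels))
      out[[length(out) + 1L]] <- structure(
        list(gene = g, variant_ids = ids, anchor = anchor,
             carriers = x$samples[carr],
             per_group_carriers = setNames(as.integer(pgc), group_levels),
             haplotype_dosage = setNames(as.integer(hd), x$samples[carr]),
             first_pos = min(v$pos[members])),
        class = "candidate_haplotype")
    }
  }
  ord <- order(vapply(out, `[[`, "", "gene"),
               -vapply(out, function(s) length(s$variant_ids), 0L),
               vapply(out, `[[`, 0L, "first_pos"))
  structure(out[ord], class = "candidate_list")
}

#' @exportS3Method base::print
print.candidate_haplotype <- function(x, ...) {
  cat(sprintf("candidate haplotype in %s: %d variants, %d carriers (%s)\n",
              x$gene, length(x$variant_ids), length(x$carriers),
              paste(sprintf("%s=%d", names(x$per_group_carriers),
                            x$per_group_carriers), collapse = ", ")))
  cat("  members:", paste(x$variant_ids, collapse = ", "), "\n")
  cat("  anchor: ", x$anchor, "\n")
  invisible(x)
}

#' @exportS3Method base::print
print.candidate_list <- function(x, ...) {
  cat(length(x), "candidate haplotype(s)\n")
  for (s in x) print(s)
  invisible(x)
}

#' @export
as.data.frame.candidate_list <- function(x, ...) {
  if (!length(x))
    return(data.frame(gene = character(0), n_variants = integer(0),
                      variant_ids = character(0), anchor = character(0),
                      n_carriers = integer(0), stringsAsFactors = FALSE))
  base <- data.frame(
    gene = vapply(x, `[[`, "", "gene"),
    n_variants = vapply(x, function(s) length(s$variant_ids), 0L),
    variant_ids = vapply(x, function(s)
      paste(s$variant_ids, collapse = ","), ""),
    anchor = vapply(x, `[[`, "", "anchor"),
    n_carriers = vapply(x, function(s) length(s$carriers), 0L),
    stringsAsFactors = FALSE)
  pgc <- do.call(rbind, lapply(x, function(s)
    as.data.frame(as.list(s$per_group_carriers))))
  names(pgc) <- paste0("carriers_", names(x[[1L]]$per_group_carriers))
  cbind(base, pgc)
}
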