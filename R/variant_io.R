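# Reading/writing VCF, cohort tables, gene maps and phased panels, and the
# 0/1/2 alternate-allele dosage matrix they populate.

#' Build a variant table
#'
#' One row per biallelic variant; the canonical `id` column is derived
#' with [variant_id()].  `maf_external` is an annotation frequency in
#' \[0, 1\] (e.g. a European reference MAF), `NA` when absent.
#'
#' @param chrom chromosome label(s)
#' @param pos 1-based position(s)
#' @param ref,alt allele strings (must differ)
#' @param rsid,gene,hgvs_c optional identifier, gene symbol and
#'   coding-sequence name
#' @param maf_external optional annotation MAF
#' @return data frame with columns id, chrom, pos, ref, alt, rsid, gene,
#'   maf_external, hgvs_c
#' @export
new_variant_table <- function(chrom, pos, ref, alt, rsid = "", gene = "",
                              maf_external = NA_real_, hgvs_c = "") {
  pos <- as.integer(pos)
  stopifnot(all(pos >= 1L), all(ref != alt))
  if (any(!is.na(maf_external) & (maf_external < 0 | maf_external > 1)))
    stop("maf_external must lie in [0, 1]")
  data.frame(
    id = variant_id(chrom, pos, ref, alt),
    chrom = as.character(chrom), pos = pos,
    ref = as.character(ref), alt = as.character(alt),
    rsid = as.character(rsid), gene = as.character(gene),
    maf_external = as.numeric(maf_external),
    hgvs_c = as.character(hgvs_c),
    stringsAsFactors = FALSE
  )
}

#' Build a genotype matrix from dosages
#'
#' Validates the 0/1/2/missing dosage coding and, when ordered allele
#' pairs are supplied, that each pair sums to its dosage.
#'
#' @param dosage integer matrix, samples x variants (rownames = sample
#'   ids); values 0, 1, 2 or `NA`
#' @param variants a variant table (see [new_variant_table()]) with one
#'   row per dosage column
#' @param hap1,hap2 optional ordered allele matrices (0/1/NA) of the same
#'   shape
#' @param phased optional logical matrix marking which calls were phased
#' @return a `genotype_matrix`
#' @export
new_genotype_matrix <- function(dosage, variants, hap1 = NULL, hap2 = NULL,
                                phased = NULL) {
  stopifnot(is.matrix(dosage), nrow(variants) == ncol(dosage))
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad)) stop("dosage values must be 0, 1, 2 or missing")
  colnames(dosage) <- variants$id
  if (!is.null(hap1)) {
    stopifnot(identical(dim(hap1), dim(dosage)),
              identical(dim(hap2), dim(dosage)))
    ok <- is.na(hap1) | is.na(hap2) | (hap1 + hap2 == dosage)
    if (!all(ok)) stop("phase allele pair must sum to dosage")
    dimnames(hap1) <- dimnames(dosage)
    dimnames(hap2) <- dimnames(dosage)
  }
  structure(
    list(samples = rownames(dosage), variants = variants, dosage = dosage,
         hap1 = hap1, hap2 = hap2, phased = phased),
    class = "genotype_matrix"
  )
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%d with phase)\n",
              length(x$samples), nrow(x$variants),
              if (is.null(x$phased)) 0L else sum(x$phased, na.rm = TRUE)))
  genes <- unique(x$variants$gene)
  genes <- genes[genes != ""]
  if (length(genes)) cat("genes:", paste(genes, collapse = ", "), "\n")
  invisible(x)
}

#' Subset a genotype matrix to selected variants
#'
#' @param x a `genotype_matrix`
#' @param idx integer, logical or character (variant id) index
#' @return a `genotype_matrix` over the selected variants
#' @export
subset_variants <- function(x, idx) {
  if (is.character(idx)) {
    j <- match(idx, x$variants$id)
    if (anyNA(j)) stop("unknown variant id(s): ",
                       paste(idx[is.na(j)], collapse = ", "))
    idx <- j
  }
  new_genotype_matrix(
    x$dosage[, idx, drop = FALSE], x$variants[idx, , drop = FALSE],
    if (!is.null(x$hap1)) x$hap1[, idx, drop = FALSE],
    if (!is.null(x$hap2)) x$hap2[, idx, drop = FALSE],
    if (!is.null(x$phased)) x$phased[, idx, drop = FALSE]
  )
}

# Parse one VCF record's GT strings for one alternate allele index.
# Returns dosage (copies of that alt), per-haplotype carriage and phase flags.
parse_gt <- function(gt, alt_index, chrom, pos, samples) {
  gt[is.na(gt)] <- "./."   # readers may pre-convert missing calls to NA
  gt <- sub(":.*$", "", gt)
  gt[gt == "."] <- "./."
  ok <- grepl("^(\\.|[0-9]+)[/|](\\.|[0-9]+)$", gt)
  if (any(!ok)) {
    i <- which(!ok)[1L]
    stop(sprintf("malformed GT '%s' for sample %s at %s:%d",
                 gt[i], samples[i], chrom, pos))
  }
  phased <- grepl("|", gt, fixed = TRUE)
  a <- sub("^(.+)[/|](.+)$", "\\1", gt)
  b <- sub("^(.+)[/|](.+)$", "\\2", gt)
  miss <- a == "." | b == "."
  ai <- suppressWarnings(as.integer(a))
  bi <- suppressWarnings(as.integer(b))
  h1 <- ifelse(miss, NA_integer_, as.integer(ai == alt_index))
  h2 <- ifelse(miss, NA_integer_, as.integer(bi == alt_index))
  list(dosage = h1 + h2, h1 = h1, h2 = h2, phased = phased & !miss)
}

#' Read a VCF into a dosage matrix
#'
#' Loads a VCF 4.x file with a GT FORMAT field into a samples-by-variants
#' matrix of alternate-allele dosages (0 = reference homozygote,
#' 1 = heterozygote, 2 = alternate homozygote, `NA` = missing call).
#' Multiallelic records are split into one variant per alternate allele,
#' each dosage counting copies of that allele only.  Where a genotype is
#' written phased (`|`), the ordered allele pair is retained.
#'
#' `EURMAF`, `GENE` and `HGVSC` INFO keys, when present, populate the
#' variant table's external MAF, gene symbol and coding-sequence name.
#'
#' @param path VCF file path
#' @param region optional `"chrom"` or `"chrom:start-end"` filter
#' @return a `genotype_matrix`: list with `samples`, `variants` (data frame
#'   with columns id, chrom, pos, ref, alt, rsid, gene, maf_external,
#'   hgvs_c), `dosage`, and `hap1`/`hap2`/`phased` when any GT was phased
#' @export
read_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(vcf@gt) < 2L) stop("VCF has no sample columns: ", path)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = 7L,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  fmt <- vcf@gt[, 1L]
  no_gt <- !grepl("(^|:)GT($|:)", fmt)
  if (any(no_gt)) {
    i <- which(no_gt)[1L]
    stop(sprintf("record %s:%s has no GT field in FORMAT",
                 fix[i, "CHROM"], fix[i, "POS"]))
  }
  gt <- vcf@gt[, -1L, drop = FALSE]
  samples <- colnames(gt)
  eurmaf <- suppressWarnings(
    as.numeric(vcfR::extract.info(vcf, element = "EURMAF")))
  gene <- vcfR::extract.info(vcf, element = "GENE")
  hgvs <- vcfR::extract.info(vcf, element = "HGVSC")

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    chrom <- fix[i, "CHROM"]; pos <- as.integer(fix[i, "POS"])
    rsid <- fix[i, "ID"]
    if (is.na(rsid) || rsid == ".") rsid <- ""
    per_alt <- lapply(seq_along(alts), function(k) {
      p <- parse_gt(gt[i, ], k, chrom, pos, samples)
      list(var = new_variant_table(
             chrom, pos, fix[i, "REF"], alts[k], rsid = rsid,
             gene = if (is.na(gene[i]) || is.null(gene[i])) "" else gene[i],
             maf_external = if (length(eurmaf)) eurmaf[i] else NA_real_,
             hgvs_c = if (is.na(hgvs[i]) || is.null(hgvs[i])) "" else hgvs[i]),
           gt = p)
    })
    rows[[i]] <- per_alt
  }
  rows <- unlist(rows, recursive = FALSE)
  variants <- do.call(rbind, lapply(rows, `[[`, "var"))
  n <- length(samples); m <- nrow(variants)
  dosage <- matrix(NA_integer_, n, m, dimnames = list(samples, variants$id))
  h1 <- h2 <- matrix(NA_integer_, n, m, dimnames = list(samples, variants$id))
  phased <- matrix(FALSE, n, m, dimnames = list(samples, variants$id))
  for (j in seq_len(m)) {
    p <- rows[[j]]$gt
    dosage[, j] <- p$dosage
    phased[, j] <- p$phased
    h1[, j] <- ifelse(p$phased, p$h1, NA_integer_)
    h2[, j] <- ifelse(p$phased, p$h2, NA_integer_)
  }
  any_phase <- any(phased)
  out <- new_genotype_matrix(dosage, variants,
                             hap1 = if (any_phase) h1,
                             hap2 = if (any_phase) h2,
                             phased = if (any_phase) phased)
  if (!is.null(region)) {
    rg <- parse_region(region)
    keep <- out$variants$chrom == rg$chrom &
      out$variants$pos >= rg$start & out$variants$pos <= rg$end
    out <- subset_variants(out, which(keep))
  }
  out
}

parse_region <- function(region) {
  if (grepl(":", region, fixed = TRUE)) {
    chrom <- sub(":.*$", "", region)
    rng <- strsplit(sub("^.*:", "", region), "-", fixed = TRUE)[[1L]]
    list(chrom = chrom, start = as.integer(rng[1L]),
         end = as.integer(rng[2L]))
  } else {
    list(chrom = region, start = 1L, end = .Machine$integer.max)
  }
}

#' Write a genotype matrix as VCF 4.2
#'
#' Variants are written one biallelic record each.  Unphased output encodes
#' dosage 0/1/2 as `0/0`, `0/1`, `1/1` and missing as `./.`; with
#' `phased = TRUE` the stored ordered allele pairs are written `a|b`.
#' External MAF, gene and HGVS annotations round-trip through the INFO keys
#' `EURMAF`, `GENE` and `HGVSC`.
#'
#' @param x a `genotype_matrix`
#' @param path output file path
#' @param phased write phased genotypes (requires phase for every
#'   non-missing call)
#' @return `path`, invisibly
#' @export
write_vcf <- function(x, path, phased = FALSE) {
  v <- x$variants
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=haploscan",
    "##INFO=<ID=EURMAF,Number=1,Type=Float,Description=\"External minor allele frequency\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=HGVSC,Number=1,Type=String,Description=\"Coding-sequence name\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t")
  )
  info <- vapply(seq_len(nrow(v)), function(j) {
    parts <- character(0)
    if (!is.na(v$maf_external[j]))
      parts <- c(parts, sprintf("EURMAF=%.6g", v$maf_external[j]))
    if (v$gene[j] != "") parts <- c(parts, paste0("GENE=", v$gene[j]))
    if (v$hgvs_c[j] != "") parts <- c(parts, paste0("HGVSC=", v$hgvs_c[j]))
    if (length(parts)) paste(parts, collapse = ";") else "."
  }, character(1))
  lines <- vapply(seq_len(nrow(v)), function(j) {
    if (phased) {
      if (is.null(x$hap1)) stop("no phase stored; cannot write phased VCF")
      a <- x$hap1[, j]; b <- x$hap2[, j]
      if (any(is.na(a) & !is.na(x$dosage[, j])))
        stop("phase missing for non-missing calls at ", v$id[j])
      gt <- ifelse(is.na(a), ".|.", paste0(a, "|", b))
    } else {
      gt <- c("0/0", "0/1", "1/1")[x$dosage[, j] + 1L]
      gt[is.na(gt)] <- "./."
    }
    paste(c(v$chrom[j], v$pos[j],
            if (v$rsid[j] == "") "." else v$rsid[j],
            v$ref[j], v$alt[j], ".", "PASS", info[j], "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a sample-to-group cohort table
#'
#' Expects a two-column tab-delimited file (sample_id, group) with no
#' header, e.g. 62 rows labelled `P` and 69 rows labelled `C1`.
#'
#' @param path TSV path
#' @return a `cohort`: list with `assignment` (named character vector,
#'   sample id -> group label) and `sizes` (named integer vector)
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  tab <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
               col.names = c("sample_id", "group"),
               colClasses = "character"),
    error = function(e) stop("cannot read cohort table ", path, ": ",
                             conditionMessage(e)))
  if (nrow(tab) == 0L) stop("cohort table is empty: ", path)
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample id(s) in cohort table: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]),
               collapse = ", "))
  new_cohort(setNames(tab$group, tab$sample_id))
}

#' Build a cohort from a sample-to-group assignment
#'
#' @param assignment named character vector, sample id -> group label
#' @return a `cohort` with `assignment` and `sizes`
#' @export
new_cohort <- function(assignment) {
  stopifnot(!is.null(names(assignment)), !anyDuplicated(names(assignment)))
  sizes <- table(assignment)
  structure(
    list(assignment = assignment,
         sizes = setNames(as.integer(sizes), names(sizes))),
    class = "cohort"
  )
}

#' @exportS3Method base::print
print.cohort <- function(x, ...) {
  cat("cohort:",
      paste(sprintf("%s=%d", names(x$sizes), x$sizes), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a cohort table
#' @param cohort a `cohort`
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_cohort <- function(cohort, path) {
  write.table(
    data.frame(names(cohort$assignment), unname(cohort$assignment)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Check that every matrix sample has a cohort label
#'
#' @param x a `genotype_matrix`
#' @param cohort a `cohort`
#' @param on_unassigned `"error"` to fail, `"drop"` to warn and drop
#'   unassigned samples from the matrix
#' @return the (possibly subset) `genotype_matrix`
#' @export
match_cohort <- function(x, cohort, on_unassigned = c("error", "drop")) {
  on_unassigned <- match.arg(on_unassigned)
  missing <- setdiff(x$samples, names(cohort$assignment))
  if (!length(missing)) return(x)
  if (on_unassigned == "error")
    stop("samples absent from cohort table: ",
         paste(missing, collapse = ", "))
  warning("dropping ", length(missing), " sample(s) absent from cohort table")
  keep <- x$samples %in% names(cohort$assignment)
  new_genotype_matrix(
    x$dosage[keep, , drop = FALSE], x$variants,
    if (!is.null(x$hap1)) x$hap1[keep, , drop = FALSE],
    if (!is.null(x$hap2)) x$hap2[keep, , drop = FALSE],
    if (!is.null(x$phased)) x$phased[keep, , drop = FALSE])
}

#' Read a variant-to-gene map
#'
#' Two layouts are accepted, sniffed from the file: a four-column interval
#' map (chrom, start, end, gene; 1-based inclusive coordinates) or a
#' two-column rsid map (rsid, gene).  No header.
#'
#' @param path TSV path
#' @return a `gene_map`: list with `type` (`"interval"` or `"rsid"`) and
#'   `table`
#' @export
read_gene_map <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(tab) == 4L) {
    names(tab) <- c("chrom", "start", "end", "gene")
    tab$start <- as.integer(tab$start); tab$end <- as.integer(tab$end)
    if (anyNA(tab$start) || anyNA(tab$end) || any(tab$start > tab$end))
      stop("malformed interval gene map: ", path)
    structure(list(type = "interval", table = tab), class = "gene_map")
  } else if (ncol(tab) == 2L) {
    names(tab) <- c("rsid", "gene")
    structure(list(type = "rsid", table = tab), class = "gene_map")
  } else {
    stop("gene map must have 2 (rsid, gene) or 4 (chrom, start, end, gene) ",
         "columns: ", path)
  }
}

#' Assign gene symbols to a genotype matrix's variants
#'
#' Every mapped variant is assigned exactly one gene; a variant hit by
#' intervals of two different genes is an error.  Unmapped variants keep an
#' empty gene symbol and trigger a warning.
#'
#' @param x a `genotype_matrix`
#' @param map a `gene_map` from [read_gene_map()]
#' @return `x` with the `gene` column filled in
#' @export
assign_genes <- function(x, map) {
  stopifnot(inherits(map, "gene_map"))
  v <- x$variants
  gene <- character(nrow(v))
  if (map$type == "interval") {
    for (i in seq_len(nrow(v))) {
      hit <- map$table$chrom == v$chrom[i] &
        map$table$start <= v$pos[i] & map$table$end >= v$pos[i]
      genes <- unique(map$table$gene[hit])
      if (length(genes) > 1L)
        stop("variant ", v$id[i], " assigned to multiple genes: ",
             paste(genes, collapse = ", "))
      gene[i] <- if (length(genes)) genes else ""
    }
  } else {
    j <- match(v$rsid, map$table$rsid)
    gene <- ifelse(is.na(j), "", map$table$gene[j])
  }
  if (any(gene == ""))
    warning(sum(gene == ""), " variant(s) not mapped to any gene")
  x$variants$gene <- gene
  colnames(x$dosage) <- x$variants$id
  x
}

#' Read a phased reference panel
#'
#' Loads a fully `|`-phased VCF (any `/`-separated genotype is fatal: phase
#' is the panel's purpose) together with a two-column sample-to-population
#' table, into two haplotypes per sample.
#'
#' @param path_vcf phased VCF path
#' @param path_pops TSV path (sample_id, population; no header)
#' @return a `phased_panel`: list with `hap` (2N x variants 0/1/NA matrix,
#'   rows `<sample>_1`, `<sample>_2`), `hap_sample` (sample of each row),
#'   `variants`, `samples` and `populations` (named by sample)
#' @export
read_phased_panel <- function(path_vcf, path_pops) {
  x <- read_vcf(path_vcf)
  unphased <- if (is.null(x$phased)) !is.na(x$dosage) else
    (!x$phased & !is.na(x$dosage))
  if (any(unphased)) {
    bad <- which(unphased, arr.ind = TRUE)
    stop("panel contains unphased genotype(s), e.g. sample ",
         x$samples[bad[1L, 1L]], " at ", x$variants$id[bad[1L, 2L]])
  }
  if (!file.exists(path_pops)) stop("input file not found: ", path_pops)
  pops <- read.table(path_pops, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE,
                     col.names = c("sample_id", "population"),
                     colClasses = "character")
  as_phased_panel(x, setNames(pops$population, pops$sample_id))
}

#' Convert a phased genotype matrix to a phased panel
#'
#' @param x a `genotype_matrix` with phase for every non-missing call
#' @param populations named character vector, sample id -> population label
#' @return a `phased_panel`
#' @export
as_phased_panel <- function(x, populations) {
  if (is.null(x$hap1)) stop("genotype matrix carries no phase")
  miss <- setdiff(x$samples, names(populations))
  if (length(miss))
    stop("panel samples missing from population table: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  n <- length(x$samples)
  hap <- matrix(NA_integer_, 2L * n, nrow(x$variants),
                dimnames = list(
                  paste0(rep(x$samples, each = 2L), c("_1", "_2")),
                  x$variants$id))
  hap[seq(1L, 2L * n, by = 2L), ] <- x$hap1
  hap[seq(2L, 2L * n, by = 2L), ] <- x$hap2
  structure(
    list(hap = hap, hap_sample = rep(x$samples, each = 2L),
         variants = x$variants, samples = x$samples,
         populations = populations[x$samples]),
    class = "phased_panel"
  )
}

#' @exportS3Method base::print
print.phased_panel <- function(x, ...) {
  cat(sprintf("phased_panel: %d samples (%d haplotypes) x %d variants, %d populations\n",
              length(x$samples), nrow(x$hap), nrow(x$variants),
              length(unique(x$populations))))
  invisible(x)
}

#' Write a sample-to-population table
#' @param populations named character vector (sample id -> population)
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_populations <- function(populations, path) {
  write.table(data.frame(names(populations), unname(populations)),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# Match candidate variant ids against a panel, falling back to rsid.
match_panel <- function(panel, ids) {
  j <- match(ids, panel$variants$id)
  if (anyNA(j)) {
    j2 <- match(ids, panel$variants$rsid)  # allow plain rsids too
    j[is.na(j)] <- j2[is.na(j)]
  }
  if (anyNA(j))
    stop("candidate variant(s) absent from panel: ",
         paste(ids[is.na(j)], collapse = ", "))
  j
}
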