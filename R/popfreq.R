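# Cross-population haplotype frequency table from a phased panel.

#' Per-population haplotype carrier counts and frequencies
#'
#' For each population of the panel: the number of haplotypes carrying
#' every member allele of the candidate, the number of carrier samples
#' (at least one such haplotype), and the haplotype frequency
#' full-haplotype count / (2 N_population).  With all-heterozygous
#' carriers the haplotype count equals the carrier count, so the frequency
#' is the familiar n / (2N).
#'
#' All populations are returned (zero-carrier rows included), sorted by
#' descending frequency then population label; [write_popfreq()] omits the
#' zero rows from the display table, as is conventional.
#'
#' @param panel a `phased_panel`
#' @param candidate a `candidate_haplotype`
#' @return data frame (class `popfreq_table`) with columns `population`,
#'   `n_carriers`, `n_samples`, `n_haplotypes`, `frequency`
#' @export
population_frequencies <- function(panel, candidate) {
  j <- match_panel(panel, candidate$variant_ids)
  h <- panel$hap[, j, drop = FALSE]
  full_hap <- rowSums(h == 1L, na.rm = TRUE) == length(j) &
    rowSums(is.na(h)) == 0L
  pop_of_hap <- panel$populations[panel$hap_sample]
  pops <- sort(unique(panel$populations))
  rows <- lapply(pops, function(p) {
    sel <- pop_of_hap == p
    n_samples <- sum(panel$populations == p)
    if (n_samples == 0L) {
      warning("empty population skipped: ", p)
      return(NULL)
    }
    n_hap <- sum(full_hap[sel])
    carr <- tapply(full_hap[sel], panel$hap_sample[sel], any)
    data.frame(population = p, n_carriers = sum(carr),
               n_samples = n_samples, n_haplotypes = n_hap,
               frequency = n_hap / (2 * n_samples),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$frequency, out$population), ]
  rownames(out) <- NULL
  class(out) <- c("popfreq_table", "data.frame")
  out
}

#' Truncate a haplotype frequency for display
#'
#' Frequencies are truncated (not rounded) at 3 decimal places, or 4 when
#' the value is below 0.01, matching the convention of published carrier
#' tables (e.g. 48/5032 = 0.00954 displays as 0.0095).
#'
#' @param x numeric vector of frequencies
#' @return character vector
#' @export
format_frequency <- function(x) {
  vapply(x, function(v) {
    d <- if (!is.na(v) && v < 0.01) 4L else 3L
    formatC(floor(v * 10^d) / 10^d, format = "f", digits = d)
  }, character(1))
}

#' Write the population frequency table as TSV
#'
#' Populations without the haplotype are omitted from the TSV (they remain
#' in the full data frame / JSON output); frequencies are displayed with
#' [format_frequency()].
#'
#' @param x a `popfreq_table`
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_popfreq <- function(x, path) {
  shown <- x[x$n_haplotypes > 0L, , drop = FALSE]
  shown$frequency <- format_frequency(shown$frequency)
  write.table(shown, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
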