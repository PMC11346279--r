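# Carrier-free probability: chance a random individual carries none of a
# variant set, given sampled frequencies and chromosome-appropriate copy
# numbers in a mixed XX/XY population.

#' Gene copies carried per individual
#'
#' Autosomal genes: 2 copies for every karyotype. X-linked genes: 2 copies
#' for XX individuals, 1 for XY (hemizygous). Pseudoautosomal-region
#' subtleties are ignored; inheritance mode is a per-gene property.
#'
#' @param inheritance_mode `"autosomal"` or `"x_linked"`.
#' @param karyotype `"XX"` or `"XY"`.
#' @return Integer 1 or 2.
#' @export
chromosome_copies <- function(inheritance_mode, karyotype) {
  inheritance_mode <- match.arg(inheritance_mode, c("autosomal", "x_linked"))
  karyotype <- match.arg(karyotype, c("XX", "XY"))
  if (inheritance_mode == "autosomal") 2L
  else if (karyotype == "XX") 2L else 1L
}

#' Probability an individual carries none of a variant list
#'
#' Assuming variants assort randomly and independently at the given allele
#' frequencies, an individual of the given karyotype escapes variant `i`
#' with probability `(1 - p_i)^copies_i`, where the copy number comes from
#' [chromosome_copies()]; the carrier-free probability is the product over
#' variants. Linkage between variants would raise the true value; it is
#' not modeled.
#'
#' @param freq Numeric vector of allele frequencies in \[0, 1\].
#' @param inheritance_mode Character vector (recycled) of modes per variant.
#' @param karyotype `"XX"` or `"XY"`.
#' @return Probability in \[0, 1\]; 1 for an empty list.
#' @examples
#' noncarrier_probability(0.5, "autosomal", "XX")  # 0.25
#' @export
noncarrier_probability <- function(freq, inheritance_mode, karyotype) {
  if (length(freq) == 0L) return(1)
  if (any(is.na(freq)) || any(freq < 0 | freq > 1))
    stop("frequencies must lie in [0, 1] and be non-missing", call. = FALSE)
  inheritance_mode <- rep_len(inheritance_mode, length(freq))
  copies <- vapply(inheritance_mode, chromosome_copies, integer(1),
                   karyotype = karyotype)
  prod((1 - freq)^copies)
}

#' Percent of a population expected to carry none of a variant set
#'
#' Reproduces the carrier-free estimator for one population: each variant
#' contributes its sampled frequency AC/AN in that population; the
#' per-karyotype non-carrier probabilities are multiplied across variants
#' and averaged over the karyotype mix (default half-XX/half-XY). Variants
#' with AN = 0 in the population are skipped and counted, never imputed:
#' silence is not zero. By default only shortlisted variants that are
#' notionally population-distinctive (absent from at least one population's
#' sample) enter the set, so ubiquitous common variants can be kept out of
#' a "rare distinctive variants" claim; set `distinctive_only = FALSE` to
#' include everything.
#'
#' @param table A [frequency_table()].
#' @param pop Population label in the table.
#' @param gene Optional gene label to restrict the variant set.
#' @param distinctive_only Keep only variants absent in at least one
#'   population (default `TRUE`).
#' @param shortlisted_only Keep only shortlisted variants (default `TRUE`).
#' @param xx_fraction Fraction of XX individuals, default 0.5.
#' @return An object of class `carrier_free_estimate`: list with
#'   `population`, `p_xx`, `p_xy`, `percent`, `n_variants_used`,
#'   `n_variants_skipped_no_data`.
#' @export
population_noncarrier_percent <- function(table, pop, gene = NULL,
                                          distinctive_only = TRUE,
                                          shortlisted_only = TRUE,
                                          xx_fraction = 0.5) {
  stopifnot(inherits(table, "frequency_table"),
            xx_fraction >= 0, xx_fraction <= 1)
  if (!pop %in% table$populations)
    stop("unknown population label: ", pop, call. = FALSE)
  recs <- table$records
  if (!is.null(gene))
    recs <- Filter(function(r) r$gene == gene, recs)
  if (shortlisted_only)
    recs <- Filter(function(r) isTRUE(r$shortlisted), recs)
  if (distinctive_only)
    recs <- Filter(is_population_distinctive, recs)
  freq <- numeric(); mode <- character(); skipped <- 0L
  for (r in recs) {
    f <- frequency(r, pop)
    if (is.na(f)) { skipped <- skipped + 1L; next }
    freq <- c(freq, f)
    mode <- c(mode, r$inheritance_mode)
  }
  p_xx <- noncarrier_probability(freq, mode, "XX")
  p_xy <- noncarrier_probability(freq, mode, "XY")
  structure(list(population = pop, p_xx = p_xx, p_xy = p_xy,
                 percent = 100 * (xx_fraction * p_xx +
                                  (1 - xx_fraction) * p_xy),
                 n_variants_used = length(freq),
                 n_variants_skipped_no_data = skipped),
            class = "carrier_free_estimate")
}

#' @export
print.carrier_free_estimate <- function(x, ...) {
  cat(sprintf(
    "%s: %.2f%% carrier-free (p_xx = %.4f, p_xy = %.4f; %d variants, %d skipped no-data)\n",
    x$population, x$percent, x$p_xx, x$p_xy,
    x$n_variants_used, x$n_variants_skipped_no_data))
  invisible(x)
}

#' Carrier-free estimates for every population in a table
#'
#' @inheritParams population_noncarrier_percent
#' @param pops Populations to include; default all in the table.
#' @return data.frame with one row per population (columns `population`,
#'   `p_xx`, `p_xy`, `percent`, `n_variants_used`,
#'   `n_variants_skipped_no_data`).
#' @export
carrier_free_table <- function(table, pops = table$populations, gene = NULL,
                               distinctive_only = TRUE,
                               shortlisted_only = TRUE, xx_fraction = 0.5) {
  rows <- lapply(pops, function(p) {
    e <- population_noncarrier_percent(table, p, gene = gene,
                                       distinctive_only = distinctive_only,
                                       shortlisted_only = shortlisted_only,
                                       xx_fraction = xx_fraction)
    data.frame(population = e$population, p_xx = e$p_xx, p_xy = e$p_xy,
               percent = e$percent, n_variants_used = e$n_variants_used,
               n_variants_skipped_no_data = e$n_variants_skipped_no_data)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
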