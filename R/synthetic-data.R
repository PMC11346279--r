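# Synthetic allele-frequency tables: a stated "true" world (per-variant,
# per-population frequencies drawn from a site-frequency-spectrum proxy)
# plus binomial sampling of allele counts at population-specific depths.

#' Site-frequency-spectrum specifications
#'
#' Three simple proxies for the frequency regime of a variant pool:
#' * `spectrum_point_mass(p)` — every variant at one true frequency `p`;
#'   the sharpest version of "many equally rare variants".
#' * `spectrum_log_uniform(p_min, p_max)` — log10-frequency uniform on
#'   \[log10 p_min, log10 p_max\]; a neutral-ish spread over orders of
#'   magnitude, with appreciable common-variant mass if `p_max` is large.
#' * `spectrum_constraint_skewed(p_min, p_max, skew)` — log-uniform tilted
#'   by `frequency^(-skew)`, renormalized over a discrete grid of 10^4
#'   log-spaced points; shifts mass toward rarer frequencies, emulating
#'   selective constraint qualitatively (no population-genetic model is
#'   implied).
#'
#' @param p Point-mass frequency in (0, 1\].
#' @param p_min,p_max Frequency bounds, `0 < p_min <= p_max <= 1`.
#' @param skew Non-negative tilt exponent; 0 recovers log-uniform on the
#'   grid.
#' @return An object of class `spectrum_spec`.
#' @name spectrum_spec
NULL

#' @rdname spectrum_spec
#' @export
spectrum_point_mass <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1)
    stop("point-mass frequency must lie in (0, 1]", call. = FALSE)
  structure(list(kind = "point_mass", p = p), class = "spectrum_spec")
}

#' @rdname spectrum_spec
#' @export
spectrum_log_uniform <- function(p_min, p_max) {
  check_bounds(p_min, p_max)
  structure(list(kind = "log_uniform", p_min = p_min, p_max = p_max),
            class = "spectrum_spec")
}

#' @rdname spectrum_spec
#' @export
spectrum_constraint_skewed <- function(p_min, p_max, skew = 1) {
  check_bounds(p_min, p_max)
  if (!is.numeric(skew) || length(skew) != 1L || skew < 0)
    stop("`skew` must be a non-negative number", call. = FALSE)
  structure(list(kind = "constraint_skewed",
                 p_min = p_min, p_max = p_max, skew = skew),
            class = "spectrum_spec")
}

check_bounds <- function(p_min, p_max) {
  if (!is.numeric(p_min) || !is.numeric(p_max) ||
      length(p_min) != 1L || length(p_max) != 1L ||
      !(p_min > 0) || !(p_min <= p_max) || !(p_max <= 1))
    stop("spectrum bounds must satisfy 0 < p_min <= p_max <= 1",
         call. = FALSE)
  invisible(TRUE)
}

# Draw n i.i.d. frequencies from a spectrum using the current RNG state.
draw_frequencies <- function(spectrum, n) {
  stopifnot(inherits(spectrum, "spectrum_spec"), n >= 0)
  if (n == 0) return(numeric())
  switch(spectrum$kind,
    point_mass = rep(spectrum$p, n),
    log_uniform = 10^stats::runif(n, log10(spectrum$p_min),
                                  log10(spectrum$p_max)),
    constraint_skewed = {
      grid <- 10^seq(log10(spectrum$p_min), log10(spectrum$p_max),
                     length.out = 10000L)
      w <- grid^(-spectrum$skew)
      sample(grid, n, replace = TRUE, prob = w / sum(w))
    },
    stop("unknown spectrum kind: ", spectrum$kind, call. = FALSE))
}

#' Draw a synthetic truth: true frequencies per variant per population
#'
#' Frequencies are i.i.d. draws from `spectrum`. With `shared = TRUE`
#' (the null the artifact argument turns on) a single frequency is drawn
#' per variant and copied to every population, so populations are
#' statistically identical by construction; with `shared = FALSE` each
#' population gets an independent draw.
#'
#' @param spectrum A [spectrum_spec] object.
#' @param n_variants Number of variants (>= 0).
#' @param populations Character vector of population labels.
#' @param shared Share one true frequency per variant across populations?
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param gene Gene label applied to all variants.
#' @param inheritance_mode `"autosomal"` or `"x_linked"`.
#' @return An object of class `synthetic_truth` with a
#'   `n_variants x populations` frequency matrix `freq`.
#' @export
draw_truth <- function(spectrum, n_variants, populations, shared = TRUE,
                       seed = 1L, gene = "GENE", inheritance_mode = "autosomal") {
  stopifnot(inherits(spectrum, "spectrum_spec"),
            n_variants >= 0, length(populations) >= 1L)
  inheritance_mode <- match.arg(inheritance_mode, c("autosomal", "x_linked"))
  populations <- as.character(populations)
  set.seed(as.integer(seed))
  if (shared) {
    p <- draw_frequencies(spectrum, n_variants)
    freq <- matrix(p, nrow = n_variants, ncol = length(populations))
  } else {
    freq <- matrix(draw_frequencies(spectrum, n_variants * length(populations)),
                   nrow = n_variants, ncol = length(populations))
  }
  ids <- if (n_variants > 0)
    sprintf("%s_v%03d", gene, seq_len(n_variants)) else character()
  dimnames(freq) <- list(ids, populations)
  structure(list(variant_id = ids,
                 gene = rep(gene, n_variants),
                 inheritance_mode = rep(inheritance_mode, n_variants),
                 freq = freq,
                 populations = populations,
                 spectrum = spectrum, shared = shared,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Combine synthetic truths over the same populations
#'
#' Used to build multi-gene truths (e.g. one X-linked and one autosomal
#' gene) from per-gene draws.
#'
#' @param ... `synthetic_truth` objects sharing identical population labels.
#' @return A single `synthetic_truth`.
#' @export
combine_truth <- function(...) {
  truths <- list(...)
  stopifnot(length(truths) >= 1L,
            all(vapply(truths, inherits, logical(1), "synthetic_truth")))
  pops <- truths[[1]]$populations
  for (tr in truths)
    if (!identical(tr$populations, pops))
      stop("all truths must share identical population labels", call. = FALSE)
  ids <- unlist(lapply(truths, `[[`, "variant_id"))
  if (anyDuplicated(ids))
    stop("combined truths must have unique variant ids", call. = FALSE)
  structure(list(variant_id = ids,
                 gene = unlist(lapply(truths, `[[`, "gene")),
                 inheritance_mode = unlist(lapply(truths, `[[`, "inheritance_mode")),
                 freq = do.call(rbind, lapply(truths, `[[`, "freq")),
                 populations = pops,
                 spectrum = lapply(truths, `[[`, "spectrum"),
                 shared = all(vapply(truths, `[[`, logical(1), "shared")),
                 seed = truths[[1]]$seed),
            class = "synthetic_truth")
}

#' Sample a frequency table from a synthetic truth
#'
#' For each variant and population, the allele number AN is the one implied
#' by the population's karyotype composition and the variant's inheritance
#' mode ([allele_number()]), and the allele count AC is a binomial draw
#' with AN trials at the variant's true frequency. Allele draws are
#' exchangeable: diploid structure and Hardy-Weinberg pairing are ignored,
#' matching the allele-level arithmetic of the downstream estimators.
#'
#' @param truth A [draw_truth()] result.
#' @param pop_specs List of [population_spec()]s whose labels match the
#'   truth's populations (any order).
#' @param seed Integer seed; sampling is deterministic given the seed.
#' @return A [frequency_table()] with all records flagged shortlisted.
#' @export
sample_table <- function(truth, pop_specs, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  labels <- vapply(pop_specs, `[[`, character(1), "label")
  if (!setequal(labels, truth$populations))
    stop("population labels of pop_specs do not match the truth: ",
         paste(setdiff(truth$populations, labels), collapse = ", "),
         call. = FALSE)
  specs <- stats::setNames(pop_specs, labels)[truth$populations]
  set.seed(as.integer(seed))
  records <- vector("list", length(truth$variant_id))
  for (i in seq_along(truth$variant_id)) {
    mode <- truth$inheritance_mode[[i]]
    an <- vapply(specs, allele_number, integer(1), inheritance_mode = mode)
    ac <- stats::rbinom(length(an), size = an, prob = truth$freq[i, ])
    records[[i]] <- variant_record(truth$variant_id[[i]], truth$gene[[i]],
                                   mode,
                                   ac = stats::setNames(ac, truth$populations),
                                   an = stats::setNames(an, truth$populations))
  }
  frequency_table(records, populations = truth$populations)
}

#' Default nine-population karyotype specs
#'
#' Nine unevenly sampled populations mirroring a gnomAD-v3-scale pooled
#' dataset: two deeply sampled groups (EUR 36,000 and AFR 23,000 people),
#' three small founder/regional groups (AMI 450, ASH 1,662, EAS 1,567),
#' and four mid-sized groups under a 15,000-person ceiling. Each is split
#' half-XX/half-XY (odd counts round the XX half up).
#'
#' @return Named list of [population_spec()]s.
#' @export
default_population_specs <- function() {
  persons <- c(AFR = 23000L, AMI = 450L, ASH = 1662L, EAS = 1567L,
               SAS = 15000L, EUR = 36000L, FIN = 10000L, AMR = 14000L,
               oth = 3000L)
  out <- lapply(names(persons), function(lab) {
    n <- persons[[lab]]
    population_spec(lab, n_xx = ceiling(n / 2), n_xy = floor(n / 2))
  })
  stats::setNames(out, names(persons))
}

#' Default two-gene synthetic truth
#'
#' A pool shaped like the motivating dataset: 131 shared rare variants
#' split between one X-linked gene (ACE2-like, 41 variants) and one
#' autosomal gene (TMPRSS2-like, 90 variants), frequencies from a
#' constraint-skewed spectrum on \[1e-6, 1e-3\].
#'
#' @param seed Integer seed.
#' @param populations Population labels; default those of
#'   [default_population_specs()].
#' @return A `synthetic_truth` with 131 variants.
#' @export
default_truth <- function(seed = 1L,
                          populations = names(default_population_specs())) {
  spec <- spectrum_constraint_skewed(1e-6, 1e-3, skew = 1)
  combine_truth(
    draw_truth(spec, 41L, populations, shared = TRUE, seed = seed,
               gene = "GENE_X", inheritance_mode = "x_linked"),
    draw_truth(spec, 90L, populations, shared = TRUE, seed = seed + 1L,
               gene = "GENE_A", inheritance_mode = "autosomal"))
}
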