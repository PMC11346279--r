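# Discovery simulation: identical true variant pools + lopsided sample
# sizes produce tallies that track sample size. Analytic expected tallies
# check the simulator; the mean origin-rooted r-squared quantifies how
# strongly the artifact mimics real population differences.

#' Expected number of variants observed at a given sampling depth
#'
#' Under binomial sampling of `n_alleles` gene copies, a variant at true
#' frequency `p` is seen at least once with probability `1 - (1-p)^n`;
#' the expected tally of a pool is the sum of those detection
#' probabilities. Non-decreasing in `n_alleles` and in every frequency —
#' the discovery-curve fact the artifact rests on.
#'
#' @param true_frequencies Numeric vector of frequencies in \[0, 1\].
#' @param n_alleles Non-negative integer number of sampled alleles.
#' @return Expected count (real).
#' @examples
#' expected_tally(rep(1e-5, 131), 72000)  # about 67.24
#' @export
expected_tally <- function(true_frequencies, n_alleles) {
  if (length(true_frequencies) == 0L) return(0)
  stopifnot(all(true_frequencies >= 0 & true_frequencies <= 1),
            length(n_alleles) == 1L, n_alleles >= 0)
  sum(detection_probability(true_frequencies, n_alleles))
}

#' Expected discovery curve over a ladder of sampling depths
#'
#' @param true_frequencies Numeric vector of frequencies in \[0, 1\].
#' @param n_ladder Integer vector of allele numbers.
#' @return data.frame with columns `n_alleles`, `expected_tally`.
#' @export
expected_discovery_curve <- function(true_frequencies, n_ladder) {
  data.frame(n_alleles = n_ladder,
             expected_tally = vapply(n_ladder, expected_tally,
                                     numeric(1),
                                     true_frequencies = true_frequencies))
}

#' Configure an artifact experiment
#'
#' Bundles the pieces of a lopsided-sampling experiment: a frequency
#' spectrum, the number of variants all populations share, per-population
#' karyotype specs (hence allele numbers), a replicate count, and a master
#' seed. Replicate seeds are derived from the master seed by a fixed rule
#' (see [replicate_seed()]) so any single replicate can be reproduced in
#' isolation.
#'
#' @param spectrum A [spectrum_spec] object.
#' @param n_variants Number of shared variants.
#' @param pop_specs List of [population_spec()]s.
#' @param replicates Number of replicate tables (>= 1).
#' @param seed Master seed (integer).
#' @param gene Gene label for the simulated variants.
#' @param inheritance_mode `"autosomal"` or `"x_linked"`.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(spectrum, n_variants, pop_specs,
                              replicates = 200L, seed = 1L,
                              gene = "GENE",
                              inheritance_mode = "autosomal") {
  stopifnot(inherits(spectrum, "spectrum_spec"), n_variants >= 0,
            length(pop_specs) >= 1L, replicates >= 1L)
  inheritance_mode <- match.arg(inheritance_mode, c("autosomal", "x_linked"))
  structure(list(spectrum = spectrum, n_variants = as.integer(n_variants),
                 pop_specs = pop_specs, replicates = as.integer(replicates),
                 seed = as.integer(seed), gene = gene,
                 inheritance_mode = inheritance_mode),
            class = "experiment_config")
}

#' Derive a replicate seed from a master seed
#'
#' Fixed documented rule: `(master * 1009 + replicate * 7919 + stage) mod
#' (2^31 - 1)`, with stage 0 for the truth draw and stage 1 for table
#' sampling. Keeps every derived seed a valid 32-bit integer and makes
#' single replicates reproducible without rerunning the whole experiment.
#'
#' @param master Master seed (integer).
#' @param replicate Replicate index (1-based).
#' @param stage Stage offset (0 = truth, 1 = sampling).
#' @return Integer seed.
#' @export
replicate_seed <- function(master, replicate, stage = 0L) {
  as.integer((as.numeric(master) * 1009 + as.numeric(replicate) * 7919 +
              stage) %% 2147483647)
}

#' The default lopsided-sampling experiment
#'
#' 131 variants shared across 9 populations at point-mass true frequency
#' 1e-5, with autosomal allele numbers {72000, 46000, 30000, 28000, 21000,
#' 10000, 3324, 3134, 900}: two deeply sampled populations, three small
#' ones at their motivating person counts doubled, and four mid-sized
#' fixture choices.
#'
#' @param replicates Number of replicates, default 200.
#' @param seed Master seed, default 1.
#' @return An `experiment_config`.
#' @export
default_experiment_config <- function(replicates = 200L, seed = 1L) {
  persons <- c(EUR = 36000L, AFR = 23000L, SAS = 15000L, AMR = 14000L,
               FIN = 10500L, oth = 5000L, ASH = 1662L, EAS = 1567L,
               AMI = 450L)
  specs <- lapply(names(persons), function(lab) {
    n <- persons[[lab]]
    population_spec(lab, n_xx = ceiling(n / 2), n_xy = floor(n / 2))
  })
  experiment_config(spectrum_point_mass(1e-5), 131L, specs,
                    replicates = replicates, seed = seed,
                    gene = "GENE_A", inheritance_mode = "autosomal")
}

#' Run a lopsided-sampling artifact experiment
#'
#' For each replicate: draw a shared truth from the spectrum, binomially
#' sample a frequency table at the configured depths, tally variants
#' present per population, and fit the through-origin regression of tally
#' on allele number. Analytic expected tallies (mean of
#' [expected_tally()] over the replicate truths) are attached for
#' comparison with the simulated means.
#'
#' @param config An [experiment_config()].
#' @return An object of class `experiment_result`: list with `tallies`
#'   (replicates x populations matrix), `sample_sizes` (named vector),
#'   `r2_origin` and `slope` (per replicate), `expected_tally` (named,
#'   analytic), `summary` (per-population data.frame), and `config`.
#' @export
run_artifact_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  labels <- vapply(config$pop_specs, `[[`, character(1), "label")
  n_pop <- length(labels)
  tallies <- matrix(NA_integer_, nrow = config$replicates, ncol = n_pop,
                    dimnames = list(NULL, labels))
  r2 <- numeric(config$replicates)
  slope <- numeric(config$replicates)
  expected <- matrix(NA_real_, nrow = config$replicates, ncol = n_pop,
                     dimnames = list(NULL, labels))
  an <- vapply(config$pop_specs, allele_number, integer(1),
               inheritance_mode = config$inheritance_mode)
  names(an) <- labels
  for (r in seq_len(config$replicates)) {
    truth <- draw_truth(config$spectrum, config$n_variants, labels,
                        shared = TRUE,
                        seed = replicate_seed(config$seed, r, 0L),
                        gene = config$gene,
                        inheritance_mode = config$inheritance_mode)
    tab <- sample_table(truth, config$pop_specs,
                        seed = replicate_seed(config$seed, r, 1L))
    tr <- tally_per_population(tab, config$gene)
    tallies[r, ] <- tr$per_population$tally[match(labels,
                                                  tr$per_population$population)]
    fit <- fit_tally(tr)
    r2[r] <- fit$r2_origin
    slope[r] <- fit$slope
    expected[r, ] <- vapply(labels, function(pop)
      expected_tally(truth$freq[, pop], an[[pop]]), numeric(1))
  }
  summary <- data.frame(
    population = labels,
    sample_size = unname(an),
    mean_tally = colMeans(tallies),
    sd_tally = apply(tallies, 2, stats::sd),
    expected_tally = colMeans(expected))
  structure(list(tallies = tallies, sample_sizes = an,
                 r2_origin = r2, slope = slope,
                 expected_tally = colMeans(expected),
                 summary = summary, config = config),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("artifact experiment: %d replicates, %d shared variants\n",
              x$config$replicates, x$config$n_variants))
  cat(sprintf("mean origin-rooted r2 = %.4f (sd %.4f)\n",
              mean(x$r2_origin, na.rm = TRUE),
              stats::sd(x$r2_origin, na.rm = TRUE)))
  print(x$summary, digits = 4)
  invisible(x)
}
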