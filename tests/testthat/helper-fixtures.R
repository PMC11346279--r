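# Shared fixtures, all built in code.

# Small hand-written table: 2 genes x 3 populations.
# GENE_X (x_linked): vX1 present in A+C, absent in B; vX2 absent everywhere.
# GENE_A (autosomal): vA1 present everywhere; vA2 present in C only, with
# no data in B; vA3 not shortlisted.
toy_table <- function() {
  pops <- c("A", "B", "C")
  frequency_table(list(
    variant_record("vX1", "GENE_X", "x_linked",
                   ac = c(A = 2, B = 0, C = 1),
                   an = c(A = 900, B = 500, C = 400)),
    variant_record("vX2", "GENE_X", "x_linked",
                   ac = c(A = 0, B = 0, C = 0),
                   an = c(A = 900, B = 500, C = 400)),
    variant_record("vA1", "GENE_A", "autosomal",
                   ac = c(A = 5, B = 3, C = 8),
                   an = c(A = 1000, B = 600, C = 800)),
    variant_record("vA2", "GENE_A", "autosomal",
                   ac = c(A = 0, B = 0, C = 2),
                   an = c(A = 1000, B = 0, C = 800)),
    variant_record("vA3", "GENE_A", "autosomal",
                   ac = c(A = 1, B = 0, C = 0),
                   an = c(A = 1000, B = 600, C = 800),
                   shortlisted = FALSE)),
    populations = pops)
}

# Random valid variant_record over given populations.
random_record <- function(id, pops, gene = "G", mode = "autosomal") {
  an <- sample(0:50, length(pops), replace = TRUE)
  ac <- vapply(an, function(n) if (n == 0) 0L else sample(0:n, 1L),
               integer(1))
  variant_record(id, gene, mode,
                 ac = stats::setNames(ac, pops),
                 an = stats::setNames(an, pops))
}

# Monte-Carlo non-carrier oracle: simulate n_individuals, each drawing
# `copies` independent alleles per variant at its frequency; returns the
# fraction carrying zero copies of every variant. Independent of the
# product-form estimator under test.
mc_noncarrier <- function(freq, mode, karyotype, n_individuals) {
  free <- rep(TRUE, n_individuals)
  for (i in seq_along(freq)) {
    copies <- chromosome_copies(mode[[i]], karyotype)
    hits <- stats::rbinom(n_individuals, copies, freq[[i]])
    free <- free & hits == 0L
  }
  mean(free)
}

# Dense grid-search minimizer of the through-origin SSE, the independent
# oracle for the closed-form slope. Two-stage grid, final step 1e-5.
grid_origin_slope <- function(x, y) {
  sse <- function(b) sum((y - b * x)^2)
  hi <- max(2 * abs(sum(x * y) / sum(x * x)), 1) + 1
  coarse <- seq(-hi, hi, length.out = 4001L)
  b0 <- coarse[which.min(vapply(coarse, sse, numeric(1)))]
  fine <- seq(b0 - 0.005, b0 + 0.005, by = 1e-5)
  fine[which.min(vapply(fine, sse, numeric(1)))]
}
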