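test_that("copy numbers follow inheritance mode and karyotype", {
  expect_equal(chromosome_copies("autosomal", "XX"), 2L)
  expect_equal(chromosome_copies("autosomal", "XY"), 2L)
  expect_equal(chromosome_copies("x_linked", "XX"), 2L)
  expect_equal(chromosome_copies("x_linked", "XY"), 1L)
})

test_that("non-carrier probability is the product of per-variant escapes", {
  expect_equal(noncarrier_probability(numeric(), character(), "XX"), 1)
  expect_equal(noncarrier_probability(0.5, "autosomal", "XX"), 0.25)
  expect_equal(noncarrier_probability(c(0.01, 0.001),
                                      c("x_linked", "autosomal"), "XY"),
               0.99 * 0.999^2)
  expect_equal(noncarrier_probability(c(0.01, 0.001),
                                      c("x_linked", "autosomal"), "XX"),
               0.99^2 * 0.999^2)
  expect_error(noncarrier_probability(1.2, "autosomal", "XX"), "\\[0, 1\\]")
})

test_that("product form agrees with an individual-level Monte-Carlo oracle", {
  set.seed(88)
  n_ind <- 1e5
  freq <- c(0.05, 0.2, 0.01)
  mode <- c("x_linked", "autosomal", "x_linked")
  for (kar in c("XX", "XY")) {
    est <- noncarrier_probability(freq, mode, kar)
    sim <- mc_noncarrier(freq, mode, kar, n_ind)
    expect_lt(abs(est - sim), 3 * sqrt(est * (1 - est) / n_ind))
  }
})

test_that("population percent reproduces direct product arithmetic", {
  # single X-linked variant at sampled frequency 0.5 in pop A, absent in B
  tab <- frequency_table(list(
    variant_record("v1", "GX", "x_linked",
                   ac = c(A = 50, B = 0), an = c(A = 100, B = 100))))
  e <- population_noncarrier_percent(tab, "A")
  expect_equal(e$p_xy, 0.5)
  expect_equal(e$p_xx, 0.25)
  expect_equal(e$percent, 37.5)
  expect_equal(e$n_variants_used, 1L)
  # everything absent -> 100%
  eb <- population_noncarrier_percent(tab, "B")
  expect_equal(eb$percent, 100)
  expect_error(population_noncarrier_percent(tab, "Z"), "Z")
})

test_that("estimates compose from extracted frequencies", {
  set.seed(99)
  tr <- combine_truth(
    draw_truth(spectrum_log_uniform(1e-3, 0.2), 6, c("A", "B"), seed = 14,
               gene = "GX", inheritance_mode = "x_linked"),
    draw_truth(spectrum_log_uniform(1e-3, 0.2), 6, c("A", "B"), seed = 15,
               gene = "GA", inheritance_mode = "autosomal"))
  tab <- sample_table(tr, list(population_spec("A", 400, 400),
                               population_spec("B", 50, 50)), seed = 16)
  est <- population_noncarrier_percent(tab, "A", distinctive_only = FALSE)
  freq <- vapply(tab$records, frequency, numeric(1), pop = "A")
  mode <- vapply(tab$records, `[[`, character(1), "inheritance_mode")
  expect_equal(est$p_xx, noncarrier_probability(freq, mode, "XX"))
  expect_equal(est$p_xy, noncarrier_probability(freq, mode, "XY"))
  expect_equal(est$percent, 100 * (est$p_xx + est$p_xy) / 2)
})

test_that("no-data variants are skipped and counted, never imputed", {
  tab <- frequency_table(list(
    variant_record("v1", "GA", "autosomal",
                   ac = c(A = 10, B = 0), an = c(A = 100, B = 50)),
    variant_record("v2", "GA", "autosomal",
                   ac = c(A = 0, B = 5), an = c(A = 0, B = 50))))
  # v2 has no A data, so it cannot be judged distinctive-or-not for A's
  # product either way; include everything to exercise the skip counter
  e <- population_noncarrier_percent(tab, "A", distinctive_only = FALSE)
  expect_equal(e$n_variants_used, 1L)
  expect_equal(e$n_variants_skipped_no_data, 1L)
  expect_equal(e$p_xx, 0.9^2)
})

test_that("ubiquitous variants are excluded by default, included on request", {
  tab <- frequency_table(list(
    variant_record("vu", "GA", "autosomal",          # present everywhere
                   ac = c(A = 30, B = 20), an = c(A = 100, B = 100)),
    variant_record("vd", "GA", "autosomal",          # distinctive
                   ac = c(A = 10, B = 0), an = c(A = 100, B = 100))))
  e1 <- population_noncarrier_percent(tab, "A")
  expect_equal(e1$n_variants_used, 1L)
  expect_equal(e1$p_xx, 0.9^2)
  e2 <- population_noncarrier_percent(tab, "A", distinctive_only = FALSE)
  expect_equal(e2$n_variants_used, 2L)
  expect_equal(e2$p_xx, 0.7^2 * 0.9^2)
})

test_that("percent is order-invariant, and p > 0 variants strictly lower it", {
  recs <- list(
    variant_record("v1", "GX", "x_linked",
                   ac = c(A = 5, B = 0), an = c(A = 100, B = 100)),
    variant_record("v2", "GA", "autosomal",
                   ac = c(A = 3, B = 0), an = c(A = 100, B = 100)),
    variant_record("v3", "GA", "autosomal",
                   ac = c(A = 0, B = 1), an = c(A = 100, B = 100)))
  t1 <- frequency_table(recs, populations = c("A", "B"))
  t2 <- frequency_table(rev(recs), populations = c("A", "B"))
  e1 <- population_noncarrier_percent(t1, "A")
  expect_equal(e1$percent, population_noncarrier_percent(t2, "A")$percent)
  # drop v2 (p = 0.03 in A): percent must strictly increase
  t3 <- frequency_table(recs[-2], populations = c("A", "B"))
  expect_gt(population_noncarrier_percent(t3, "A")$percent, e1$percent)
  # v3 has p = 0 in A: dropping it changes nothing
  t4 <- frequency_table(recs[-3], populations = c("A", "B"))
  expect_equal(population_noncarrier_percent(t4, "A")$percent, e1$percent)
})

test_that("all-autosomal sets give identical XX and XY probabilities", {
  set.seed(111)
  recs <- lapply(1:5, function(i)
    random_record(paste0("v", i), c("A", "B"), gene = "GA"))
  tab <- frequency_table(recs, populations = c("A", "B"))
  e <- population_noncarrier_percent(tab, "A", distinctive_only = FALSE)
  expect_equal(e$p_xx, e$p_xy)
})

test_that("carrier_free_table summarizes every population", {
  cf <- carrier_free_table(toy_table())
  expect_equal(cf$population, c("A", "B", "C"))
  expect_true(all(cf$percent >= 0 & cf$percent <= 100))
  expect_equal(cf$n_variants_skipped_no_data, c(0L, 1L, 0L))  # vA2 has no B data
})
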