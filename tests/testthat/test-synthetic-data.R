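test_that("spectrum constructors reject invalid bounds", {
  expect_error(spectrum_point_mass(0), "\\(0, 1\\]")
  expect_error(spectrum_point_mass(1.5), "\\(0, 1\\]")
  expect_error(spectrum_log_uniform(0, 0.1), "bounds")
  expect_error(spectrum_log_uniform(0.1, 0.01), "bounds")
  expect_error(spectrum_log_uniform(1e-3, 2), "bounds")
  expect_error(spectrum_constraint_skewed(1e-4, 1e-2, skew = -1), "skew")
})

test_that("point-mass truths put every variant at the stated frequency", {
  pops <- c("A", "B", "C")
  tr <- draw_truth(spectrum_point_mass(1e-5), 131, pops, shared = TRUE,
                   seed = 3)
  expect_equal(dim(tr$freq), c(131L, 3L))
  expect_true(all(tr$freq == 1e-5))
  empty <- draw_truth(spectrum_point_mass(0.5), 0, pops, seed = 3)
  expect_equal(nrow(empty$freq), 0L)
  expect_length(empty$variant_id, 0L)
})

test_that("log-uniform spectrum has the right mean on the log10 scale", {
  # log10(p) ~ Uniform(-6, -4): mean -5, variance 4/12
  tr <- draw_truth(spectrum_log_uniform(1e-6, 1e-4), 10000, "A", seed = 11)
  se <- sqrt((4 / 12) / 10000)
  expect_lt(abs(mean(log10(tr$freq)) - (-5)), 3 * se)
  expect_true(all(tr$freq >= 1e-6 & tr$freq <= 1e-4))
})

test_that("constraint-skewed spectrum shifts mass toward rare frequencies", {
  tr_sk <- draw_truth(spectrum_constraint_skewed(1e-6, 1e-3, skew = 1),
                      5000, "A", seed = 5)
  tr_lu <- draw_truth(spectrum_log_uniform(1e-6, 1e-3), 5000, "A", seed = 5)
  expect_lt(mean(log10(tr_sk$freq)), mean(log10(tr_lu$freq)))
  expect_true(all(tr_sk$freq >= 1e-6 & tr_sk$freq <= 1e-3))
})

test_that("shared truths copy one draw per variant across populations", {
  pops <- c("A", "B", "C", "D")
  tr <- draw_truth(spectrum_log_uniform(1e-5, 1e-2), 50, pops,
                   shared = TRUE, seed = 9)
  expect_true(all(apply(tr$freq, 1, function(z) length(unique(z)) == 1L)))
  tr2 <- draw_truth(spectrum_log_uniform(1e-5, 1e-2), 50, pops,
                    shared = FALSE, seed = 9)
  expect_false(all(apply(tr2$freq, 1, function(z) length(unique(z)) == 1L)))
})

test_that("sampling is deterministic given the seed and varies across seeds", {
  tr <- draw_truth(spectrum_log_uniform(1e-3, 1e-1), 20, c("A", "B"),
                   seed = 21)
  specs <- list(population_spec("A", 500, 500), population_spec("B", 50, 50))
  t1 <- sample_table(tr, specs, seed = 5)
  t2 <- sample_table(tr, specs, seed = 5)
  t3 <- sample_table(tr, specs, seed = 6)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_false(identical(as.data.frame(t1), as.data.frame(t3)))
})

test_that("degenerate truths sample degenerate tables", {
  pops <- c("A", "B")
  specs <- list(population_spec("A", 10, 10), population_spec("B", 4, 6))
  tr1 <- draw_truth(spectrum_point_mass(1), 5, pops, seed = 2)
  tab1 <- sample_table(tr1, specs, seed = 2)
  df1 <- as.data.frame(tab1)
  expect_true(all(df1$ac == df1$an))
  tr0 <- draw_truth(spectrum_point_mass(1e-5), 5, pops, seed = 2)
  tr0$freq[] <- 0
  tab0 <- sample_table(tr0, specs, seed = 2)
  expect_true(all(as.data.frame(tab0)$ac == 0))
})

test_that("allele numbers in sampled tables respect inheritance mode", {
  specs <- list(population_spec("A", 100, 100), population_spec("B", 30, 70))
  tr <- combine_truth(
    draw_truth(spectrum_point_mass(0.01), 3, c("A", "B"), seed = 1,
               gene = "GX", inheritance_mode = "x_linked"),
    draw_truth(spectrum_point_mass(0.01), 3, c("A", "B"), seed = 2,
               gene = "GA", inheritance_mode = "autosomal"))
  df <- as.data.frame(sample_table(tr, specs, seed = 3))
  expect_true(all(df$an[df$gene == "GA" & df$population == "A"] == 400))
  expect_true(all(df$an[df$gene == "GX" & df$population == "A"] == 300))
  expect_true(all(df$an[df$gene == "GA" & df$population == "B"] == 200))
  expect_true(all(df$an[df$gene == "GX" & df$population == "B"] == 130))
})

test_that("sampled frequencies are unbiased for the truth (binomial check)", {
  # 500 replicate tables of one variant at p = 0.01, an = 20000
  p <- 0.01
  tr <- draw_truth(spectrum_point_mass(p), 1, "A", seed = 4)
  spec <- list(population_spec("A", 5000, 5000))
  fr <- vapply(1:500, function(i) {
    df <- as.data.frame(sample_table(tr, spec, seed = 1000 + i))
    df$ac / df$an
  }, numeric(1))
  se <- sqrt(p * (1 - p) / 20000 / 500)
  expect_lt(abs(mean(fr) - p), 3 * se)
})

test_that("law of large numbers: ac/an approaches truth at an = 1e6", {
  p <- 0.01
  tr <- draw_truth(spectrum_point_mass(p), 1, "A", seed = 8)
  spec <- list(population_spec("A", 250000, 250000))
  df <- as.data.frame(sample_table(tr, spec, seed = 8))
  expect_equal(df$an, 1e6)
  expect_lt(abs(df$ac / df$an - p), 3 * sqrt(p * (1 - p) / 1e6))
})

test_that("sample_table rejects mismatched population labels", {
  tr <- draw_truth(spectrum_point_mass(0.1), 2, c("A", "B"), seed = 1)
  expect_error(sample_table(tr, list(population_spec("A", 5, 5)), seed = 1),
               "labels")
})

test_that("default fixtures have the documented shape", {
  specs <- default_population_specs()
  expect_length(specs, 9L)
  expect_equal(allele_number(specs$EUR, "autosomal"), 72000L)
  expect_equal(allele_number(specs$AFR, "autosomal"), 46000L)
  expect_equal(allele_number(specs$AMI, "autosomal"), 900L)
  tr <- default_truth(seed = 1)
  expect_length(tr$variant_id, 131L)
  expect_setequal(unique(tr$inheritance_mode), c("x_linked", "autosomal"))
  expect_true(all(tr$freq >= 1e-6 & tr$freq <= 1e-3))
})
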