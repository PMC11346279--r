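# Per-population shortlisted-variant tallies, per-gene effective sample
# sizes, and the origin-rooted regression of tally on sample size.

#' Is a variant notionally population-distinctive?
#'
#' A sampling-dependent label: the variant is present (AC >= 1) in at least
#' one population's sample and absent (AC = 0 with AN > 0) in at least one
#' other. Populations with no data (AN = 0) count toward neither side.
#'
#' @param record A [variant_record()].
#' @return Logical scalar.
#' @export
is_population_distinctive <- function(record) {
  stopifnot(inherits(record, "variant_record"),
            length(record$ac) >= 1L)
  status <- vapply(names(record$ac), function(p) presence_status(record, p),
                   character(1))
  any(status == "present") && any(status == "absent")
}

#' Tally shortlisted variants present per population
#'
#' For one gene, counts the shortlisted variants with presence status
#' `"present"` in each population, and reports the population's effective
#' sample size for that gene: the maximum AN over the gene's shortlisted
#' records (tallied after exclusions). Exclusion lists let record-keeping
#' corrections (variants to drop from a published shortlist) be expressed
#' as configuration rather than edits to the data.
#'
#' @param table A [frequency_table()].
#' @param gene Gene label occurring in the table.
#' @param exclude Character vector of variant ids to leave out.
#' @return An object of class `tally_result`: list with `gene` and a
#'   data.frame `per_population` (columns `population`, `tally`,
#'   `sample_size`).
#' @export
tally_per_population <- function(table, gene, exclude = character()) {
  stopifnot(inherits(table, "frequency_table"))
  genes <- vapply(table$records, `[[`, character(1), "gene")
  if (!gene %in% genes)
    stop("gene not in table: ", gene, call. = FALSE)
  ids <- vapply(table$records, `[[`, character(1), "variant_id")
  keep <- genes == gene &
    vapply(table$records, `[[`, logical(1), "shortlisted") &
    !(ids %in% exclude)
  recs <- table$records[keep]
  tally <- integer(length(table$populations))
  size <- integer(length(table$populations))
  for (j in seq_along(table$populations)) {
    pop <- table$populations[[j]]
    if (length(recs)) {
      status <- vapply(recs, function(r) presence_status(r, pop), character(1))
      tally[j] <- sum(status == "present")
      size[j] <- max(vapply(recs, function(r) r$an[[pop]], numeric(1)))
    }
  }
  structure(list(gene = gene,
                 per_population = data.frame(
                   population = table$populations,
                   tally = tally, sample_size = size)),
            class = "tally_result")
}

#' @export
print.tally_result <- function(x, ...) {
  cat(sprintf("tally_result for gene %s\n", x$gene))
  print(x$per_population)
  invisible(x)
}

#' Through-origin least-squares fit with uncentered r-squared
#'
#' Fits `y = slope * x` by least squares: `slope = sum(x*y) / sum(x^2)`.
#' Fit quality is the uncentered coefficient of determination
#' `r2 = (sum(x*y))^2 / (sum(x^2) * sum(y^2))`, the squared cosine between
#' the x and y vectors; the centered r-squared is ill-defined for a
#' forced-origin fit. When all y are zero the slope is 0 and r2 is
#' undefined (`NA` with a warning), not 1: a flat line through noise-free
#' zeros says nothing about proportionality.
#'
#' @param x Numeric vector (sample sizes); at least one nonzero.
#' @param y Numeric vector (tallies), same length.
#' @return An object of class `regression_fit`: list with `slope`,
#'   `r2_origin`, `n_points`.
#' @examples
#' origin_rooted_fit(c(1, 2, 3), c(1, 2, 4))  # slope 17/14, r2 289/294
#' @export
origin_rooted_fit <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 1L)
  if (all(x == 0))
    stop("through-origin fit needs at least one point with x != 0",
         call. = FALSE)
  sxy <- sum(x * y)
  sxx <- sum(x * x)
  syy <- sum(y * y)
  slope <- sxy / sxx
  if (syy == 0) {
    warning("all y values are zero: r2_origin is undefined", call. = FALSE)
    r2 <- NA_real_
  } else {
    r2 <- sxy^2 / (sxx * syy)
  }
  structure(list(slope = slope, r2_origin = r2, n_points = length(x)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("origin-rooted fit: slope = %.6g, r2 = %.4f (n = %d)\n",
              x$slope, x$r2_origin, x$n_points))
  invisible(x)
}

#' Fit a tally result's tallies against its sample sizes
#'
#' Convenience composition of [tally_per_population()] output and
#' [origin_rooted_fit()]. Populations with sample size 0 carry no
#' information about a per-allele discovery rate and are dropped with a
#' warning.
#'
#' @param tally A `tally_result`.
#' @return A `regression_fit`.
#' @export
fit_tally <- function(tally) {
  stopifnot(inherits(tally, "tally_result"))
  pp <- tally$per_population
  drop <- pp$sample_size == 0
  if (any(drop)) {
    warning("dropping population(s) with sample_size 0 from regression: ",
            paste(pp$population[drop], collapse = ", "), call. = FALSE)
    pp <- pp[!drop, , drop = FALSE]
  }
  origin_rooted_fit(pp$sample_size, pp$tally)
}
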