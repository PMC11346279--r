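# Binomial absence-confidence calculator: how many sampled alleles are
# needed before a variant's absence from a sample argues it is truly
# rarer than an assumed frequency.

#' Probability of detecting a variant in n sampled alleles
#'
#' Under binomial sampling at true allele frequency `p`, the probability
#' that at least one of `n` sampled gene copies carries the variant:
#' `1 - (1 - p)^n`. Computed as `-expm1(n * log1p(-p))` for accuracy at
#' small `p`.
#'
#' @param p True allele frequency (or vector), in \[0, 1\].
#' @param n Number of sampled alleles (or vector), non-negative integer.
#' @return Detection probability, vectorized over `p` and `n`.
#' @examples
#' detection_probability(0.5, 2)  # 0.75
#' @export
detection_probability <- function(p, n) {
  if (any(p < 0 | p > 1)) stop("`p` must lie in [0, 1]", call. = FALSE)
  if (any(n < 0)) stop("`n` must be non-negative", call. = FALSE)
  if (any(n != round(n))) stop("`n` must be integer-valued", call. = FALSE)
  out <- -expm1(n * log1p(-p))
  # p = 1, n = 0 gives 0 * -Inf = NaN; detection with zero draws is 0
  out[n == 0] <- 0
  out[p == 1 & n > 0] <- 1
  out
}

#' Smallest allele count giving a target detection confidence
#'
#' The least integer `n` with `detection_probability(p, n) >= conf`:
#' how many gene copies must be sampled so that, were the variant truly at
#' frequency `p`, it would be seen at least once with probability `conf` —
#' equivalently, so continued absence leaves at most `1 - conf` probability
#' under that frequency. The closed-form candidate
#' `ceiling(log(1 - conf) / log(1 - p))` is bracketed and verified by
#' direct evaluation at `n` and `n - 1`, so exact-threshold cases (e.g.
#' `p = 0.5, conf = 0.75 -> 2`) are not lost to floating-point ceilings.
#'
#' @param p Assumed true allele frequency in (0, 1\].
#' @param conf Target detection probability in \[0, 1).
#' @return Integer-valued numeric allele count.
#' @examples
#' min_alleles_for_confidence(1e-4, 0.9)  # 23025
#' @export
min_alleles_for_confidence <- function(p, conf) {
  if (length(p) != 1L || !is.numeric(p) || p <= 0 || p > 1)
    stop("`p` must be a single frequency in (0, 1]: no finite sample ",
         "can bound a variant of frequency 0", call. = FALSE)
  if (length(conf) != 1L || !is.numeric(conf) || conf < 0 || conf >= 1)
    stop("`conf` must lie in [0, 1)", call. = FALSE)
  if (conf == 0) return(0)
  if (p == 1) return(1)
  candidate <- ceiling(log1p(-conf) / log1p(-p))
  for (n in seq(max(0, candidate - 2), candidate + 2)) {
    if (detection_probability(p, n) >= conf) {
      if (n > 0 && detection_probability(p, n - 1) >= conf)
        next  # not minimal; keep searching downward-safe bracket
      return(n)
    }
  }
  stop("internal error: bracket around closed-form candidate failed")
}

#' Convert an allele count to a person count
#'
#' People are the natural unit of recruitment, alleles the unit of the
#' binomial model. Each person contributes 2 copies of an autosomal gene;
#' for an X-linked gene, 2 copies if XX and 1 if XY, so a population with
#' XX fraction `xx_fraction` contributes `1 + xx_fraction` copies per
#' person on average.
#'
#' @param n_alleles Allele count (numeric).
#' @param inheritance_mode `"autosomal"` or `"x_linked"`.
#' @param xx_fraction Fraction of XX individuals, default 0.5.
#' @return Number of people, rounded up.
#' @export
alleles_to_people <- function(n_alleles, inheritance_mode = "autosomal",
                              xx_fraction = 0.5) {
  inheritance_mode <- match.arg(inheritance_mode, c("autosomal", "x_linked"))
  stopifnot(n_alleles >= 0, xx_fraction >= 0, xx_fraction <= 1)
  per_person <- if (inheritance_mode == "autosomal") 2 else 1 + xx_fraction
  ceiling(n_alleles / per_person)
}
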