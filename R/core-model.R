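# Core domain types: variant records, frequency tables, population specs.
# All downstream stages (tallies, carrier-free estimates, simulations) work
# on these containers; file I/O lives in io-tsv.R / io-vcf.R.

#' Construct a per-variant allele count record
#'
#' A `variant_record` holds, for one variant, the sampled allele count (AC)
#' and allele number (AN) in each population, together with the gene label,
#' the gene's inheritance mode, and an externally supplied shortlist flag.
#' AC/AN is the sampled allele frequency; AN = 0 means the site was not
#' genotyped in that population and is treated as "no data", never as
#' absence.
#'
#' @param variant_id Unique variant identifier (string).
#' @param gene Gene label (string).
#' @param inheritance_mode `"autosomal"` or `"x_linked"`. Constant per gene.
#' @param ac Named non-negative integer vector of allele counts, one entry
#'   per population.
#' @param an Named non-negative integer vector of allele numbers with the
#'   same names as `ac`.
#' @param shortlisted Logical flag: is this variant a member of the analyzed
#'   shortlist? Shortlist membership is an input, not recomputed.
#' @return An object of class `variant_record`.
#' @examples
#' variant_record("v1", "GENE_A", "autosomal",
#'                ac = c(AFR = 3, EAS = 0), an = c(AFR = 1000, EAS = 500))
#' @export
variant_record <- function(variant_id, gene, inheritance_mode,
                           ac, an, shortlisted = TRUE) {
  stopifnot(is.character(variant_id), length(variant_id) == 1L,
            is.character(gene), length(gene) == 1L,
            is.logical(shortlisted), length(shortlisted) == 1L)
  inheritance_mode <- match.arg(inheritance_mode, c("autosomal", "x_linked"))
  if (is.null(names(ac)) || is.null(names(an)))
    stop("`ac` and `an` must be named by population label", call. = FALSE)
  if (!identical(sort(names(ac)), sort(names(an))))
    stop("`ac` and `an` must cover the same population labels", call. = FALSE)
  an <- an[names(ac)]
  structure(
    list(variant_id = variant_id, gene = gene,
         inheritance_mode = inheritance_mode,
         ac = stats::setNames(as.numeric(ac), names(ac)),
         an = stats::setNames(as.numeric(an), names(an)),
         shortlisted = shortlisted),
    class = "variant_record")
}

#' Construct a frequency table from variant records
#'
#' The central container: an ordered set of population labels plus a list of
#' [variant_record()]s, each carrying AC/AN for exactly those populations.
#' Structural problems are reported by [validate_table()]; by default the
#' constructor refuses invalid input.
#'
#' @param records List of [variant_record()] objects.
#' @param populations Ordered character vector of population labels. Default:
#'   the populations of the first record.
#' @param validate If `TRUE` (default), error on any invariant violation.
#' @return An object of class `frequency_table`.
#' @export
frequency_table <- function(records, populations = NULL, validate = TRUE) {
  if (length(records) && !all(vapply(records, inherits, logical(1), "variant_record")))
    stop("all elements of `records` must be variant_record objects", call. = FALSE)
  if (is.null(populations)) {
    populations <- if (length(records)) names(records[[1]]$ac) else character()
  }
  tab <- structure(list(populations = as.character(populations),
                        records = records),
                   class = "frequency_table")
  if (validate) {
    v <- validate_table(tab)
    if (nrow(v) > 0L)
      stop("invalid frequency table:\n",
           paste(utils::capture.output(print(v)), collapse = "\n"),
           call. = FALSE)
  }
  tab
}

#' @export
print.frequency_table <- function(x, ...) {
  cat(sprintf("frequency_table: %d variants x %d populations\n",
              length(x$records), length(x$populations)))
  cat("populations:", paste(x$populations, collapse = ", "), "\n")
  genes <- unique(vapply(x$records, `[[`, character(1), "gene"))
  if (length(genes)) cat("genes:", paste(genes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.frequency_table <- function(x) length(x$records)

#' Look up a variant record by id
#'
#' @param table A [frequency_table()].
#' @param variant_id Variant identifier.
#' @return The matching [variant_record()].
#' @export
ft_record <- function(table, variant_id) {
  ids <- vapply(table$records, `[[`, character(1), "variant_id")
  i <- match(variant_id, ids)
  if (is.na(i)) stop("unknown variant id: ", variant_id, call. = FALSE)
  table$records[[i]]
}

#' Convert a frequency table to a long-format data frame
#'
#' One row per variant x population, the canonical interchange layout.
#'
#' @param x A [frequency_table()].
#' @param row.names,optional Unused, for S3 compatibility.
#' @param ... Unused.
#' @return A data.frame with columns `variant_id`, `gene`,
#'   `inheritance_mode`, `population`, `ac`, `an`, `shortlisted`.
#' @export
as.data.frame.frequency_table <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  if (!length(x$records))
    return(data.frame(variant_id = character(), gene = character(),
                      inheritance_mode = character(), population = character(),
                      ac = numeric(), an = numeric(), shortlisted = logical()))
  pieces <- lapply(x$records, function(r) {
    data.frame(variant_id = r$variant_id, gene = r$gene,
               inheritance_mode = r$inheritance_mode,
               population = x$populations,
               ac = unname(r$ac[x$populations]),
               an = unname(r$an[x$populations]),
               shortlisted = r$shortlisted)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Sampled allele frequency of a variant in one population
#'
#' Returns AC/AN when AN > 0. When AN = 0 the frequency is undefined (no
#' gene copies were genotyped) and `NA_real_` is returned: absence of data
#' is not a frequency of zero.
#'
#' @param record A [variant_record()].
#' @param pop Population label present in the record.
#' @return Numeric in \[0, 1\], or `NA_real_` when AN = 0.
#' @export
frequency <- function(record, pop) {
  stopifnot(inherits(record, "variant_record"))
  if (!pop %in% names(record$ac))
    stop("unknown population label: ", pop, call. = FALSE)
  an <- record$an[[pop]]
  if (an == 0) return(NA_real_)
  record$ac[[pop]] / an
}

#' Presence status of a variant in one population
#'
#' `"present"` iff AC >= 1; `"absent"` iff AC = 0 with AN > 0 (the site was
#' genotyped and the allele was not seen); `"no_data"` iff AN = 0.
#'
#' @inheritParams frequency
#' @return One of `"present"`, `"absent"`, `"no_data"`.
#' @export
presence_status <- function(record, pop) {
  stopifnot(inherits(record, "variant_record"))
  if (!pop %in% names(record$ac))
    stop("unknown population label: ", pop, call. = FALSE)
  ac <- record$ac[[pop]]
  an <- record$an[[pop]]
  if (an == 0) "no_data" else if (ac >= 1) "present" else "absent"
}

#' Validate a frequency table
#'
#' Checks every type invariant and reports violations as data, not errors:
#' AC and AN non-negative, AC <= AN, every record keyed by exactly the
#' table's population labels, unique variant ids, and a single inheritance
#' mode per gene.
#'
#' @param table A `frequency_table` (or a structurally similar list).
#' @return A data.frame with columns `variant_id`, `population`, `rule`;
#'   zero rows iff the table is valid.
#' @export
validate_table <- function(table) {
  viol <- function(id, pop, rule)
    data.frame(variant_id = id, population = pop, rule = rule)
  out <- list()
  ids <- vapply(table$records, `[[`, character(1), "variant_id")
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) out[[length(out) + 1L]] <-
    viol(d, NA_character_, "variant_id must be unique within the table")
  gene_modes <- list()
  for (r in table$records) {
    if (!setequal(names(r$ac), table$populations) ||
        !setequal(names(r$an), table$populations)) {
      out[[length(out) + 1L]] <- viol(
        r$variant_id, NA_character_,
        "counts must be keyed by exactly the table's population labels")
      next
    }
    for (pop in table$populations) {
      ac <- r$ac[[pop]]; an <- r$an[[pop]]
      if (is.na(ac) || is.na(an) || ac < 0 || an < 0)
        out[[length(out) + 1L]] <-
          viol(r$variant_id, pop, "ac and an must be non-negative")
      else if (ac > an)
        out[[length(out) + 1L]] <- viol(r$variant_id, pop, "ac must be <= an")
    }
    prev <- gene_modes[[r$gene]]
    if (is.null(prev)) gene_modes[[r$gene]] <- r$inheritance_mode
    else if (!identical(prev, r$inheritance_mode))
      out[[length(out) + 1L]] <- viol(
        r$variant_id, NA_character_,
        "inheritance_mode must be constant per gene")
  }
  if (!length(out))
    return(data.frame(variant_id = character(), population = character(),
                      rule = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Describe a population's karyotype composition
#'
#' Sample sizes are stated in people; allele numbers depend on karyotype:
#' every individual carries two copies of an autosomal gene, while only XX
#' individuals carry two copies of an X-linked gene (XY individuals are
#' hemizygous, one copy).
#'
#' @param label Population label.
#' @param n_xx Number of XX individuals (non-negative integer).
#' @param n_xy Number of XY individuals (non-negative integer).
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(label, n_xx, n_xy) {
  stopifnot(length(n_xx) == 1L, length(n_xy) == 1L,
            n_xx >= 0, n_xy >= 0,
            n_xx == round(n_xx), n_xy == round(n_xy))
  structure(list(label = as.character(label),
                 n_xx = as.integer(n_xx), n_xy = as.integer(n_xy)),
            class = "population_spec")
}

#' Allele number implied by a population spec and inheritance mode
#'
#' Autosomal: `2 * (n_xx + n_xy)`. X-linked: `2 * n_xx + n_xy`.
#'
#' @param spec A [population_spec()].
#' @param inheritance_mode `"autosomal"` or `"x_linked"`.
#' @return Integer allele number.
#' @export
allele_number <- function(spec, inheritance_mode) {
  stopifnot(inherits(spec, "population_spec"))
  inheritance_mode <- match.arg(inheritance_mode, c("autosomal", "x_linked"))
  if (inheritance_mode == "autosomal") 2L * (spec$n_xx + spec$n_xy)
  else 2L * spec$n_xx + spec$n_xy
}
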