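# Canonical long-format TSV interchange: one row per variant x population,
# tab-delimited, UTF-8, header required.

#' Describe the column names of a long-format allele-count TSV
#'
#' @param variant_id,gene,inheritance_mode,population,ac,an,shortlisted
#'   Column names for each field. `shortlisted` is optional in input files
#'   (defaults to TRUE when the column is missing).
#' @return An object of class `table_dialect`.
#' @export
table_dialect <- function(variant_id = "variant_id", gene = "gene",
                          inheritance_mode = "inheritance_mode",
                          population = "population",
                          ac = "ac", an = "an",
                          shortlisted = "shortlisted") {
  structure(list(variant_id = variant_id, gene = gene,
                 inheritance_mode = inheritance_mode,
                 population = population, ac = ac, an = an,
                 shortlisted = shortlisted),
            class = "table_dialect")
}

#' Write a frequency table as long-format TSV
#'
#' @param table A [frequency_table()].
#' @param path Output file path.
#' @param dialect A [table_dialect()].
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(table, path, dialect = table_dialect()) {
  stopifnot(inherits(table, "frequency_table"),
            inherits(dialect, "table_dialect"))
  df <- as.data.frame(table)
  names(df) <- unlist(dialect[c("variant_id", "gene", "inheritance_mode",
                                "population", "ac", "an", "shortlisted")])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a long-format allele-count TSV into a frequency table
#'
#' Parses and validates in one pass. Structural errors (missing columns,
#' non-integer AC/AN, duplicate variant x population rows) are reported
#' with the offending file line number. Invariant violations found by
#' [validate_table()] abort unless `lenient = TRUE`, in which case they
#' are logged to standard error and the table is returned as-is.
#'
#' @param path Input file path.
#' @param dialect A [table_dialect()].
#' @param lenient Log invariant violations instead of failing?
#' @return A [frequency_table()].
#' @export
read_table_tsv <- function(path, dialect = table_dialect(),
                           lenient = FALSE) {
  stopifnot(inherits(dialect, "table_dialect"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          fileEncoding = "UTF-8")
  required <- unlist(dialect[c("variant_id", "gene", "inheritance_mode",
                               "population", "ac", "an")])
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  line_of <- function(row) row + 1L  # header occupies line 1
  parse_count <- function(col, what) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) | x != floor(x) | x < 0)
    if (length(bad))
      stop(sprintf("non-integer or negative %s on line %s", what,
                   paste(line_of(bad), collapse = ", ")), call. = FALSE)
    x
  }
  ac <- parse_count(dialect$ac, "ac")
  an <- parse_count(dialect$an, "an")
  bad <- which(ac > an)
  if (length(bad))
    stop("ac > an on line ", paste(line_of(bad), collapse = ", "),
         call. = FALSE)
  vid <- df[[dialect$variant_id]]
  pop <- df[[dialect$population]]
  dup <- which(duplicated(paste(vid, pop, sep = "\r")))
  if (length(dup))
    stop("duplicate (variant, population) row on line ",
         paste(line_of(dup), collapse = ", "), call. = FALSE)
  shortlisted <- if (dialect$shortlisted %in% names(df))
    as.logical(df[[dialect$shortlisted]]) else rep(TRUE, nrow(df))
  populations <- unique(pop)
  records <- lapply(unique(vid), function(v) {
    rows <- which(vid == v)
    variant_record(
      v,
      gene = df[[dialect$gene]][rows[1]],
      inheritance_mode = df[[dialect$inheritance_mode]][rows[1]],
      ac = stats::setNames(ac[rows], pop[rows]),
      an = stats::setNames(an[rows], pop[rows]),
      shortlisted = isTRUE(shortlisted[rows[1]]))
  })
  tab <- frequency_table(records, populations = populations,
                         validate = FALSE)
  v <- validate_table(tab)
  if (nrow(v) > 0L) {
    if (!lenient)
      stop("invalid table in ", path, ":\n",
           paste(utils::capture.output(print(v)), collapse = "\n"),
           call. = FALSE)
    log_msg("read_table_tsv: %d invariant violation(s) in %s (lenient mode)",
            nrow(v), path)
  }
  tab
}

# All diagnostics go to standard error; results never do.
log_msg <- function(fmt, ...) {
  message(sprintf(paste0("[lopsided] ", fmt), ...))
}
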