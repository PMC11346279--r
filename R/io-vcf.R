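# Convenience reader for per-population allele counts carried in VCF INFO
# fields keyed by population suffix (the gnomAD dialect: AC_afr / AN_afr,
# ...). One dialect, not a general VCF toolkit.

#' Read per-population AC/AN INFO fields from a VCF
#'
#' Builds one [variant_record()] per VCF record from INFO keys
#' `<ac_prefix><pop>` / `<an_prefix><pop>` for each requested population.
#' Inheritance mode is inferred from the contig name through
#' `contig_mode_map` (e.g. `c(chrX = "x_linked")`), falling back to
#' `default_mode` — an unmapped contig with no default is an error.
#' Records missing a requested key are skipped with a warning and
#' summarized. Multi-allelic records must be pre-split (e.g. with
#' `bcftools norm -m-`) and are rejected otherwise.
#'
#' Requires the VariantAnnotation package.
#'
#' @param path VCF file path (plain or bgzipped).
#' @param populations Character vector of population suffixes as spelled
#'   in the INFO keys (e.g. `c("afr", "eas")`).
#' @param contig_mode_map Named character vector mapping contig names to
#'   `"autosomal"` / `"x_linked"`.
#' @param default_mode Mode for unmapped contigs; `NULL` (default) makes
#'   unmapped contigs an error.
#' @param ac_prefix,an_prefix INFO key prefixes, default `"AC_"` / `"AN_"`.
#' @param gene_map Optional named character vector mapping contig names to
#'   gene labels; unmapped contigs use the contig name as the gene.
#' @param label_map Optional named character vector renaming population
#'   suffixes to output labels (e.g. `c(afr = "AFR")`).
#' @return A [frequency_table()].
#' @export
read_vcf_population_counts <- function(path, populations, contig_mode_map,
                                       default_mode = NULL,
                                       ac_prefix = "AC_",
                                       an_prefix = "AN_",
                                       gene_map = NULL,
                                       label_map = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf_population_counts requires the VariantAnnotation package",
         call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path)
  info <- VariantAnnotation::info(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  if (any(lengths(alt) > 1L))
    stop("multi-allelic record(s) found; split them first ",
         "(e.g. `bcftools norm -m-`)", call. = FALSE)
  out_labels <- if (is.null(label_map)) populations
                else ifelse(populations %in% names(label_map),
                            label_map[populations], populations)
  records <- list()
  skipped <- character()
  for (i in seq_len(nrow(info))) {
    contig <- as.character(GenomicRanges::seqnames(rr))[i]
    mode <- if (contig %in% names(contig_mode_map)) contig_mode_map[[contig]]
            else if (!is.null(default_mode)) default_mode
            else stop("contig not in contig_mode_map and no default_mode: ",
                      contig, call. = FALSE)
    vid <- rownames(info)[i]
    if (is.null(vid) || is.na(vid) || vid == ".")
      vid <- sprintf("%s:%d_%s/%s", contig,
                     GenomicRanges::start(rr)[i],
                     as.character(VariantAnnotation::ref(vcf)[i]),
                     as.character(unlist(alt[i])))
    ac <- numeric(length(populations))
    an <- numeric(length(populations))
    ok <- TRUE
    for (j in seq_along(populations)) {
      ack <- paste0(ac_prefix, populations[[j]])
      ank <- paste0(an_prefix, populations[[j]])
      if (!ack %in% names(info) || !ank %in% names(info)) {
        ok <- FALSE; break
      }
      a <- unlist(info[[ack]][i])[1]
      n <- unlist(info[[ank]][i])[1]
      if (is.null(a) || is.null(n) || is.na(a) || is.na(n)) {
        ok <- FALSE; break
      }
      ac[j] <- a; an[j] <- n
    }
    if (!ok) { skipped <- c(skipped, vid); next }
    gene <- if (!is.null(gene_map) && contig %in% names(gene_map))
      gene_map[[contig]] else contig
    records[[length(records) + 1L]] <- variant_record(
      vid, gene, mode,
      ac = stats::setNames(ac, out_labels),
      an = stats::setNames(an, out_labels))
  }
  if (length(skipped)) {
    warning(sprintf(
      "skipped %d record(s) lacking requested AC/AN INFO keys: %s",
      length(skipped),
      paste(utils::head(skipped, 5), collapse = ", ")), call. = FALSE)
  }
  frequency_table(records, populations = out_labels)
}
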