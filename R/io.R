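# Readers and writers for the package's plain-text interchange formats:
# taxa-as-rows TSV count tables with a `taxon_id` first column, and CSV
# sample metadata / taxonomy sidecars. Output files carry `#`-prefixed
# provenance comment lines which the readers skip.

#' Read a count table (TSV) with optional metadata and taxonomy
#'
#' @param path TSV file, first column `taxon_id`, one integer column per
#'   sample; `#`-prefixed lines are ignored.
#' @param meta_path Optional CSV with a `sample_id` column matching the
#'   table's sample columns; mismatches raise an error naming the
#'   offending samples.
#' @param taxonomy_path Optional CSV with a `taxon_id` column and taxonomy
#'   ranks.
#' @return A validated [count_table].
#' @export
read_count_table <- function(path, meta_path = NULL, taxonomy_path = NULL) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "taxon_id") {
    abort_param("first column of the count table must be `taxon_id`")
  }
  if (anyDuplicated(df$taxon_id)) abort_param("duplicate taxon ids")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || any(is.na(m)) ||
      any(abs(m - round(m)) > 1e-8) || any(m < 0)) {
    abort_param("count cells must be non-negative integers")
  }
  rownames(m) <- df$taxon_id
  meta <- if (!is.null(meta_path)) {
    utils::read.csv(meta_path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
  } else {
    NULL
  }
  tax <- if (!is.null(taxonomy_path)) {
    utils::read.csv(taxonomy_path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
  } else {
    NULL
  }
  count_table(m, sample_meta = meta, taxonomy = tax)
}

#' Write a count table (TSV) with metadata and taxonomy sidecars
#'
#' @param x A [count_table].
#' @param path Output TSV path.
#' @param meta_path,taxonomy_path Optional CSV paths for the sidecars.
#' @param provenance Extra provenance strings for the comment header.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path, meta_path = NULL,
                              taxonomy_path = NULL, provenance = NULL) {
  stopifnot(inherits(x, "count_table"))
  con <- file(path, "w")
  writeLines(provenance_header(provenance), con)
  df <- data.frame(taxon_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  if (!is.null(meta_path)) {
    write_with_provenance(x$sample_meta, meta_path, provenance)
  }
  if (!is.null(taxonomy_path) && !is.null(x$taxonomy)) {
    write_with_provenance(x$taxonomy, taxonomy_path, provenance)
  }
  invisible(path)
}
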