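#' Construct a taxon-by-sample read-count table
#'
#' The central container of the package: a non-negative integer matrix with
#' taxa as rows and samples as columns, optionally carrying per-sample
#' metadata (e.g. consumer species and season) and per-taxon taxonomy
#' (family/genus/species labels, any of which may be missing).
#'
#' @param counts Numeric matrix of non-negative integers, taxa in rows and
#'   samples in columns. Row and column names are used as taxon and sample
#'   ids; defaults are generated when absent.
#' @param sample_meta Optional data frame with a `sample_id` column matching
#'   the matrix columns; one row per sample.
#' @param taxonomy Optional data frame with a `taxon_id` column and any of
#'   `family`, `genus`, `species`; missing ranks are `NA`.
#' @return An object of class `count_table`: a list with elements `counts`,
#'   `sample_meta` and `taxonomy`.
#' @examples
#' m <- matrix(c(75L, 25L), nrow = 2, dimnames = list(c("t1", "t2"), "s1"))
#' count_table(m)
#' @export
count_table <- function(counts, sample_meta = NULL, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    abort_param("`counts` must be finite and non-negative")
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    abort_param("`counts` must be integers")
  }
  storage.mode(counts) <- "double"
  counts <- round(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("taxon_%03d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("sample_%02d", seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts))) abort_param("duplicate taxon ids")
  if (anyDuplicated(colnames(counts))) abort_param("duplicate sample ids")

  if (is.null(sample_meta)) {
    sample_meta <- tibble::tibble(sample_id = colnames(counts))
  } else {
    sample_meta <- tibble::as_tibble(sample_meta)
    if (!"sample_id" %in% names(sample_meta)) {
      abort_param("`sample_meta` needs a `sample_id` column")
    }
    missing <- setdiff(colnames(counts), sample_meta$sample_id)
    extra <- setdiff(sample_meta$sample_id, colnames(counts))
    if (length(missing) || length(extra)) {
      abort_param(sprintf(
        "sample ids disagree between counts and metadata%s%s",
        if (length(missing)) {
          paste0("; missing from metadata: ", toString(missing))
        } else "",
        if (length(extra)) {
          paste0("; absent from counts: ", toString(extra))
        } else ""
      ))
    }
    sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample_id), ]
  }
  if (!is.null(taxonomy)) {
    taxonomy <- tibble::as_tibble(taxonomy)
    if (!"taxon_id" %in% names(taxonomy)) {
      abort_param("`taxonomy` needs a `taxon_id` column")
    }
    taxonomy <- taxonomy[match(rownames(counts), taxonomy$taxon_id), ]
    taxonomy$taxon_id <- rownames(counts)
  }
  structure(
    list(counts = counts, sample_meta = sample_meta, taxonomy = taxonomy),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf(
    "<count_table> %d taxa x %d samples (%s reads)\n",
    nrow(x$counts), ncol(x$counts), format(sum(x$counts), big.mark = ",")
  ))
  meta_cols <- setdiff(names(x$sample_meta), "sample_id")
  if (length(meta_cols)) {
    cat("  sample metadata:", toString(meta_cols), "\n")
  }
  if (!is.null(x$taxonomy)) {
    ranks <- intersect(c("family", "genus", "species"), names(x$taxonomy))
    cat("  taxonomy ranks:", toString(ranks), "\n")
  }
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

as_count_matrix <- function(x) {
  if (inherits(x, "count_table")) x$counts else as.matrix(x)
}

#' Per-sample observed richness
#'
#' Number of taxa with at least one read in each sample.
#'
#' @param x A [count_table] or a counts matrix.
#' @return Named integer vector, one entry per sample.
#' @export
sample_richness <- function(x) {
  colSums(as_count_matrix(x) > 0)
}

# replace the counts matrix, keeping metadata rows/taxonomy aligned
replace_counts <- function(x, counts) {
  stopifnot(inherits(x, "count_table"))
  tax <- x$taxonomy
  if (!is.null(tax)) tax <- tax[match(rownames(counts), tax$taxon_id), ]
  meta <- x$sample_meta[match(colnames(counts), x$sample_meta$sample_id), ]
  count_table(counts, sample_meta = meta, taxonomy = tax)
}

# group label used across modules when samples are pooled / summarised
group_labels <- function(meta, group_by) {
  missing <- setdiff(group_by, names(meta))
  if (length(missing)) {
    abort_param(paste0(
      "unknown metadata key(s): ", toString(missing)
    ))
  }
  do.call(paste, c(lapply(group_by, function(k) meta[[k]]), sep = "_"))
}
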