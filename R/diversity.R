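# Hill numbers: a unified family of diversity indices in "effective number
# of taxa" units, D(q) = (sum p_i^q)^(1/(1-q)), with the order q tuning the
# weight of abundant versus rare taxa. q = 0 is richness, q = 1 the
# exponential of Shannon entropy (taken as the limit), q = 2 the inverse of
# Simpson concentration.

#' Hill number of a composition
#'
#' @param p Non-negative proportion vector; renormalized internally, zero
#'   entries are excluded from the power sum at every order (standard Hill
#'   convention).
#' @param q Order(s) of the diversity, each >= 0; vectorized.
#' @return Numeric vector of effective numbers of taxa, one per `q`.
#' @examples
#' hill_number(c(0.8, 0.2), q = c(0, 1, 2))
#' @export
hill_number <- function(p, q) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0)) {
    abort_param("`p` must be finite and non-negative")
  }
  if (sum(p) <= 0) abort_param("undefined diversity: all-zero composition")
  if (any(!is.finite(q)) || any(q < 0)) abort_param("`q` must be >= 0")
  p <- p[p > 0]
  p <- p / sum(p)
  vapply(q, function(qi) {
    if (qi == 0) {
      length(p)
    } else if (abs(qi - 1) < 1e-10) {
      exp(-sum(p * log(p)))
    } else {
      sum(p^qi)^(1 / (1 - qi))
    }
  }, numeric(1))
}

#' Diversity profiles D(q) over a grid of orders
#'
#' Evaluates Hill numbers on a grid of orders for every sample, or for
#' pooled groups of samples.
#'
#' @param x A [count_table] or counts matrix.
#' @param q_grid Orders at which to evaluate D(q); default 0 to 2 by 0.05.
#' @param pool_by Optional metadata keys; samples are combined within each
#'   group before computing proportions.
#' @param method How to combine samples when `pool_by` is given:
#'   `"pooled"` sums raw counts (default), `"mean_rra"` averages per-sample
#'   RRA vectors.
#' @return Tidy tibble with `unit_id` (sample or group label), `q`, `d`.
#'   All-zero units are skipped with a warning.
#' @examples
#' tab <- simulate_consumers(seed = 1, n_reads = 2000, n_taxa = 30)
#' dp <- diversity_profile(tab, q_grid = c(0, 1, 2))
#' @export
diversity_profile <- function(x, q_grid = seq(0, 2, by = 0.05),
                              pool_by = NULL,
                              method = c("pooled", "mean_rra")) {
  method <- match.arg(method)
  m <- as_count_matrix(x)
  if (!is.null(pool_by)) {
    meta <- if (inherits(x, "count_table")) x$sample_meta else
      abort_param("`pool_by` requires a count_table with metadata")
    labels <- group_labels(meta, pool_by)
    groups <- unique(labels)
    pooled <- vapply(groups, function(g) {
      sub <- m[, labels == g, drop = FALSE]
      if (method == "pooled") {
        rowSums(sub)
      } else {
        tot <- colSums(sub)
        if (all(tot == 0)) rowSums(sub) else
          rowMeans(sweep(sub[, tot > 0, drop = FALSE], 2, tot[tot > 0], "/"))
      }
    }, numeric(nrow(m)))
    m <- pooled
  }
  keep <- colSums(m) > 0
  if (any(!keep)) {
    warning("skipping empty unit(s): ", toString(colnames(m)[!keep]))
    m <- m[, keep, drop = FALSE]
  }
  out <- lapply(colnames(m), function(id) {
    tibble::tibble(unit_id = id, q = q_grid,
                   d = hill_number(m[, id], q_grid))
  })
  dplyr::bind_rows(out)
}

#' Group means and standard deviations of Hill numbers
#'
#' Summarises per-sample diversity profiles into per-group mean and SD of
#' D(q) at the requested orders, optionally on the natural-log scale (the
#' transform is applied per sample before averaging).
#'
#' @param profiles Per-sample tibble from [diversity_profile()] (one
#'   `unit_id` per sample).
#' @param meta Sample metadata with `sample_id` and the grouping columns.
#' @param group_by Metadata keys defining groups.
#' @param q Orders to summarise (must be present in `profiles`).
#' @param transform `"none"` or `"log"` (natural log).
#' @return Tibble with `group`, `q`, `mean`, `sd`, `n`; single-member
#'   groups get `sd = 0` and are flagged in `single_member`.
#' @export
group_summary <- function(profiles, meta, group_by, q = c(0, 1, 2),
                          transform = c("none", "log")) {
  transform <- match.arg(transform)
  stopifnot(all(c("unit_id", "q", "d") %in% names(profiles)))
  meta <- tibble::as_tibble(meta)
  labels <- tibble::tibble(
    unit_id = meta$sample_id,
    group = group_labels(meta, group_by)
  )
  df <- profiles |>
    dplyr::filter(vapply(.data$q, function(qi) {
      any(abs(qi - q) < 1e-9)
    }, logical(1))) |>
    dplyr::inner_join(labels, by = "unit_id")
  if (!nrow(df)) abort_param("no profile rows at the requested q values")
  df$value <- if (transform == "log") log(df$d) else df$d
  df |>
    dplyr::group_by(.data$group, .data$q) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
      n = dplyr::n(),
      single_member = dplyr::n() == 1,
      .groups = "drop"
    )
}

#' Compare DNA metabarcoding and microhistology diversity
#'
#' Pairs per-group Hill-number summaries from a DNA count table with values
#' from a group-level microhistology percent-composition table (composite
#' scans, one column per group). Microhistology columns are renormalized to
#' proportions before computing D(q).
#'
#' @param dna_table A [count_table] with sample metadata.
#' @param micro_table Matrix or data frame, categories x groups, percent
#'   values with each column summing to 100 within 2%. Column names must
#'   match the DNA group labels (`group_by` values joined by `_`).
#' @param q_set Orders to compare (default 0, 1, 2).
#' @param group_by Metadata keys that define the composites.
#' @param dna_pathway `"per_sample"` (default): mean and SD of per-sample
#'   Hill numbers, the usual way sample-level DNA data are reported;
#'   `"pooled"`: counts pooled per group before computing D(q), matching
#'   how the microhistology composites are built (like-for-like when
#'   assessing the effect of taxonomic lumping).
#' @return Tibble with `group`, `q`, `method` (`"dna"` /
#'   `"microhistology"`), `mean`, `sd`, `n`; for microhistology `sd` is `NA`
#'   and `n = 1` (a single composite per group).
#' @export
compare_methods <- function(dna_table, micro_table, q_set = c(0, 1, 2),
                            group_by = c("species", "season"),
                            dna_pathway = c("per_sample", "pooled")) {
  dna_pathway <- match.arg(dna_pathway)
  stopifnot(inherits(dna_table, "count_table"))
  micro <- as.matrix(micro_table)
  sums <- colSums(micro)
  if (any(abs(sums - 100) > 2)) {
    abort_param(paste0(
      "microhistology columns must sum to ~100%: off for ",
      toString(colnames(micro)[abs(sums - 100) > 2])
    ))
  }
  dna_groups <- unique(group_labels(dna_table$sample_meta, group_by))
  mism <- c(setdiff(dna_groups, colnames(micro)),
            setdiff(colnames(micro), dna_groups))
  if (length(mism)) {
    abort_param(paste0("unmatched group(s): ", toString(unique(mism))))
  }
  dna <- if (dna_pathway == "per_sample") {
    group_summary(
      diversity_profile(dna_table, q_grid = q_set),
      meta = dna_table$sample_meta, group_by = group_by, q = q_set
    ) |>
      dplyr::transmute(.data$group, .data$q, method = "dna",
                       .data$mean, .data$sd, .data$n)
  } else {
    labels <- group_labels(dna_table$sample_meta, group_by)
    diversity_profile(dna_table, q_grid = q_set, pool_by = group_by) |>
      dplyr::transmute(
        group = .data$unit_id, .data$q, method = "dna", mean = .data$d,
        sd = NA_real_,
        n = vapply(.data$unit_id, function(g) sum(labels == g), 0L)
      )
  }
  micro_rows <- lapply(dna_groups, function(g) {
    tibble::tibble(
      group = g, q = q_set, method = "microhistology",
      mean = hill_number(micro[, g] / 100, q_set),
      sd = NA_real_, n = 1L
    )
  })
  dplyr::bind_rows(dna, dplyr::bind_rows(micro_rows)) |>
    dplyr::arrange(.data$group, .data$q, .data$method)
}
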