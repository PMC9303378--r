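# Sample-wise relative read abundance (RRA) thresholding and the threshold
# sweep: richness loss, convergence, rank-order inversion, taxon dropout.

#' Convert counts to relative read abundance
#'
#' Each sample column is divided by its read total; all-zero samples stay
#' zero and trigger a warning.
#'
#' @param x A [count_table] or counts matrix.
#' @return Matrix of the same shape with columns summing to 1 (or 0).
#' @examples
#' to_rra(matrix(c(75, 25), nrow = 2))
#' @export
to_rra <- function(x) {
  m <- as_count_matrix(x)
  tot <- colSums(m)
  if (any(tot == 0)) {
    warning("all-zero sample(s): ", toString(colnames(m)[tot == 0]))
  }
  sweep(m, 2, pmax(tot, 1), "/")
}

#' Apply a sample-wise RRA threshold
#'
#' Within each sample independently, a taxon is retained iff its RRA
#' (computed on the *input* table) strictly exceeds `threshold`; counts of
#' retained taxa are unchanged (no renormalization), all others are zeroed.
#' At `threshold = 0` every taxon with at least one read is retained, so the
#' output equals the input. Thresholds are always meant to be applied to the
#' original table, never sequentially; because retained counts are
#' unchanged, re-application is idempotent and retained sets are nested
#' across thresholds either way.
#'
#' @param x A [count_table] or counts matrix.
#' @param threshold RRA cutoff as a fraction in \[0, 1\].
#' @return Object of the same class as `x` with sub-threshold counts zeroed.
#'   Counts are never renormalized; when RRA re-expressed among the retained
#'   taxa is wanted downstream, compose `to_rra(apply_threshold(x, t))`.
#' @examples
#' m <- matrix(c(90, 6, 4), ncol = 1)
#' apply_threshold(m, 0.05)
#' @export
apply_threshold <- function(x, threshold) {
  assert_fraction(threshold, "threshold")
  m <- as_count_matrix(x)
  tot <- colSums(m)
  rra <- sweep(m, 2, pmax(tot, 1), "/")
  keep <- rra > threshold
  m[!keep] <- 0
  if (inherits(x, "count_table")) replace_counts(x, m) else m
}

#' Sweep RRA thresholds and track richness loss
#'
#' Applies every threshold in `thresholds` to the original table and
#' records, per sample: observed richness, percent loss of the threshold-0
#' richness `100 * (1 - S_t / S_0)`, and the retained taxon sets.
#'
#' @param x A [count_table] or counts matrix.
#' @param thresholds Ascending grid of fractions; default 0 to 5% in 0.2%
#'   steps (26 points), matching common reporting of RRA filters.
#' @return A `sweep_result`: list with `thresholds`, a tidy `richness`
#'   tibble (`sample_id`, `threshold`, `richness`, `pct_loss`), a `retained`
#'   list (per threshold, per sample, retained taxon ids) and the sample
#'   metadata.
#' @examples
#' tab <- simulate_consumers(seed = 1, n_reads = 2000, n_taxa = 30)
#' sw <- threshold_sweep(tab)
#' head(sw$richness)
#' @export
threshold_sweep <- function(x, thresholds = seq(0, 0.05, by = 0.002)) {
  if (length(thresholds) < 1) abort_param("empty threshold grid")
  if (is.unsorted(thresholds)) abort_param("thresholds must be ascending")
  for (t in thresholds) assert_fraction(t, "thresholds")
  m <- as_count_matrix(x)
  tot <- colSums(m)
  rra <- sweep(m, 2, pmax(tot, 1), "/")
  s0 <- colSums(m > 0)

  rows <- list()
  retained <- list()
  for (t in thresholds) {
    keep <- rra > t
    st <- colSums(keep)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      sample_id = colnames(m),
      threshold = t,
      richness = as.integer(st),
      pct_loss = unname(ifelse(s0 > 0, 100 * (1 - st / s0), 0))
    )
    retained[[sprintf("%g", t)]] <- lapply(
      seq_len(ncol(m)),
      function(j) rownames(m)[keep[, j]]
    ) |> stats::setNames(colnames(m))
  }
  structure(
    list(
      thresholds = thresholds,
      richness = dplyr::bind_rows(rows),
      retained = retained,
      s0 = s0,
      sample_meta = if (inherits(x, "count_table")) x$sample_meta else
        tibble::tibble(sample_id = colnames(m))
    ),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf(
    "<sweep_result> %d samples x %d thresholds (%g to %g)\n",
    length(x$s0), length(x$thresholds),
    min(x$thresholds), max(x$thresholds)
  ))
  invisible(x)
}

#' Smallest threshold at which samples converge in richness
#'
#' Finds the smallest grid threshold where the spread (max - min) of
#' per-sample richness is at most `tolerance` taxa. With `tolerance = NULL`
#' (default) the minimal achievable spread on the grid is used and reported,
#' since "similar richness" has no canonical cutoff.
#'
#' @param sweep A [threshold_sweep()] result over >= 2 samples.
#' @param tolerance Maximum allowed richness spread in taxa, or `NULL`.
#' @return List with `threshold` (`NA` if never within tolerance),
#'   `tolerance` (the spread actually achieved there) and a `spread` tibble.
#' @export
convergence_threshold <- function(sweep, tolerance = NULL) {
  stopifnot(inherits(sweep, "sweep_result"))
  if (length(sweep$s0) < 2) abort_param("need >= 2 samples")
  spread <- sweep$richness |>
    dplyr::group_by(.data$threshold) |>
    dplyr::summarise(
      spread = max(.data$richness) - min(.data$richness),
      .groups = "drop"
    )
  if (is.null(tolerance)) tolerance <- min(spread$spread)
  hit <- spread$threshold[spread$spread <= tolerance]
  thr <- if (length(hit)) min(hit) else NA_real_
  list(
    threshold = thr,
    tolerance = if (is.na(thr)) NA_integer_ else
      spread$spread[spread$threshold == thr],
    spread = spread
  )
}

#' Sample richness rankings across thresholds, and rank inversions
#'
#' Ranks samples by richness at each threshold (ties share the minimum
#' rank) and lists every threshold at which a strict ordering between two
#' samples at threshold 0 is strictly reversed.
#'
#' @param sweep A [threshold_sweep()] result over >= 2 samples.
#' @return List with a `ranks` tibble (`sample_id`, `threshold`, `richness`,
#'   `rank`) and an `inversions` tibble (`threshold`, `sample_high`,
#'   `sample_low`) where `sample_high` was strictly richer at threshold 0
#'   but strictly poorer at `threshold`.
#' @export
rank_order_trajectory <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  if (length(sweep$s0) < 2) abort_param("need >= 2 samples")
  ranks <- sweep$richness |>
    dplyr::group_by(.data$threshold) |>
    dplyr::mutate(rank = rank(-.data$richness, ties.method = "min")) |>
    dplyr::ungroup()

  base <- sweep$s0
  ids <- names(base)
  pairs <- utils::combn(ids, 2, simplify = FALSE)
  inv <- list()
  rich_wide <- tidyr::pivot_wider(
    sweep$richness[, c("sample_id", "threshold", "richness")],
    names_from = "sample_id", values_from = "richness"
  )
  for (pr in pairs) {
    a <- pr[1]; b <- pr[2]
    if (base[a] == base[b]) next
    hi <- if (base[a] > base[b]) a else b
    lo <- if (base[a] > base[b]) b else a
    flipped <- rich_wide$threshold[rich_wide[[hi]] < rich_wide[[lo]]]
    if (length(flipped)) {
      inv[[length(inv) + 1L]] <- tibble::tibble(
        threshold = flipped, sample_high = hi, sample_low = lo
      )
    }
  }
  inversions <- if (length(inv)) {
    dplyr::arrange(dplyr::bind_rows(inv), .data$threshold)
  } else {
    tibble::tibble(threshold = numeric(), sample_high = character(),
                   sample_low = character())
  }
  list(ranks = ranks, inversions = inversions)
}

#' Ledger of taxa dropped from groups by thresholding
#'
#' A taxon is "present in a group" at threshold t when it is retained in at
#' least one of the group's samples. The ledger lists, per group and
#' threshold, the taxa present at threshold 0 but absent at t, aggregated at
#' the requested taxonomic rank (taxa without a label at that rank are
#' reported under `"unknown"`).
#'
#' @param x A [count_table] with sample metadata (and taxonomy, unless
#'   `taxon_level = "taxon_id"`).
#' @param thresholds Ascending grid of fractions (0 is added if absent).
#' @param group_by Character vector of metadata columns defining groups.
#' @param taxon_level One of `"taxon_id"`, `"family"`, `"genus"`,
#'   `"species"`.
#' @return Tibble with `group`, `threshold`, `rank_label`, `n_taxa_lost`
#'   and `taxa` (semicolon-collapsed taxon ids).
#' @export
dropout_ledger <- function(x, thresholds = seq(0, 0.05, by = 0.002),
                           group_by = "species", taxon_level = "family") {
  stopifnot(inherits(x, "count_table"))
  labels <- group_labels(x$sample_meta, group_by)
  if (taxon_level != "taxon_id") {
    if (is.null(x$taxonomy) || !taxon_level %in% names(x$taxonomy)) {
      abort_param(sprintf("taxonomy rank `%s` not available", taxon_level))
    }
    rank_of <- x$taxonomy[[taxon_level]]
    rank_of[is.na(rank_of) | rank_of == ""] <- "unknown"
  } else {
    rank_of <- rownames(x$counts)
  }
  names(rank_of) <- rownames(x$counts)

  thresholds <- sort(unique(c(0, thresholds)))
  m <- as_count_matrix(x)
  rra <- sweep(m, 2, pmax(colSums(m), 1), "/")
  out <- list()
  for (g in unique(labels)) {
    sub <- rra[, labels == g, drop = FALSE]
    present0 <- rownames(sub)[rowSums(sub > 0) > 0]
    for (t in setdiff(thresholds, 0)) {
      present_t <- rownames(sub)[rowSums(sub > t) > 0]
      lost <- setdiff(present0, present_t)
      if (!length(lost)) next
      by_rank <- split(lost, rank_of[lost])
      out[[length(out) + 1L]] <- tibble::tibble(
        group = g,
        threshold = t,
        rank_label = names(by_rank),
        n_taxa_lost = lengths(by_rank),
        taxa = vapply(by_rank, paste, "", collapse = ";")
      )
    }
  }
  if (!length(out)) {
    return(tibble::tibble(
      group = character(), threshold = numeric(), rank_label = character(),
      n_taxa_lost = integer(), taxa = character()
    ))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$group, .data$threshold,
                 dplyr::desc(.data$n_taxa_lost))
}
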