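# End-to-end workflows composing the modules: the theoretical simulation
# study (three consumers, threshold sweep, Hill profiles) and the
# wildlife-style analysis (rarefaction, sweep, group richness, population
# extrapolation, Hill and microhistology comparisons).

#' Run the theoretical simulation study
#'
#' Simulates the consumer panel, sweeps RRA thresholds, locates the
#' convergence threshold, tracks rank order, and profiles Hill diversity --
#' deterministic given `seed`.
#'
#' @param alphas,n_taxa,n_reads,strategy Passed to [simulate_consumers()].
#' @param thresholds Threshold grid for [threshold_sweep()].
#' @param q_grid Order grid for [diversity_profile()].
#' @param seed Master seed.
#' @param out_dir Optional directory; when given, writes `counts.tsv`,
#'   `meta.csv`, `richness.csv`, `rank_order.csv` and `hill.csv`, each with
#'   a provenance comment header.
#' @return List with `table`, `sweep`, `convergence`, `rank_order`,
#'   `hill`.
#' @examples
#' res <- run_simulation_study(seed = 1, n_taxa = 30, n_reads = 2000)
#' res$convergence$threshold
#' @export
run_simulation_study <- function(alphas = c(specialist = 0.20,
                                            intermediate = 0.35,
                                            generalist = 1.00),
                                 n_taxa = 100, n_reads = 25000,
                                 thresholds = seq(0, 0.05, by = 0.002),
                                 q_grid = seq(0, 2, by = 0.05),
                                 seed = 1, strategy = "calibrated",
                                 out_dir = NULL) {
  tab <- simulate_consumers(alphas = alphas, n_taxa = n_taxa,
                            n_reads = n_reads, seed = seed,
                            strategy = strategy)
  sweep <- threshold_sweep(tab, thresholds)
  multi <- ncol(tab$counts) >= 2
  conv <- if (multi) convergence_threshold(sweep) else NULL
  ranks <- if (multi) rank_order_trajectory(sweep) else NULL
  hill <- diversity_profile(tab, q_grid = q_grid)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    prov <- sprintf("run_simulation_study seed=%d strategy=%s", seed,
                    strategy)
    write_count_table(tab, file.path(out_dir, "counts.tsv"),
                      meta_path = file.path(out_dir, "meta.csv"),
                      provenance = prov)
    write_with_provenance(sweep$richness,
                          file.path(out_dir, "richness.csv"), prov)
    if (!is.null(ranks)) {
      write_with_provenance(ranks$ranks,
                            file.path(out_dir, "rank_order.csv"), prov)
    }
    write_with_provenance(hill, file.path(out_dir, "hill.csv"), prov)
  }
  list(table = tab, sweep = sweep, convergence = conv, rank_order = ranks,
       hill = hill)
}

#' Run the wildlife-style analysis
#'
#' Composes the field-data workflow on a provided count table or on a
#' freshly generated synthetic wildlife data set: rarefy samples to equal
#' depth, sweep RRA thresholds, summarise mean richness per group,
#' extrapolate population-level richness per threshold, profile Hill
#' diversity per group, and (when a microhistology table is available)
#' compare the two methods.
#'
#' @param table A [count_table], or `NULL` to generate one from `config`.
#' @param config [fixture_config()] used when `table` is `NULL`.
#' @param micro Optional microhistology percent table; with the default
#'   `"auto"`, one is generated alongside a synthetic `table` and skipped
#'   (with a notice) for user-provided tables.
#' @param thresholds Threshold grid.
#' @param q_grid Hill order grid.
#' @param group_by Metadata keys defining groups.
#' @param rarefy Rarefy to the minimum sample depth first (default `TRUE`).
#' @param seed Master seed.
#' @param out_dir Optional output directory for tidy CSVs with provenance
#'   headers.
#' @return List with `table` (post-rarefaction), `sweep`,
#'   `group_richness`, `population`, `population_ci`, `hill_by_group`,
#'   `method_comparison` (`NULL` when no micro table).
#' @export
run_wildlife_study <- function(table = NULL, config = fixture_config(),
                               micro = "auto",
                               thresholds = seq(0, 0.05, by = 0.002),
                               q_grid = seq(0, 2, by = 0.05),
                               group_by = c("species", "season"),
                               rarefy = TRUE, seed = 1, out_dir = NULL) {
  seeds <- split_seed(seed, 3)
  if (is.null(table)) {
    table <- generate_wildlife_dataset(config, seed = seeds[1])
    if (identical(micro, "auto")) {
      micro <- generate_microhistology(table)
    }
  } else if (identical(micro, "auto")) {
    message("no microhistology table supplied; comparison step skipped")
    micro <- NULL
  }
  if (rarefy) table <- rarefy_table(table, seed = seeds[2])
  sweep <- threshold_sweep(table, thresholds)
  group_richness <- sweep$richness |>
    dplyr::inner_join(table$sample_meta, by = "sample_id") |>
    dplyr::mutate(group = group_labels(
      dplyr::pick(dplyr::everything()), group_by
    )) |>
    dplyr::group_by(.data$group, .data$threshold) |>
    dplyr::summarise(
      mean_richness = mean(.data$richness),
      sd_richness = stats::sd(.data$richness),
      n = dplyr::n(), .groups = "drop"
    )
  population <- sweep_population_richness(table, thresholds, group_by)
  population_ci <- bootstrap_ci(table, group_by, seed = seeds[3])
  hill_by_group <- diversity_profile(table, q_grid = q_grid,
                                     pool_by = group_by)
  method_comparison <- if (!is.null(micro)) {
    compare_methods(table, micro, group_by = group_by)
  } else {
    NULL
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    prov <- sprintf("run_wildlife_study seed=%d", seed)
    write_count_table(table, file.path(out_dir, "counts.tsv"),
                      meta_path = file.path(out_dir, "meta.csv"),
                      taxonomy_path = file.path(out_dir, "taxonomy.csv"),
                      provenance = prov)
    write_with_provenance(sweep$richness,
                          file.path(out_dir, "richness.csv"), prov)
    write_with_provenance(group_richness,
                          file.path(out_dir, "group_richness.csv"), prov)
    write_with_provenance(population,
                          file.path(out_dir, "population_richness.csv"),
                          prov)
    write_with_provenance(hill_by_group,
                          file.path(out_dir, "hill_by_group.csv"), prov)
    if (!is.null(method_comparison)) {
      write_with_provenance(method_comparison,
                            file.path(out_dir, "method_comparison.csv"),
                            prov)
    }
  }
  list(table = table, sweep = sweep, group_richness = group_richness,
       population = population, population_ci = population_ci,
       hill_by_group = hill_by_group,
       method_comparison = method_comparison)
}
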