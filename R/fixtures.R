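# Synthetic wildlife data: emulates the statistical structure of a
# two-species (bighorn-like / bison-like), two-season herbivore fecal
# metabarcoding study -- 35 samples, a 355-taxon plant pool with partial
# taxonomic annotation, skewed per-sample rank-abundance distributions,
# summer-richer-than-winter and bison-richer-than-bighorn effects -- plus a
# companion microhistology-style composite table sharing the same true
# diets. The generator defines study conditions for testing the pipeline;
# it makes no claim of fidelity to any real data set.

#' Configuration for the synthetic wildlife data set
#'
#' @param cells Tibble with `species`, `season`, `n`: samples per
#'   species-by-season cell. Defaults: bighorn summer 6 / winter 4, bison
#'   summer 14 / winter 11 (total 35, median 10 per species-season; minimum
#'   seasonal sizes 4 and 10, so the double-minimum extrapolation rule
#'   gives targets of 8 and 20 units).
#' @param n_taxa_pool Total plant taxa in the regional pool (default 355).
#' @param family_structure Named integer vector of taxa per family; must
#'   sum to `n_taxa_pool`. Grass-like families get many members so that
#'   coarse lumping and dropout concentrate there.
#' @param base_richness Mean true per-sample richness of the
#'   bighorn-in-winter reference cell.
#' @param season_multiplier Summer-over-winter richness multiplier (> 0).
#' @param species_multiplier Bison-over-bighorn richness multiplier (> 0).
#' @param low_rra_summer_excess If `TRUE` (default) the summer richness
#'   excess of the bison-like species is carried by low-abundance taxa
#'   (steeper rank-abundance skew), so that RRA filtering erases or
#'   reverses its seasonal richness ordering; bighorn summer profiles get
#'   only a mild skew and keep their ordering.
#' @param skew Named vector of Zipf rank-abundance exponents used for the
#'   per-sample true compositions: `even` (winter), `mild` (bighorn
#'   summer), `steep` (bison summer under the excess option).
#' @param richness_jitter_sdlog Lognormal sd of per-sample richness jitter.
#' @param species_pool_frac Named fractions of the pool accessible to each
#'   species (bison larger, driving greater population-level richness).
#' @param winter_pool_frac Fraction of a species pool available in winter
#'   (summer uses the full species pool).
#' @param annotation Fractions of taxa annotated at family / genus /
#'   species (non-increasing; defaults 0.88 / 0.55 / 0.23).
#' @param reads_range Min and max reads per sample (uniform).
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(cells = tibble::tibble(
                             species = c("bighorn", "bighorn",
                                         "bison", "bison"),
                             season = c("summer", "winter",
                                        "summer", "winter"),
                             n = c(6L, 4L, 14L, 11L)
                           ),
                           n_taxa_pool = 355,
                           family_structure = c(
                             Poaceae = 60, Asteraceae = 45, Cyperaceae = 30,
                             Fabaceae = 25, Rosaceae = 25, Brassicaceae = 18,
                             Polygonaceae = 15, Onagraceae = 12,
                             Apiaceae = 12, Salicaceae = 10,
                             Ranunculaceae = 10, Ericaceae = 10,
                             Caryophyllaceae = 10, Orobanchaceae = 8,
                             Chenopodiaceae = 8, Juncaceae = 8,
                             Boraginaceae = 8, Scrophulariaceae = 8,
                             Liliaceae = 8, Lamiaceae = 7,
                             Equisetaceae = 7, Geraniaceae = 6,
                             Pinaceae = 5
                           ),
                           base_richness = 28,
                           season_multiplier = 1.6,
                           species_multiplier = 1.5,
                           low_rra_summer_excess = TRUE,
                           skew = c(even = 0.7, mild = 1.1, steep = 1.6),
                           richness_jitter_sdlog = 0.12,
                           species_pool_frac = c(bighorn = 0.55,
                                                 bison = 0.85),
                           winter_pool_frac = 0.6,
                           annotation = c(family = 0.88, genus = 0.55,
                                          species = 0.23),
                           reads_range = c(30000, 60000)) {
  cells <- tibble::as_tibble(cells)
  stopifnot(all(c("species", "season", "n") %in% names(cells)))
  if (any(cells$n < 2)) {
    abort_param("every species-season cell needs >= 2 samples")
  }
  assert_scalar_number(season_multiplier, "season_multiplier",
                       lower = 0, strict = TRUE)
  assert_scalar_number(species_multiplier, "species_multiplier",
                       lower = 0, strict = TRUE)
  if (sum(family_structure) != n_taxa_pool) {
    abort_param("`family_structure` must sum to `n_taxa_pool`")
  }
  if (any(annotation < 0 | annotation > 1) || is.unsorted(rev(annotation))) {
    abort_param(
      "`annotation` fractions must lie in [0, 1] and be non-increasing"
    )
  }
  richer <- names(which.max(species_pool_frac))
  for (i in seq_len(nrow(cells))) {
    sp <- cells$species[i]; se <- cells$season[i]
    need <- base_richness *
      ifelse(se == "summer", season_multiplier, 1) *
      ifelse(sp == richer, species_multiplier, 1)
    pool <- species_pool_frac[[sp]] * n_taxa_pool *
      ifelse(se == "winter", winter_pool_frac, 1)
    if (1.6 * need > pool) {
      abort_param(sprintf(
        "taxon pool too small for the configured richness in cell %s/%s",
        sp, se
      ))
    }
  }
  structure(
    list(
      cells = cells, n_taxa_pool = as.integer(n_taxa_pool),
      family_structure = family_structure,
      base_richness = base_richness,
      season_multiplier = season_multiplier,
      species_multiplier = species_multiplier,
      low_rra_summer_excess = low_rra_summer_excess,
      skew = skew,
      richness_jitter_sdlog = richness_jitter_sdlog,
      species_pool_frac = species_pool_frac,
      winter_pool_frac = winter_pool_frac,
      annotation = annotation,
      reads_range = reads_range
    ),
    class = "fixture_config"
  )
}

# skew exponent used for one sample's true rank-abundance distribution
cell_skew <- function(config, species, season) {
  if (season != "summer" || !config$low_rra_summer_excess) {
    return(config$skew[["even"]])
  }
  richer <- names(which.max(config$species_pool_frac))
  if (species == richer) config$skew[["steep"]] else config$skew[["mild"]]
}

#' Generate the synthetic wildlife count table
#'
#' Draws, per sample, a true diet as a Zipf-skewed composition over a
#' species- and season-specific taxon pool whose size encodes the
#' configured effects (summer > winter, bison > bighorn), then draws reads
#' multinomially. Taxonomy labels are emitted with the configured
#' annotation completeness. Regeneration with the same seed is identical.
#'
#' @param config A [fixture_config()].
#' @param seed Integer master seed.
#' @return A [count_table] with sample metadata (`species`, `season`,
#'   `n_reads`, `true_richness`, `skew`, `seed`) and taxonomy; the true
#'   per-sample composition vectors are attached as `attr(, "true_diets")`
#'   and the configuration as `attr(, "config")`.
#' @examples
#' cfg <- fixture_config()
#' ds <- generate_wildlife_dataset(cfg, seed = 1)
#' ds
#' @export
generate_wildlife_dataset <- function(config = fixture_config(), seed = 1) {
  stopifnot(inherits(config, "fixture_config"))
  n_pool <- config$n_taxa_pool
  width <- max(3L, nchar(n_pool))
  taxon_ids <- sprintf(paste0("taxon_%0", width, "d"), seq_len(n_pool))

  with_seed(seed, {
    # taxonomy: families laid out contiguously, genera of ~3 members
    fam <- rep(names(config$family_structure), config$family_structure)
    genus_full <- unlist(lapply(names(config$family_structure), function(f) {
      k <- config$family_structure[[f]]
      g <- ceiling(seq_len(k) / 3)
      sprintf("%s_gen%02d", f, g)
    }))
    species_full <- paste0(genus_full, "_sp", unlist(lapply(
      config$family_structure, function(k) ((seq_len(k) - 1) %% 3) + 1
    )))
    n_fam <- round(config$annotation[["family"]] * n_pool)
    n_gen <- round(config$annotation[["genus"]] * n_pool)
    n_sp <- round(config$annotation[["species"]] * n_pool)
    fam_idx <- sort(sample.int(n_pool, n_fam))
    gen_idx <- sort(sample(fam_idx, n_gen))
    sp_idx <- sort(sample(gen_idx, n_sp))
    taxonomy <- tibble::tibble(
      taxon_id = taxon_ids,
      family = ifelse(seq_len(n_pool) %in% fam_idx, fam, NA),
      genus = ifelse(seq_len(n_pool) %in% gen_idx, genus_full, NA),
      species = ifelse(seq_len(n_pool) %in% sp_idx, species_full, NA)
    )

    # global commonness weights: Zipf ranks over a random permutation so
    # families mix; shared weights make dominant taxa consistent across
    # samples and create realistic incidence structure
    w <- (seq_len(n_pool)^-0.8)[order(stats::runif(n_pool))]
    names(w) <- taxon_ids

    pools <- list()
    for (sp in unique(config$cells$species)) {
      sp_size <- round(config$species_pool_frac[[sp]] * n_pool)
      sp_pool <- sample(taxon_ids, sp_size, prob = w)
      pools[[paste0(sp, "_summer")]] <- sp_pool
      pools[[paste0(sp, "_winter")]] <- sample(
        sp_pool, round(config$winter_pool_frac * sp_size),
        prob = w[sp_pool]
      )
    }

    richer <- names(which.max(config$species_pool_frac))
    counts <- matrix(
      0, n_pool, sum(config$cells$n),
      dimnames = list(taxon_ids, rep(NA, sum(config$cells$n)))
    )
    meta <- list()
    true_diets <- list()
    j <- 0L
    for (i in seq_len(nrow(config$cells))) {
      sp <- config$cells$species[i]
      se <- config$cells$season[i]
      pool <- pools[[paste0(sp, "_", se)]]
      mult <- ifelse(se == "summer", config$season_multiplier, 1) *
        ifelse(sp == richer, config$species_multiplier, 1)
      skew <- cell_skew(config, sp, se)
      for (k in seq_len(config$cells$n[i])) {
        j <- j + 1L
        id <- sprintf("%s_%s_%02d", sp, se, k)
        r <- round(config$base_richness * mult *
                     exp(stats::rnorm(1, 0, config$richness_jitter_sdlog)))
        r <- max(5L, min(r, length(pool)))
        taxa <- sample(pool, r, prob = w[pool])
        taxa <- taxa[order(w[taxa], decreasing = TRUE)]
        probs <- seq_len(r)^(-skew)
        probs <- probs / sum(probs)
        n_reads <- round(stats::runif(1, config$reads_range[1],
                                      config$reads_range[2]))
        cnt <- stats::rmultinom(1, n_reads, probs)
        counts[taxa, j] <- cnt
        colnames(counts)[j] <- id
        true <- stats::setNames(numeric(n_pool), taxon_ids)
        true[taxa] <- probs
        true_diets[[id]] <- true
        meta[[id]] <- tibble::tibble(
          sample_id = id, species = sp, season = se,
          n_reads = as.integer(n_reads), true_richness = r, skew = skew
        )
      }
    }
    out <- count_table(counts, sample_meta = dplyr::bind_rows(meta),
                       taxonomy = taxonomy)
    attr(out, "true_diets") <- true_diets
    attr(out, "config") <- config
    attr(out, "seed") <- seed
    out
  })
}

#' Generate the companion microhistology-style composite table
#'
#' Pools the *true* diet compositions of the wildlife data set into one
#' composite per species-season group (emulating composite slide scans of
#' pooled fecal material) and applies coarse taxonomic lumping: with
#' `lumping = "genus"` (default) each taxon is reported under its genus
#' when annotated, under an `"unknown <family>"` sink when only the family
#' is known, and under `"unidentified"` otherwise -- so species-rich
#' families collapse into few categories. `lumping = "identity"` keeps one
#' category per taxon.
#'
#' @param dataset Output of [generate_wildlife_dataset()] (needs its
#'   `true_diets` attribute).
#' @param lumping `"genus"` or `"identity"`.
#' @return Matrix of percent compositions, categories x groups; every
#'   column sums to 100.
#' @export
generate_microhistology <- function(dataset,
                                    lumping = c("genus", "identity")) {
  lumping <- match.arg(lumping)
  true <- attr(dataset, "true_diets")
  if (is.null(true)) {
    abort_param("`dataset` must come from generate_wildlife_dataset()")
  }
  meta <- dataset$sample_meta
  labels <- group_labels(meta, c("species", "season"))
  tax <- dataset$taxonomy
  category <- if (lumping == "identity") {
    tax$taxon_id
  } else {
    ifelse(!is.na(tax$genus), tax$genus,
           ifelse(!is.na(tax$family), paste("unknown", tax$family),
                  "unidentified"))
  }
  names(category) <- tax$taxon_id

  groups <- unique(labels)
  out <- vapply(groups, function(g) {
    ids <- meta$sample_id[labels == g]
    pooled <- rowMeans(vapply(ids, function(s) true[[s]],
                              numeric(length(true[[1]]))))
    agg <- tapply(pooled, category[names(pooled)], sum)
    full <- stats::setNames(numeric(length(unique(category))),
                            sort(unique(category)))
    full[names(agg)] <- agg
    100 * full / sum(full)
  }, numeric(length(unique(category))))
  out
}
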