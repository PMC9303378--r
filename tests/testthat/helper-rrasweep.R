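# fixtures built in code, shared across test files

toy_counts <- function() {
  m <- matrix(
    c(900,  60,  40,   0,
      500, 250, 200,  50,
      100, 100, 100, 700),
    nrow = 4,
    dimnames = list(
      c("t1", "t2", "t3", "t4"),
      c("skewed", "even", "dominated")
    )
  )
  m
}

toy_table <- function() {
  count_table(
    toy_counts(),
    sample_meta = tibble::tibble(
      sample_id = c("skewed", "even", "dominated"),
      species = c("a", "a", "b"),
      season = c("summer", "winter", "summer")
    ),
    taxonomy = tibble::tibble(
      taxon_id = c("t1", "t2", "t3", "t4"),
      family = c("Poaceae", "Poaceae", NA, "Rosaceae"),
      genus = c("Poa", NA, NA, "Rosa"),
      species = c(NA, NA, NA, NA)
    )
  )
}

random_counts <- function(seed, n_taxa = 10, n_samples = 4, lambda = 40) {
  set.seed(seed)
  matrix(
    rpois(n_taxa * n_samples, lambda) *
      rbinom(n_taxa * n_samples, 1, 0.8),
    nrow = n_taxa,
    dimnames = list(
      sprintf("t%02d", seq_len(n_taxa)),
      sprintf("s%02d", seq_len(n_samples))
    )
  )
}

random_composition <- function(seed, n = 12) {
  set.seed(seed)
  p <- rgamma(n, shape = runif(1, 0.3, 2))
  p / sum(p)
}

small_fixture_config <- function(...) {
  fixture_config(
    cells = tibble::tibble(
      species = c("bighorn", "bighorn", "bison", "bison"),
      season = c("summer", "winter", "summer", "winter"),
      n = c(3L, 2L, 4L, 3L)
    ),
    reads_range = c(8000, 12000),
    ...
  )
}
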