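test_that("hill_number matches hand-computed effective taxon counts", {
  expect_equal(hill_number(rep(1 / 7, 7), c(0, 1, 2)), rep(7, 3))

  p <- c(0.8, 0.2)
  expect_equal(hill_number(p, 2), 1 / (0.64 + 0.04))          # 1.470588...
  expect_equal(hill_number(p, 1), exp(-(0.8 * log(0.8) + 0.2 * log(0.2))),
               tolerance = 1e-12)
  expect_equal(hill_number(p, 1), 1.6493849, tolerance = 1e-6)
  expect_equal(hill_number(p, 0), 2)

  expect_error(hill_number(c(0, 0), 1), "all-zero")
  expect_error(hill_number(c(0.5, 0.5), -1), "q")
  expect_error(hill_number(c(-0.1, 1.1), 1), "non-negative")
})

test_that("Hill numbers are monotone in q, continuous at q = 1, and double under replication", {
  q_grid <- seq(0, 3, by = 0.1)
  for (s in 1:20) {
    p <- random_composition(s)
    d <- hill_number(p, q_grid)
    expect_true(all(d >= 1))
    expect_true(all(diff(d) <= 1e-10))
    expect_equal(d[q_grid == 0], sum(p > 0))

    expect_lt(abs(hill_number(p, 1 + 1e-6) - hill_number(p, 1)), 1e-4)
    expect_lt(abs(hill_number(p, 1 - 1e-6) - hill_number(p, 1)), 1e-4)

    # doubling: spreading each proportion over two taxa doubles D(q)
    doubled <- rep(p / 2, 2)
    for (q in c(0, 0.5, 1, 2)) {
      expect_equal(hill_number(doubled, q), 2 * hill_number(p, q),
                   tolerance = 1e-10)
    }

    # scale invariance of the input vector
    expect_equal(hill_number(5 * p, q_grid), d, tolerance = 1e-12)
  }
})

test_that("hill_number agrees with vegan's Renyi-based implementation", {
  scales <- c(0, 0.25, 0.5, 1, 1.5, 2, 4)
  for (s in 1:15) {
    p <- random_composition(s, n = 20)
    ref <- as.numeric(vegan::renyi(p, scales = scales, hill = TRUE))
    expect_equal(hill_number(p, scales), ref, tolerance = 1e-9)
  }
})

test_that("diversity_profile covers samples and pooled groups coherently", {
  tab <- simulate_consumers(seed = 3)
  q_grid <- seq(0, 2, by = 0.25)
  dp <- diversity_profile(tab, q_grid = q_grid)

  # simulated consumer ordering holds at every order
  wide <- tidyr::pivot_wider(dp, names_from = "unit_id", values_from = "d")
  expect_true(all(wide$generalist >= wide$intermediate))
  expect_true(all(wide$intermediate >= wide$specialist))

  # q = 0 equals observed richness from the threshold-0 sweep
  sw <- threshold_sweep(tab, 0)
  d0 <- dp[dp$q == 0, ]
  expect_equal(d0$d[match(sw$richness$sample_id, d0$unit_id)],
               as.numeric(sw$richness$richness))

  # monoculture sample has a flat profile at 1
  mono <- matrix(42, 1, 1, dimnames = list("t1", "s1"))
  expect_true(all(diversity_profile(mono, q_grid)$d == 1))

  # pooled groups equal profiles of summed counts
  toy <- toy_table()
  pooled <- diversity_profile(toy, q_grid = c(0, 1, 2),
                              pool_by = "species")
  manual <- rowSums(toy$counts[, toy$sample_meta$species == "a"])
  expect_equal(pooled$d[pooled$unit_id == "a"],
               hill_number(manual / sum(manual), c(0, 1, 2)))

  z <- cbind(s1 = c(5, 5), s2 = c(0, 0))
  expect_warning(dz <- diversity_profile(z, c(0, 1)), "empty")
  expect_identical(unique(dz$unit_id), "s1")
})

test_that("group_summary averages Hill numbers, optionally on the log scale", {
  profiles <- tibble::tibble(
    unit_id = c("s1", "s2", "s3"),
    q = 0,
    d = c(2, 8, 5)
  )
  meta <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                         species = c("a", "a", "b"))
  gs <- group_summary(profiles, meta, "species", q = 0, transform = "log")
  a <- gs[gs$group == "a", ]
  expect_equal(a$mean, (log(2) + log(8)) / 2)        # 1.3862944
  expect_equal(a$mean, 1.3862944, tolerance = 1e-6)
  expect_equal(a$sd, abs(log(8) - log(2)) / sqrt(2)) # 0.9802581
  b <- gs[gs$group == "b", ]
  expect_equal(b$sd, 0)
  expect_true(b$single_member)

  raw <- group_summary(profiles, meta, "species", q = 0)
  expect_equal(raw$mean[raw$group == "a"], 5)

  same <- group_summary(
    tibble::tibble(unit_id = c("s1", "s2"), q = 1, d = c(4, 4)),
    tibble::tibble(sample_id = c("s1", "s2"), species = "a"),
    "species", q = 1
  )
  expect_equal(same$sd, 0)
})

test_that("compare_methods pairs DNA and microhistology summaries per group", {
  tab <- toy_table()

  # one-category composite: diversity collapses to 1 at every order
  micro1 <- matrix(100, 1, 3,
                   dimnames = list("grass", c("a_summer", "a_winter",
                                              "b_summer")))
  cmp1 <- compare_methods(tab, micro1)
  m1 <- cmp1[cmp1$method == "microhistology", ]
  expect_true(all(m1$mean == 1))

  # identical composition on both sides gives identical D at all q
  pooled <- vapply(
    unique(paste(tab$sample_meta$species, tab$sample_meta$season,
                 sep = "_")),
    function(g) {
      keep <- paste(tab$sample_meta$species, tab$sample_meta$season,
                    sep = "_") == g
      v <- rowSums(tab$counts[, keep, drop = FALSE])
      100 * v / sum(v)
    },
    numeric(nrow(tab$counts))
  )
  cmp2 <- compare_methods(tab, pooled, dna_pathway = "pooled")
  wide <- tidyr::pivot_wider(cmp2, id_cols = c("group", "q"),
                             names_from = "method", values_from = "mean")
  expect_equal(wide$dna, wide$microhistology, tolerance = 1e-12)

  bad <- micro1
  colnames(bad) <- c("a_summer", "a_winter", "elsewhere")
  expect_error(compare_methods(tab, bad), "unmatched")
  off <- micro1 * 1.1
  expect_error(compare_methods(tab, off), "100")
})
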