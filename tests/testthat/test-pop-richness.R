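# independent frozen formula used as a cross-check, written directly from
# the published incidence-based estimator rather than calling the package
chao2_oracle <- function(T, Q1, Q2) {
  if (Q1 == 0) return(0)
  if (Q2 > 0) (T - 1) / T * Q1^2 / (2 * Q2) else
    (T - 1) / T * Q1 * (Q1 - 1) / 2
}

make_freqs <- function(T, S_obs, Q1, Q2) {
  structure(list(group = "g", T = T, S_obs = S_obs, Q1 = Q1, Q2 = Q2),
            class = "incidence_freqs")
}

random_incidence <- function(seed, T = sample(3:12, 1), n_taxa = 30) {
  set.seed(seed)
  m <- matrix(rbinom(n_taxa * T, 1, runif(1, 0.1, 0.5)), nrow = n_taxa)
  m[1, ] <- 1  # keep at least one taxon detected
  dimnames(m) <- list(sprintf("t%02d", 1:n_taxa), sprintf("s%02d", 1:T))
  m
}

test_that("incidence_freqs reduces detection patterns correctly", {
  one <- matrix(c(3, 1, 2, 9, 4), ncol = 1,
                dimnames = list(paste0("t", 1:5), "s1"))
  f <- incidence_freqs(one)$all
  expect_equal(f[c("T", "S_obs", "Q1", "Q2")],
               list(T = 1L, S_obs = 5L, Q1 = 5L, Q2 = 0L))

  m <- matrix(c(1, 1, 0,
                1, 0, 0,
                1, 1, 1), nrow = 3, byrow = TRUE)
  dimnames(m) <- list(paste0("t", 1:3), paste0("s", 1:3))
  f2 <- incidence_freqs(m)$all
  expect_equal(f2$S_obs, 3L)
  expect_equal(f2$Q1, 1L)
  expect_equal(f2$Q2, 1L)
  expect_equal(f2$T, 3L)

  expect_error(incidence_freqs(matrix(0, 3, 2)), "no detected taxa")
})

test_that("the undetected-richness estimator matches hand-computed values", {
  expect_equal(estimate_undetected(make_freqs(10, 20, 0, 3)), 0)
  expect_equal(estimate_undetected(make_freqs(10, 20, 5, 2)), 5.625)
  expect_equal(estimate_undetected(make_freqs(10, 20, 3, 0)), 2.7)
  expect_error(estimate_undetected(make_freqs(1, 5, 5, 0)), "T >= 2")
})

test_that("extrapolation obeys its closed form, bounds, and monotonicity", {
  f <- make_freqs(10, 20, 5, 2)
  expect_equal(extrapolate_richness(f, 10), 20)   # t* = 0
  expect_equal(extrapolate_richness(f, 1e6), 25.625, tolerance = 1e-9)
  expect_error(extrapolate_richness(f, 9), "target_T")

  for (s in 1:25) {
    set.seed(s)
    T <- sample(2:15, 1)
    Q1 <- sample(0:8, 1); Q2 <- sample(0:5, 1)
    S <- Q1 + Q2 + sample(0:10, 1)
    fr <- make_freqs(T, S, Q1, Q2)
    q0 <- chao2_oracle(T, Q1, Q2)
    expect_equal(estimate_undetected(fr), q0, tolerance = 1e-12)
    targets <- T + c(0, 1, 3, 10, 100)
    est <- vapply(targets, function(tt) extrapolate_richness(fr, tt),
                  numeric(1))
    # re-derived closed form, evaluated independently
    expected <- if (q0 == 0 || Q1 == 0) rep(S, length(targets)) else
      S + q0 * (1 - (1 - Q1 / (Q1 + T * q0))^(targets - T))
    expect_equal(est, expected, tolerance = 1e-12)
    expect_true(all(diff(est) >= 0))
    expect_true(all(est >= S - 1e-9 & est <= S + q0 + 1e-9))
  }
})

test_that("the asymptotic estimate agrees with vegan::specpool on random incidence data", {
  for (s in 1:100) {
    m <- random_incidence(s)
    f <- incidence_freqs(m)$all
    asymptote <- f$S_obs + estimate_undetected(f)
    ref <- vegan::specpool(t(m))$chao
    expect_equal(asymptote, ref, tolerance = 1e-6)
  }
})

test_that("pooling more sampling units never decreases observed richness", {
  m <- random_incidence(99, T = 10)
  s_obs <- vapply(2:10, function(k) {
    incidence_freqs(m[, 1:k, drop = FALSE])$all$S_obs
  }, integer(1))
  expect_true(all(diff(s_obs) >= 0))
})

test_that("bootstrap intervals behave at the degenerate and generic ends", {
  # identical sampling units: no uniques, zero-width interval at S_obs
  same <- matrix(rep(c(5, 3, 0, 2), 4), nrow = 4,
                 dimnames = list(paste0("t", 1:4), paste0("s", 1:4)))
  ci <- bootstrap_ci(same, B = 50, seed = 1)
  expect_equal(ci$estimate, 3)
  expect_equal(ci$lower, 3)
  expect_equal(ci$upper, 3)

  m <- random_incidence(7, T = 8)
  # level 0 collapses the percentile interval onto the bootstrap median
  ci0 <- bootstrap_ci(m, B = 60, level = 0, seed = 2)
  expect_equal(ci0$lower, ci0$upper)

  # recentered interval brackets the point estimate
  cir <- bootstrap_ci(m, B = 60, ci_type = "recentered", seed = 3)
  expect_true(cir$lower <= cir$estimate && cir$estimate <= cir$upper)

  # seed reproducibility
  expect_identical(bootstrap_ci(m, B = 40, seed = 5),
                   bootstrap_ci(m, B = 40, seed = 5))
  expect_error(bootstrap_ci(m, B = 1, seed = 1), "B")
})

test_that("population richness sweeps start from the unfiltered estimate", {
  tab <- toy_table()
  sw <- sweep_population_richness(tab, thresholds = c(0, 0.05),
                                  group_by = "species", target_T = 6)
  base <- incidence_freqs(tab, "species")
  for (g in names(base)) {
    row0 <- sw[sw$group == g & sw$threshold == 0, ]
    expected <- if (base[[g]]$T < 2) {
      as.numeric(base[[g]]$S_obs)  # single unit: no extrapolation possible
    } else {
      extrapolate_richness(base[[g]], max(6, base[[g]]$T))
    }
    expect_equal(row0$estimate, expected)
    expect_equal(row0$S_obs, base[[g]]$S_obs)
  }
  one <- sweep_population_richness(tab, thresholds = 0.01,
                                   group_by = "species", target_T = 6)
  expect_identical(nrow(one), 2L)
})

test_that("the double-minimum target rule works within the outer stratum", {
  cfg <- small_fixture_config()
  ds <- generate_wildlife_dataset(cfg, seed = 4)
  ci <- bootstrap_ci(ds, group_by = c("species", "season"), B = 20,
                     seed = 1)
  expect_equal(ci$target_T[ci$group == "bighorn_summer"], 4L)  # 2 x min(3, 2)
  expect_equal(ci$target_T[ci$group == "bison_winter"], 6L)    # 2 x min(4, 3)
})
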