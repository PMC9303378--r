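test_that("to_rra converts counts to per-sample proportions", {
  expect_equal(as.vector(to_rra(matrix(25000, 1, 1))), 1)
  expect_equal(as.vector(to_rra(matrix(c(75, 25), 2, 1))), c(0.75, 0.25))

  for (s in 1:10) {
    m <- random_counts(s)
    keep <- colSums(m) > 0
    expect_equal(unname(colSums(to_rra(m))[keep]),
                 rep(1, sum(keep)), tolerance = 1e-12)
  }

  z <- cbind(a = c(3, 1), b = c(0, 0))
  expect_warning(r <- to_rra(z), "all-zero")
  expect_true(all(r[, "b"] == 0))
})

test_that("apply_threshold retains strictly above-threshold taxa, unrenormalized", {
  tab <- toy_table()
  expect_identical(apply_threshold(tab, 0)$counts, tab$counts)

  m <- matrix(c(90, 6, 4), ncol = 1,
              dimnames = list(c("t1", "t2", "t3"), "s"))
  f <- apply_threshold(m, 0.05)
  expect_equal(as.vector(f), c(90, 6, 0))
  expect_equal(sum(f > 0), 2)

  # strict inequality: RRA = 1 in a monoculture does not exceed 1
  expect_true(all(apply_threshold(m, 1) == 0))
  expect_true(all(apply_threshold(matrix(10, 1, 1), 1) == 0))
  expect_error(apply_threshold(m, 1.5), "threshold")
})

test_that("thresholding is idempotent, nested, and matches a brute-force oracle", {
  thresholds <- c(0, 0.002, 0.01, 0.05, 0.2)
  for (s in 1:5) {
    m <- random_counts(s)
    prev <- NULL
    for (t in thresholds) {
      f <- apply_threshold(m, t)
      expect_identical(apply_threshold(f, t), f)

      # oracle: independent per-cell RRA comparison loop
      expected <- m
      for (j in seq_len(ncol(m))) {
        tot <- sum(m[, j])
        for (i in seq_len(nrow(m))) {
          if (tot == 0 || m[i, j] / tot <= t) expected[i, j] <- 0
        }
      }
      expect_identical(f, expected)

      # nesting: higher thresholds retain subsets
      if (!is.null(prev)) expect_true(all(prev[f > 0] > 0))
      prev <- f

      # richness bound: retained RRAs each exceed t and sum to <= 1
      if (t > 0) expect_true(all(colSums(f > 0) < 1 / t))
    }
  }
})

test_that("threshold_sweep tracks monotone richness loss against baseline", {
  tab <- toy_table()
  sw <- threshold_sweep(tab, seq(0, 0.5, by = 0.05))
  for (id in colnames(tab$counts)) {
    r <- sw$richness[sw$richness$sample_id == id, ]
    expect_true(all(diff(r$richness) <= 0))
    expect_true(all(diff(r$pct_loss) >= 0))
    expect_equal(r$pct_loss[r$threshold == 0], 0)
    expect_true(all(r$pct_loss >= 0 & r$pct_loss <= 100))
  }

  mono <- matrix(5, 1, 1, dimnames = list("t1", "s1"))
  swm <- threshold_sweep(mono, c(0, 0.3, 0.9))
  expect_true(all(swm$richness$richness == 1))
  expect_true(all(swm$richness$pct_loss == 0))

  expect_error(threshold_sweep(tab, numeric()), "empty")
  expect_error(threshold_sweep(tab, c(0.05, 0.01)), "ascending")
})

test_that("convergence_threshold finds where samples stop differing", {
  m <- cbind(a = c(10, 5, 2), b = c(10, 5, 2))
  sw <- threshold_sweep(m, c(0, 0.01, 0.05))
  conv <- convergence_threshold(sw, tolerance = 0)
  expect_equal(conv$threshold, 0)

  # disjoint monocultures tie at richness 1 from the start
  dm <- cbind(a = c(7, 0), b = c(0, 9))
  expect_equal(
    convergence_threshold(threshold_sweep(dm, c(0, 0.02)), 0)$threshold, 0
  )

  # minimal achievable tolerance is found and reported
  sp <- cbind(a = c(60, 25, 15), b = c(100, 0, 0))
  swp <- threshold_sweep(sp, c(0, 0.2, 0.7))
  auto <- convergence_threshold(swp)
  expect_equal(auto$threshold, 0.2)   # spreads are 2, 1, 1 on this grid
  expect_equal(auto$tolerance, 1)
  expect_true(is.na(convergence_threshold(swp, tolerance = -1)$threshold))

  expect_error(convergence_threshold(threshold_sweep(mono <- matrix(1))),
               "2 samples")
})

test_that("rank_order_trajectory records inversions of the baseline ordering", {
  stable <- cbind(a = c(rep(10, 10)), b = c(rep(10, 5), rep(0, 5)))
  sw <- threshold_sweep(stable, c(0, 0.05))
  tr <- rank_order_trajectory(sw)
  expect_identical(nrow(tr$inversions), 0L)
  expect_true(all(tr$ranks$rank[tr$ranks$sample_id == "a"] == 1))

  # an even sample overtakes an initially richer skewed one
  even10 <- rep(100, 10)
  skew12 <- c(820, rep(15, 11))
  m <- matrix(0, 12, 2, dimnames = list(paste0("t", 1:12), c("A", "B")))
  m[1:10, "A"] <- even10
  m[, "B"] <- skew12
  sw2 <- threshold_sweep(m, c(0, 0.05))
  tr2 <- rank_order_trajectory(sw2)
  expect_identical(tr2$inversions$threshold, 0.05)
  expect_identical(tr2$inversions$sample_high, "B")
  expect_identical(tr2$inversions$sample_low, "A")
})

test_that("dropout_ledger aggregates group-level taxon losses by rank", {
  tab <- toy_table()
  led <- dropout_ledger(tab, thresholds = c(0.002, 0.05, 0.15),
                        group_by = "species", taxon_level = "family")
  # t1 holds >= 50% RRA in one sample per group: never lost up to 5%
  led_low <- led[led$threshold <= 0.05, ]
  expect_false(any(grepl("\\bt1\\b", led_low$taxa)))
  # nothing drops out of either group at a 0.2% threshold
  expect_false(any(led$threshold == 0.002))
  # unannotated taxa are ledgered under "unknown"
  expect_true("unknown" %in% led$rank_label)

  # brute-force recomputation of one group/threshold cell
  rra <- to_rra(tab)
  grp <- tab$sample_meta$species == "a"
  present0 <- rownames(rra)[rowSums(rra[, grp, drop = FALSE] > 0) > 0]
  present5 <- rownames(rra)[rowSums(rra[, grp, drop = FALSE] > 0.05) > 0]
  lost <- setdiff(present0, present5)
  got <- led[led$group == "a" & led$threshold == 0.05, ]
  expect_setequal(unlist(strsplit(got$taxa, ";")), lost)
  expect_equal(sum(got$n_taxa_lost), length(lost))

  expect_identical(nrow(dropout_ledger(tab, thresholds = 0,
                                       group_by = "species")), 0L)
  expect_error(dropout_ledger(tab, group_by = "habitat"), "unknown")
  expect_error(dropout_ledger(tab, group_by = "species",
                              taxon_level = "order"), "order")
})
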