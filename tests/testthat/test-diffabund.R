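small_table <- function(seed = 1) random_count_table(D = 6, S = 6,
                                                     seed = seed)

test_that("monte-carlo ensembles are reproducible and shaped correctly", {
  tab <- small_table()
  e1 <- sample_mc_instances(tab, K = 10, seed = 42)
  e2 <- sample_mc_instances(tab, K = 10, seed = 42)
  expect_identical(e1$clr, e2$clr)
  e3 <- sample_mc_instances(tab, K = 10, seed = 43)
  expect_false(identical(e1$clr, e3$clr))
  expect_equal(dim(e1$clr), c(6L, 6L, 10L))
  # every instance is a valid CLR vector
  expect_true(all(abs(apply(e1$clr, c(2, 3), sum)) < 1e-9))
  expect_error(sample_mc_instances(tab, K = 0), "K")
  expect_error(sample_mc_instances(tab, prior = -1), "prior")
})

test_that("dirichlet instances concentrate on uniform for huge equal counts", {
  m <- matrix(1e6, nrow = 5, ncol = 2,
              dimnames = list(paste0("f", 1:5), paste0("s", 1:2)))
  ens <- sample_mc_instances(count_table(m), K = 128, seed = 9)
  expect_lt(max(abs(ens$clr)), 0.01)
})

test_that("exact effect statistics match hand-enumerated pooled pairs", {
  # P_A={0,0}, P_B={1,3}: 1 feature, 2 samples per group, K = 1
  arr <- array(c(0, 0, 1, 3), dim = c(1, 4, 1),
               dimnames = list("f1", c("a1", "a2", "b1", "b2"), NULL))
  ens <- manual_ensemble(arr, K = 1)
  des <- group_design(c("a1", "a2", "b1", "b2"), c("A", "A", "B", "B"))
  eff <- effect_statistics(ens, des, mode = "exact")
  expect_equal(eff$diff.btw, 2)

  arr2 <- array(c(0, 2, 4, 6), dim = c(1, 4, 1),
                dimnames = list("f1", c("a1", "a2", "b1", "b2"), NULL))
  eff2 <- effect_statistics(manual_ensemble(arr2, 1), des, mode = "exact")
  expect_equal(eff2$diff.btw, 4)
  expect_equal(eff2$diff.win, 2)
  expect_equal(eff2$effect, 2)
  expect_equal(eff2$overlap, 0)

  # degenerate: both groups constant and equal
  arr3 <- array(1, dim = c(1, 4, 1),
                dimnames = list("f1", c("a1", "a2", "b1", "b2"), NULL))
  eff3 <- effect_statistics(manual_ensemble(arr3, 1), des, mode = "exact")
  expect_equal(eff3$diff.btw, 0)
  expect_equal(eff3$diff.win, 0)
  expect_equal(eff3$effect, 0)        # 0/0 convention
  expect_equal(eff3$overlap, 0.5)     # ties split evenly
})

test_that("exact effect statistics equal the brute-force oracle", {
  for (seed in 1:25) {
    dims <- withr::with_seed(seed, {
      nA <- sample(2:3, 1); nB <- sample(2:3, 1); K <- sample(1:4, 1)
      vals <- array(round(stats::rnorm(2 * (nA + nB) * K), 2),
                    dim = c(2, nA + nB, K),
                    dimnames = list(c("f1", "f2"),
                                    sprintf("s%d", 1:(nA + nB)), NULL))
      list(nA = nA, nB = nB, K = K, vals = vals)
    })
    ens <- manual_ensemble(dims$vals, dims$K)
    des <- group_design(sprintf("s%d", 1:(dims$nA + dims$nB)),
                        rep(c("A", "B"), c(dims$nA, dims$nB)))
    eff <- effect_statistics(ens, des, mode = "exact")
    for (f in 1:2) {
      a <- as.vector(dims$vals[f, 1:dims$nA, ])
      b <- as.vector(dims$vals[f, (dims$nA + 1):(dims$nA + dims$nB), ])
      orc <- oracle_effect_stats(a, b)
      expect_equal(eff$diff.btw[f], orc$diff_btw, tolerance = 1e-12)
      expect_equal(eff$diff.win[f], orc$diff_win, tolerance = 1e-12)
      expect_equal(eff$effect[f], orc$effect, tolerance = 1e-12)
      expect_equal(eff$overlap[f], orc$overlap, tolerance = 1e-12)
    }
  }
})

test_that("subsampled estimates are unbiased for the exact estimands", {
  tab <- small_table(seed = 4)
  ens <- sample_mc_instances(tab, K = 4, seed = 7)
  des <- group_design(colnames(tab$counts), rep(c("A", "B"), each = 3))
  exact <- effect_statistics(ens, des, mode = "exact")
  ests <- sapply(1:20, function(s)
    effect_statistics(ens, des, mode = "subsample", max_pairs = 2000,
                      seed = s)$diff.btw[1])
  se <- stats::sd(ests) / sqrt(length(ests))
  # the subsampled median converges into the interval between the two
  # central order statistics of the enumerated pair differences; allow
  # that discretisation gap on top of the monte-carlo error
  pooled_A <- as.vector(ens$clr[1, 1:3, ]); pooled_B <- as.vector(ens$clr[1, 4:6, ])
  d <- sort(as.vector(outer(pooled_B, pooled_A, "-")))
  gap <- d[length(d) / 2 + 1] - d[length(d) / 2]
  expect_lt(abs(mean(ests) - exact$diff.btw[1]), 2 * se + gap)
  # and error shrinks with more pairs
  big <- effect_statistics(ens, des, mode = "subsample",
                           max_pairs = 50000, seed = 1)
  expect_lt(abs(big$diff.btw[1] - exact$diff.btw[1]), 0.05)
})

test_that("swapping the group labels negates the signed statistics", {
  tab <- small_table(seed = 6)
  ens <- sample_mc_instances(tab, K = 3, seed = 11)
  ids <- colnames(tab$counts)
  d1 <- group_design(ids, rep(c("A", "B"), each = 3))
  # same partition, but listed so the second group's label appears first,
  # which swaps the group roles under the first-appearance rule
  d2 <- group_design(ids[c(4:6, 1:3)],
                     rep(c("B", "A"), each = 3)[c(4:6, 1:3)])
  e1 <- effect_statistics(ens, d1, mode = "exact")
  e2 <- effect_statistics(ens, d2, mode = "exact")
  expect_equal(e2$diff.btw, -e1$diff.btw, tolerance = 1e-12)
  expect_equal(e2$effect, -e1$effect, tolerance = 1e-12)
  expect_equal(e2$diff.win, e1$diff.win, tolerance = 1e-12)
  expect_equal(e2$overlap, e1$overlap, tolerance = 1e-12)
  t1 <- per_instance_tests(ens, d1)
  t2 <- per_instance_tests(ens, d2)
  expect_equal(t1, t2, tolerance = 1e-12)
})

test_that("effect-table invariants hold on generated data", {
  s <- generate_counts(synth_spec(n_features = 30,
                                  samples_per_group = c(4, 4),
                                  depth_range = c(1000, 2000), seed = 3))
  eff <- aldex_like(s$table, s$metadata$data$group, K = 16, seed = 4)
  expect_true(all(eff$diff.win >= 0))
  expect_true(all(eff$overlap >= 0 & eff$overlap <= 0.5))
  pcols <- c("we.ep", "we.eBH", "wi.ep", "wi.eBH")
  expect_true(all(unlist(eff[pcols]) >= 0 & unlist(eff[pcols]) <= 1))
  nz <- eff$diff.win > 0
  expect_equal(sign(eff$effect[nz]), sign(eff$diff.btw[nz]))
  # the hover-style uncertainty interval brackets the median difference
  expect_true(all(eff$diff.btw.q025 <= eff$diff.btw + 1e-12))
  expect_true(all(eff$diff.btw >= eff$diff.btw.q025 - 1e-12 &
                    eff$diff.btw <= eff$diff.btw.q975 + 1e-12))
  rec <- effect_plot_data(eff)
  expect_true(all(c("y_q025", "y_q975") %in% names(rec)))
})

test_that("per-instance tests agree with the reference test functions", {
  # one instance, no ties: exact Wilcoxon and Welch against stats::
  a <- c(1.2, -0.3, 0.8, 2.1); b <- c(3.3, 2.8, 4.1, 3.0)
  arr <- array(c(a, b), dim = c(1, 8, 1),
               dimnames = list("f1", sprintf("s%d", 1:8), NULL))
  ens <- manual_ensemble(arr, 1)
  des <- group_design(sprintf("s%d", 1:8), rep(c("A", "B"), each = 4))
  res <- per_instance_tests(ens, des)
  expect_equal(res$wi.ep,
               stats::wilcox.test(a, b, exact = TRUE)$p.value,
               tolerance = 1e-12)
  expect_equal(res$we.ep, stats::t.test(a, b)$p.value, tolerance = 1e-12)

  # larger groups with ties: the tie-corrected normal approximation
  a2 <- c(rep(1, 6), 2:9); b2 <- c(rep(1, 3), 5:15)
  arr2 <- array(c(a2, b2), dim = c(1, 28, 1),
                dimnames = list("f1", sprintf("s%d", 1:28), NULL))
  res2 <- per_instance_tests(manual_ensemble(arr2, 1),
                             group_design(sprintf("s%d", 1:28),
                                          rep(c("A", "B"), each = 14)))
  expect_equal(res2$wi.ep,
               suppressWarnings(
                 stats::wilcox.test(a2, b2, exact = FALSE,
                                    correct = TRUE)$p.value),
               tolerance = 1e-12)
})

test_that("separated ranks give the enumerated two-sided p of 2/70", {
  arr <- array(c(1, 2, 3, 4, 5, 6, 7, 8), dim = c(1, 8, 1),
               dimnames = list("f1", sprintf("s%d", 1:8), NULL))
  res <- per_instance_tests(manual_ensemble(arr, 1),
                            group_design(sprintf("s%d", 1:8),
                                         rep(c("A", "B"), each = 4)))
  expect_equal(res$wi.ep, 2 / 70, tolerance = 1e-12)
})

test_that("a feature identical everywhere yields p = 1", {
  arr <- array(5, dim = c(2, 8, 2),
               dimnames = list(c("f1", "f2"), sprintf("s%d", 1:8), NULL))
  arr[2, , ] <- rep(1:8, times = 2)  # keep a second, varying feature
  res <- per_instance_tests(manual_ensemble(arr, 2),
                            group_design(sprintf("s%d", 1:8),
                                         rep(c("A", "B"), each = 4)))
  expect_equal(res$we.ep[1], 1)
})

test_that("expected values are arithmetic means across instances", {
  # two instances engineered so the per-instance BH values differ
  arr <- array(0, dim = c(2, 8, 2),
               dimnames = list(c("f1", "f2"), sprintf("s%d", 1:8), NULL))
  arr[1, , 1] <- c(1, 2, 3, 4, 10, 11, 12, 13)
  arr[2, , 1] <- c(1, 3, 2, 4, 2, 3, 1, 4)
  arr[1, , 2] <- c(1, 2, 3, 4, 5, 6, 7, 8)
  arr[2, , 2] <- c(4, 2, 3, 1, 2, 3, 1, 4)
  des <- group_design(sprintf("s%d", 1:8), rep(c("A", "B"), each = 4))
  both <- per_instance_tests(manual_ensemble(arr, 2), des)
  one <- per_instance_tests(manual_ensemble(arr[, , 1, drop = FALSE], 1),
                            des)
  two <- per_instance_tests(manual_ensemble(arr[, , 2, drop = FALSE], 1),
                            des)
  expect_equal(both$wi.eBH, (one$wi.eBH + two$wi.eBH) / 2,
               tolerance = 1e-12)
  expect_equal(both$we.ep, (one$we.ep + two$we.ep) / 2, tolerance = 1e-12)
})

test_that("benjamini-hochberg handles edges and propagates NAs", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.3), 0.3)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  out <- benjamini_hochberg(c(0.01, NA, 0.04))
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], c(0.02, 0.04))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("plot records class features by the shared rule", {
  eff <- data.frame(rab.all = c(3.2, 0.1, -1), diff.btw = c(-1.1, 0.05, 2),
                    diff.win = c(0.7, 0.5, 1),
                    effect = c(-1.5, 0.1, 2.0),
                    wi.eBH = c(0.2, 0.8, 0.01),
                    row.names = c("f1", "f2", "f3"))
  ep <- effect_plot_data(eff)
  expect_equal(ep$class, c("effect_only", "nonsignificant", "both"))
  expect_equal(ep$x, eff$diff.win)
  expect_equal(ep$y, eff$diff.btw)
  ma <- ma_plot_data(eff)
  expect_equal(ma$class, ep$class)
  expect_equal(ma$x, eff$rab.all)
  expect_equal(ma[ma$feature == "f1", "y"], -1.1)
  empty <- ma_plot_data(eff[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("group designs reject degenerate labellings", {
  expect_error(group_design(c("s1", "s2"), c("A", "A")), "exactly two")
  expect_error(group_design(c("s1", "s2"), c("A", NA)), "labelled")
  d <- group_design(c("s1", "s2", "s3"), c("x", "y", "x"))
  expect_equal(d$groups, c("x", "y"))
})
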