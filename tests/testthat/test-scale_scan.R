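scan_fixture <- function(seed = 1) {
  ds <- suppressWarnings(synthetic_dataset(small_config(seed), periods = 2))
  pairs <- default_pairs(ds)
  ptab <- pair_abundance_table(ds$table, pairs)
  tree <- ward_dendrogram(pair_fluvial_matrix(pairs, ds$fluvial))
  list(ds = ds, pairs = pairs, ptab = ptab, tree = tree)
}

test_that("cluster temporal change pools then compares, per cluster", {
  fx <- scan_fixture()
  n <- nrow(fx$pairs)
  ids <- fx$tree$labels

  # singleton clusters reproduce the local paired values
  singletons <- setNames(seq_len(n), ids)
  v <- cluster_temporal_change(fx$ptab, singletons)
  D <- dissimilarity_matrix(fx$ptab)
  local <- paired_temporal_dissimilarity(
    D, data.frame(site_t1 = ids, site_t2 = ids))
  expect_equal(unname(v), unname(local), tolerance = 1e-12)

  # identical assemblages in both periods give zeros
  m <- matrix(c(3, 1, 2, 5, 3, 1, 2, 5), 4, 2, byrow = TRUE,
              dimnames = list(NULL, c("x", "y")))
  same <- abundance_table(m, c("p1", "p2", "p1", "p2"),
                          c("T1", "T1", "T2", "T2"))
  expect_equal(unname(cluster_temporal_change(
    same, c(p1 = 1, p2 = 2))), c(0, 0))

  # pooling can mask local turnover: period-2 assemblages are the
  # period-1 assemblages swapped between the two pairs of one cluster
  sw <- abundance_table(
    matrix(c(9, 1, 1, 9, 1, 9, 9, 1), 4, 2, byrow = TRUE,
           dimnames = list(NULL, c("x", "y"))),
    c("p1", "p2", "p1", "p2"), c("T1", "T1", "T2", "T2"))
  locals <- cluster_temporal_change(sw, c(p1 = 1, p2 = 2))
  expect_true(all(locals > 0.5))
  pooledv <- cluster_temporal_change(sw, c(p1 = 1, p2 = 1))
  expect_equal(unname(pooledv), 0, tolerance = 1e-12)

  expect_error(cluster_temporal_change(fx$ptab,
                                       setNames(seq_len(n), rev(ids))[-1]),
               "missing")
})

test_that("the scan covers every grain with the right shapes", {
  fx <- scan_fixture()
  n <- fx$tree$n_leaves
  scan <- scan_all_scales(fx$ptab, fx$tree)
  expect_identical(names(scan$per_K), as.character(1:n))
  for (K in 1:n) expect_length(scan$per_K[[as.character(K)]], K)
  expect_identical(scan$summary$K, 1:n)
  expect_identical(scan$summary$n, scan$summary$K)

  # K = N equals the local paired dissimilarities
  D <- dissimilarity_matrix(fx$ptab)
  ids <- fx$tree$labels
  local <- paired_temporal_dissimilarity(
    D, data.frame(site_t1 = ids, site_t2 = ids))
  vN <- scan$per_K[[as.character(n)]]
  expect_equal(sort(unname(vN)), sort(unname(local)), tolerance = 1e-12)
})

test_that("bootstrap test gives exact p on degenerate inputs", {
  r1 <- discontinuity_bootstrap_test(rep(0.5, 10), 4, 0.5, B = 1000,
                                     seed = 3)
  expect_equal(r1$p_value, 1.0)
  r0 <- discontinuity_bootstrap_test(c(0.4, 0.6, 0.8), 2, 0.1, B = 1000,
                                     seed = 3)
  expect_equal(r0$p_value, 0.0)

  # two-point distribution, K = 1, observed at the lower point:
  # p -> P(draw = 0) = 0.5, within 3 Monte Carlo SEs at B = 1e5
  r5 <- discontinuity_bootstrap_test(c(0, 1), 1, 0, B = 100000, seed = 11)
  mc_se <- sqrt(0.5 * 0.5 / 100000)
  expect_lt(abs(r5$p_value - 0.5), 3 * mc_se)

  # bit-exact reproducibility under fixed seed and B
  r5b <- discontinuity_bootstrap_test(c(0, 1), 1, 0, B = 100000, seed = 11)
  expect_identical(r5$p_value, r5b$p_value)
  expect_identical(r5$boot_summary, r5b$boot_summary)

  # summary quantiles follow the linear-interpolation convention
  set.seed(11)
  means <- colMeans(matrix(sample(c(0, 1), 100000, replace = TRUE), 1))
  expect_equal(unname(r5$boot_summary),
               unname(quantile(means, c(0, .25, .5, .75, 1), type = 7)))

  expect_error(discontinuity_bootstrap_test(numeric(0), 1, 0), "empty")
  expect_error(discontinuity_bootstrap_test(c(0.1), 2, 0), "out of range")
})

test_that("scan-level testing nominates K and warns on multiplicity", {
  fx <- scan_fixture()
  scan <- scan_all_scales(fx$ptab, fx$tree)
  res <- test_scan_discontinuities(scan, 4, B = 2000, seed = 5)
  expect_named(res, "K4")
  expect_equal(res$K4$observed_mean, mean(scan$per_K[["4"]]))
  expect_gte(res$K4$p_value, 0)
  expect_lte(res$K4$p_value, 1)
  expect_warning(test_scan_discontinuities(scan, c(3, 4), B = 500, seed = 5),
                 "multiplicity")
})

test_that("domain locator finds the interior minimum of the mean", {
  fx <- scan_fixture()
  scan <- scan_all_scales(fx$ptab, fx$tree)
  K <- find_domain_scale(scan)
  s <- scan$summary
  interior <- s[s$K > 1 & s$K < max(s$K), ]
  expect_equal(K, interior$K[which.min(interior$mean)])
})
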