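test_that("the whole dataset is a pure function of the configuration", {
  d1 <- suppressWarnings(synthetic_dataset(small_config(5)))
  d2 <- suppressWarnings(synthetic_dataset(small_config(5)))
  expect_identical(unclass(d1$table), unclass(d2$table))
  expect_identical(d1$fluvial, d2$fluvial)
  expect_identical(d1$network$edges, d2$network$edges)
  d3 <- suppressWarnings(synthetic_dataset(small_config(6)))
  expect_false(identical(d1$network$edges$length_km,
                         d3$network$edges$length_km))
  expect_false(identical(unclass(d1$table), unclass(d3$table)))
})

test_that("the network is a dendritic tree with valid Strahler orders", {
  cfg <- small_config(3)
  net <- generate_network(cfg)
  # a tree: one fewer edge than nodes, connected
  expect_equal(nrow(net$edges), nrow(net$nodes) - 1)
  expect_true(igraph::is_connected(net$graph))
  # headwaters are order 1, and order rises downstream to the outlet
  hw <- net$nodes$strahler[net$nodes$kind == "headwater"]
  expect_true(all(hw == 1))
  expect_gte(net$nodes$strahler[net$nodes$node == "OUT"], 2)
  expect_true(all(net$sites$stream_order >= 1))

  # Strahler recursion on a hand-built balanced binary tree of depth 3:
  # root order must be 4 (each join of two equal orders increments)
  nodes <- data.frame(node = as.character(1:15))
  edges <- data.frame(from = as.character(rep(1:7, each = 2)),
                      to = as.character(2:15),
                      length_km = 1)
  ord <- scalescan:::strahler_orders(nodes, edges, root = "1")
  expect_equal(unname(ord["1"]), 4L)
  expect_true(all(ord[as.character(8:15)] == 1L))
})

test_that("fluvial distances form a tree metric dominating straight lines", {
  net <- generate_network(small_config(8))
  fl <- net$fluvial
  ids <- rownames(fl)
  set.seed(1)
  # four-point condition: the two largest of the three pair sums agree
  for (i in 1:25) {
    q <- sample(ids, 4)
    sums <- sort(c(fl[q[1], q[2]] + fl[q[3], q[4]],
                   fl[q[1], q[3]] + fl[q[2], q[4]],
                   fl[q[1], q[4]] + fl[q[2], q[3]]))
    expect_equal(sums[2], sums[3], tolerance = 1e-9)
  }
  # embedding contracts the tree: haversine <= fluvial for all site pairs
  s <- net$sites
  for (i in seq_len(nrow(s) - 1)) for (j in (i + 1):nrow(s)) {
    hv <- haversine_km(s$latitude[i], s$longitude[i],
                       s$latitude[j], s$longitude[j])
    expect_lte(hv, fl[s$site_id[i], s$site_id[j]] + 1e-6)
  }
})

test_that("occupancy decay moves the system between its two limits", {
  # decay 0: all species available everywhere -> high local richness,
  # low beta; huge decay: each species near one site -> high beta
  cfg0 <- small_config(2, occupancy_decay = 0)
  m0 <- suppressWarnings(simulate_metacommunity(generate_network(cfg0), cfg0))
  cfgI <- small_config(2, occupancy_decay = 5)
  mI <- suppressWarnings(simulate_metacommunity(generate_network(cfgI), cfgI))
  expect_true(all(colSums(m0$occupancy) == nrow(m0$occupancy)))
  rich0 <- mean(rowSums(unclass(m0$table) > 0))
  richI <- mean(rowSums(unclass(mI$table) > 0))
  expect_gt(rich0, richI)
  b0 <- partition_diversity(m0$table, "T1", 0)$beta
  bI <- partition_diversity(mI$table, "T1", 0)$beta
  expect_gt(bI, b0)
})

test_that("pooled abundances track the regional ranking", {
  rho <- vapply(1:10, function(s) {
    cfg <- small_config(s)
    meta <- suppressWarnings(
      simulate_metacommunity(generate_network(cfg), cfg))
    cor(colSums(unclass(meta$table)), meta$pool, method = "spearman")
  }, numeric(1))
  expect_gt(mean(rho), 0.8)
})

test_that("turnover behaves at its limits and grows with tau", {
  cfg <- small_config(4)
  net <- generate_network(cfg)
  meta <- suppressWarnings(simulate_metacommunity(net, cfg))

  t2_0 <- apply_turnover(meta$table, meta, 0, cfg)
  expect_equal(unclass(t2_0), unclass(meta$table), ignore_attr = TRUE)

  mean_local <- function(tau, seed) {
    t2 <- apply_turnover(meta$table, meta, tau, cfg, seed = seed)
    mean(vapply(seq_len(nrow(meta$table)), function(i)
      morisita_horn(unclass(meta$table)[i, ], unclass(t2)[i, ]),
      numeric(1)))
  }
  taus <- c(0, 0.25, 0.5, 0.75, 1)
  curve <- vapply(taus, function(tau)
    mean(vapply(1:5, function(s) mean_local(tau, 100 + s), numeric(1))),
    numeric(1))
  expect_true(all(diff(curve) > -0.02))  # nondecreasing up to noise
  expect_gt(curve[5], curve[1] + 0.2)
})

test_that("datasets write to disk in the formats the pipeline reads", {
  ds <- suppressWarnings(synthetic_dataset(small_config(7)))
  dir <- withr::local_tempdir()
  write_synthetic_dataset(ds, dir)
  tab <- read_abundance_table(file.path(dir, "abundance.csv"), "long")
  expect_equal(sum(unclass(tab)), sum(unclass(ds$table)))
  sites <- read_site_table(file.path(dir, "sites.csv"))
  expect_setequal(unique(sites$site_id), ds$network$sites$site_id)
  fl <- read_fluvial_matrix(file.path(dir, "fluvial_km.csv"))
  expect_equal(fl, ds$fluvial, tolerance = 1e-9)
  phy <- ape::read.tree(file.path(dir, "network.nwk"))
  expect_s3_class(phy, "phylo")
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$config$seed, 7)
})
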