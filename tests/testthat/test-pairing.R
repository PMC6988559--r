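test_that("haversine distance matches the closed-form arc length", {
  expect_equal(haversine_km(35, -96, 35, -96), 0)
  expect_equal(haversine_km(0, 0, 1, 0), 6371.0088 * pi / 180,
               tolerance = 1e-6)
  set.seed(4)
  for (i in 1:10) {
    a <- runif(2, -60, 60); b <- runif(2, -60, 60)
    expect_equal(haversine_km(a[1], a[2], b[1], b[2]),
                 haversine_km(b[1], b[2], a[1], a[2]))
  }
  expect_error(haversine_km(95, 0, 0, 0), "out of range")
})

# three historical sites on a line; two resurvey sites nearest to the
# same historical site. Hand-enumerated greedy outcome: the closer
# conflicting pair wins, the loser takes its next-nearest eligible site.
conflict_fixture <- function() {
  t1 <- data.frame(site_id = c("a", "b", "c"),
                   latitude = c(35.00, 35.05, 35.10),
                   longitude = -96, stream_order = c(2, 2, 2))
  t2 <- data.frame(site_id = c("x", "y"),
                   latitude = c(35.001, 35.002),
                   longitude = -96, stream_order = c(2, 2))
  ids <- c(t1$site_id, t2$site_id)
  fl <- matrix(0, 5, 5, dimnames = list(ids, ids))
  km <- function(i, j, v) fl[i, j] <<- fl[j, i] <<- v
  km("a", "b", 6); km("a", "c", 12); km("b", "c", 6)
  km("a", "x", 1); km("a", "y", 2)   # both nearest to a
  km("b", "x", 5); km("b", "y", 4)
  km("c", "x", 11); km("c", "y", 10)
  list(t1 = t1, t2 = t2, fl = fl)
}

test_that("greedy one-to-one matching resolves conflicts by ascending
           fluvial distance", {
  fx <- conflict_fixture()
  p <- match_sites(fx$t1, fx$t2, fx$fl)
  p <- p[order(p$site_t2), ]
  expect_equal(p$site_t1[p$site_t2 == "x"], "a")  # 1 km beats 2 km
  expect_equal(p$site_t1[p$site_t2 == "y"], "b")  # displaced to next best
  expect_true(all(p$straight_km < 8))

  # input order must not matter
  p2 <- match_sites(fx$t1[c(3, 1, 2), ], fx$t2[c(2, 1), ], fx$fl)
  expect_equal(p2[order(p2$site_t2), c("site_t1", "site_t2")],
               p[, c("site_t1", "site_t2")], ignore_attr = TRUE)

  # many-to-one keeps the literal nearest for both
  p3 <- match_sites(fx$t1, fx$t2, fx$fl, one_to_one = FALSE)
  expect_equal(sort(p3$site_t1), c("a", "a"))
})

test_that("pairing filters drop by stream order and straight distance", {
  fx <- conflict_fixture()
  t1 <- fx$t1; t1$stream_order <- c(3, 2, 2)  # nearest now ineligible
  p <- match_sites(t1, fx$t2, fx$fl)
  expect_false("a" %in% p$site_t1)
  expect_equal(sort(p$site_t1), c("b"), ignore_attr = TRUE)
  # with no eligible alternative at all, the site goes unpaired
  t1b <- fx$t1; t1b$stream_order <- c(3, 3, 3)
  expect_warning(p0 <- match_sites(t1b, fx$t2, fx$fl), "no site pairs")
  expect_equal(nrow(p0), 0)

  # far-apart coordinates fail the straight-line rule
  t1c <- fx$t1; t1c$latitude <- t1c$latitude + 1
  expect_warning(pfar <- match_sites(t1c, fx$t2, fx$fl))
  expect_equal(nrow(pfar), 0)

  # fully relaxed filters pair every resurveyed site
  pall <- match_sites(t1b, fx$t2, fx$fl, max_straight_km = Inf,
                      require_same_order = FALSE, one_to_one = FALSE)
  expect_setequal(pall$site_t2, fx$t2$site_id)

  # exact matches are flagged by zero fluvial distance
  fl0 <- fx$fl; fl0["a", "x"] <- fl0["x", "a"] <- 0
  pe <- match_sites(fx$t1, fx$t2, fl0)
  expect_true(pe$exact_match[pe$site_t2 == "x"])
})

test_that("pair abundance table re-keys the right surveys", {
  tab <- toy_table()
  pairs <- data.frame(site_t1 = c("s1", "s2"), site_t2 = c("s2", "s1"))
  ptab <- pair_abundance_table(tab, pairs)
  m <- unclass(tab); pm <- unclass(ptab)
  expect_equal(unname(pm["s1~s2|T1", ]), unname(m["s1|T1", ]))
  expect_equal(unname(pm["s1~s2|T2", ]), unname(m["s2|T2", ]))
  expect_error(pair_abundance_table(
    tab, data.frame(site_t1 = "nope", site_t2 = "s1")), "nope")
})
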