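test_that("long and wide dialects read, validate and round-trip", {
  tab <- toy_table()
  for (dialect in c("long", "wide")) {
    f <- withr::local_tempfile(fileext = ".csv")
    write_abundance_table(tab, f, dialect)
    back <- read_abundance_table(f, dialect)
    expect_equal(unclass(back)[, colnames(tab)], unclass(tab),
                 ignore_attr = TRUE)
    expect_equal(ab_sites(back), ab_sites(tab))
    expect_equal(ab_periods(back), ab_periods(tab))
  }

  # long construction and wide fill rule
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site_id,period,species,count",
               "s1,T1,spA,3", "s1,T1,spB,1", "s2,T1,spA,2"), f)
  tab <- read_abundance_table(f, "long")
  expect_equal(unname(unclass(tab)["s1|T1", c("spA", "spB")]), c(3, 1))
  expect_equal(unname(unclass(tab)["s2|T1", "spB"]), 0)

  w <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site_id,period,spA,spB", "s1,T1,2,", "s2,T1,1,3"), w)
  wt <- read_abundance_table(w, "wide")
  expect_equal(unname(unclass(wt)["s1|T1", "spB"]), 0)
})

test_that("invalid records are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site_id,period,species,count", "s1,T1,spA,-2"), f)
  expect_error(read_abundance_table(f, "long"), "spA")

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site_id,period,species,count",
               "s1,T1,spA,1", "s1,T1,spA,2"), g)
  expect_error(read_abundance_table(g, "long"), "duplicate")

  m <- matrix(c(1, 2), 1, 2, dimnames = list(NULL, c("a", "a")))
  expect_error(abundance_table(m, "s1", "T1"), "duplicate species")
  m2 <- matrix(1.5, 1, 1, dimnames = list(NULL, "a"))
  expect_error(abundance_table(m2, "s1", "T1"), "invalid count")
  m3 <- matrix(0, 1, 1, dimnames = list(NULL, "a"))
  expect_error(abundance_table(m3, "s1", "T1"), "no individuals")
})

test_that("taxon harmonization merges, renames, and conserves totals", {
  m <- cbind("Campostoma anomalum" = c(4, 1), "Campostoma spadiceum" = c(2, 0),
             "Notropis rubellus" = c(3, 2), "Notropis suttkusi" = c(1, 1),
             "Fundulus notatus" = c(0, 5))
  tab <- abundance_table(m, c("s1", "s2"), c("T1", "T1"))
  out <- suppressMessages(harmonize_taxa(tab))
  expect_equal(unname(unclass(out)[, "Campostoma spp."]), c(6, 1))
  # rename onto an existing column behaves as an implicit merge
  expect_equal(unname(unclass(out)[, "Notropis suttkusi"]), c(4, 3))
  expect_false("Notropis rubellus" %in% colnames(out))
  expect_equal(rowSums(unclass(out)), rowSums(unclass(tab)),
               ignore_attr = TRUE)

  # empty map is the identity; chained maps are rejected
  empty <- data.frame(source = character(0), target = character(0),
                      kind = character(0))
  expect_equal(unclass(harmonize_taxa(tab, empty)), unclass(tab),
               ignore_attr = TRUE)
  chained <- data.frame(source = c("a", "b"), target = c("b", "c"),
                        kind = "merge")
  expect_error(harmonize_taxa(tab, chained), "chained")
})

test_that("pooling sums member sites and conserves totals per period", {
  tab <- toy_table()
  pooled <- pool_sites(tab, c(s1 = "g", s2 = "g"))
  expect_equal(unname(unclass(pooled)["g|T1", ]), c(5, 7, 4, 2))
  expect_equal(nrow(pooled), 2)
  for (p in c("T1", "T2"))
    expect_equal(sum(unclass(subset_period(pooled, p))),
                 sum(unclass(subset_period(tab, p))))

  # identity grouping is a no-op up to row keys
  ident <- pool_sites(tab, c(s1 = "s1", s2 = "s2"))
  expect_equal(unclass(ident)[rownames(tab), ], unclass(tab),
               ignore_attr = TRUE)

  expect_error(pool_sites(tab, c(s1 = "g")), "s2")
})

test_that("presence/absence transform is binary and idempotent", {
  tab <- toy_table()
  pa <- to_presence_absence(tab)
  expect_true(all(unclass(pa) %in% c(0, 1)))
  expect_equal(unclass(pa), (unclass(tab) > 0) * 1, ignore_attr = TRUE)
  expect_equal(unclass(to_presence_absence(pa)), unclass(pa),
               ignore_attr = TRUE)
})
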