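test_that("panel CSV round-trips through write and load", {
  set.seed(42)
  gen <- generate_frontier_panel(frontier_spec(n_units = 31, n_years = 11,
                                               seed = 42))
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel_csv(gen$panel, path)
  lp <- load_panel(path)
  expect_equal(lp$panel$units, gen$panel$units)
  expect_equal(lp$panel$years, gen$panel$years)
  # variable rows are renamed to the schema roles; the values round-trip
  expect_equal(lp$panel$x, gen$panel$x, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(lp$panel$y, gen$panel$y, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(lp$panel$u, gen$panel$u, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(length(lp$panel$units), 31L)
  expect_equal(length(lp$panel$years), 11L)
})

test_that("loader reports missing schema columns and duplicate rows", {
  set.seed(1)
  gen <- generate_frontier_panel(frontier_spec(n_units = 4, n_years = 2,
                                               seed = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel_csv(gen$panel, path)
  d <- read.csv(path, check.names = FALSE)
  d$B_m <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(d, path2, row.names = FALSE)
  expect_error(load_panel(path2), "B_m")
  d2 <- read.csv(path, check.names = FALSE)
  d2 <- rbind(d2, d2[1, ])
  write.csv(d2, path2, row.names = FALSE)
  expect_error(load_panel(path2), "duplicate")
})

test_that("perinatal survival is the mortality complement on [0, 1]", {
  expect_identical(perinatal_survival(0), 1)
  expect_equal(perinatal_survival(0.012), 0.988)
  expect_equal(perinatal_survival(0.240), 0.760)
  expect_error(perinatal_survival(1.2), "\\[0, 1\\]")
  expect_error(perinatal_survival(-0.1), "\\[0, 1\\]")
})

test_that("gap completion: linear interior, nearest edge, idempotent", {
  expect_equal(interpolate_missing(c(1, NA, 3)), c(1, 2, 3))
  expect_equal(interpolate_missing(c(NA, 2, 4)), c(2, 2, 4))
  expect_equal(interpolate_missing(c(1, NA, NA, 7, NA)), c(1, 3, 5, 7, 7))
  x <- c(2.5, 3.5, 1)
  expect_identical(interpolate_missing(x), x)
  once <- interpolate_missing(c(NA, 1, NA, 5))
  expect_identical(interpolate_missing(once), once)
  expect_error(interpolate_missing(c(NA_real_, NA_real_)), "all-missing")
})

test_that("region scheme is a total partition with the printed sizes", {
  tab <- fixture_table3()
  reg <- assign_regions(rownames(tab$scores))
  expect_equal(unname(table(reg)[c("Eastern", "Middle", "Western",
                                   "Northeastern")]),
               c(10L, 6L, 12L, 3L), ignore_attr = TRUE)
  expect_equal(unname(reg["GuangDong"]), "Eastern")
  expect_equal(unname(reg["JiLin"]), "Northeastern")
  expect_error(assign_regions(c("BeiJing", "Atlantis")), "Atlantis")
})

test_that("regional aggregation is unweighted and partition-consistent", {
  tab <- fixture_table3()
  ag <- aggregate_regional(tab, stat = "mean")
  # national mean equals the size-weighted mean of regional means
  sizes <- table(unname(tab$regions))
  for (yr in colnames(tab$scores)) {
    rm <- ag[ag$year == yr, ]
    wmean <- sum(rm$value * as.numeric(sizes[rm$region])) / sum(sizes)
    expect_equal(wmean, mean(tab$scores[, yr]), tolerance = 1e-12)
  }
  # single-unit region returns that unit's value
  one <- efficiency_table(matrix(c(2, 3), 2, 1,
                                 dimnames = list(c("a", "b"), "2001")),
                          regions = c(a = "R1", b = "R2"))
  ag1 <- aggregate_regional(one, stat = "mean", year = "2001")
  expect_equal(ag1$value[ag1$region == "R2"], 3)
  expect_error(aggregate_regional(efficiency_table(
    matrix(1, 1, 1, dimnames = list("a", "2001")))), "no region scheme")
})

test_that("efficiency bands use the printed half-open intervals and the
           grades refine them", {
  g <- grade_efficiency(c(0.80, 1.00, 1.01, 0.3))
  expect_equal(as.character(g$band), c("low", "medium", "high", "low"))
  expect_error(grade_efficiency(0), "> 0")
  # each grade maps into exactly one band
  v <- seq(0.05, 1.6, by = 0.01)
  gg <- grade_efficiency(v)
  crossing <- tapply(as.character(gg$band), gg$grade,
                     function(b) length(unique(b)))
  expect_true(all(crossing == 1))
  expect_equal(sort(unique(gg$grade)), 1:8)
})
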