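make_const_cube <- function(value = 20, years = 1961:1963) {
  synthesizeCube(lon_range = c(0, 5), lat_range = c(0, 5), cell_size = 1,
                 years = years, tmax_baseline = value, tmax_amplitude = 0,
                 tmax_gradient = 0, tmax_sd = 0, ppt_sd = 0, pet_sd = 0,
                 ppt_baseline = 50, pet_baseline = 100)
}

test_that("cell selection counts centers in polygons and dedupes points", {
  cube <- make_const_cube()
  # square exactly covering a 3x3 block of cell centers
  g <- SpeciesGeometry("Testus alpha", polygons = data.frame(
    lon = c(0, 3, 3, 0), lat = c(0, 0, 3, 3)))
  expect_length(cellsForGeometry(g, cube), 9L)

  # two points in the same cell select one cell
  g2 <- SpeciesGeometry("Testus alpha",
                        points = data.frame(lon = c(1.2, 1.4), lat = c(2.2, 2.3)))
  expect_length(cellsForGeometry(g2, cube), 1L)

  # geometry entirely outside the extent errors, naming the extent
  g3 <- SpeciesGeometry("Testus alpha", polygons = data.frame(
    lon = c(0, 3, 3, 0), lat = c(-10, -10, -7, -7)))
  expect_error(cellsForGeometry(g3, cube), "extent")
})

test_that("limits on a constant field are the constant; enumerated pools give min/max", {
  cube <- make_const_cube(20)
  g <- SpeciesGeometry("Testus alpha",
                       points = data.frame(lon = 0.5, lat = 0.5))
  lim <- estimateLimits(g, cube, period = c(1961, 1963))
  df <- limitsData(lim)
  tdf <- df[df$variable == "temperature", ]
  expect_equal(nrow(df), 24L)
  expect_equal(tdf$lower, rep(20, 12))
  expect_equal(tdf$upper, rep(20, 12))
  adf <- df[df$variable == "aridity", ]
  expect_equal(adf$lower, rep(0.5, 12))  # 50 mm / 100 mm

  # month-7 pool exactly {5, 10, 30} across three years -> (5, 30) at q = 0
  tmax <- SummarizedExperiment::assay(cube, "tmax")
  tm <- cubeTime(cube)
  cell <- 1L
  tmax[cell, which(tm$month == 7)] <- c(5, 10, 30)
  cube2 <- ClimateCube(tmax, SummarizedExperiment::assay(cube, "ppt"),
                       SummarizedExperiment::assay(cube, "pet"),
                       lon = cellCoords(cube)$lon, lat = cellCoords(cube)$lat,
                       year = tm$year, month = tm$month,
                       cell_size = cellSize(cube))
  df2 <- limitsData(estimateLimits(g, cube2, period = c(1961, 1963)))
  july <- df2[df2$variable == "temperature" & df2$month == 7, ]
  expect_equal(c(july$lower, july$upper), c(5, 30))
})

test_that("q = 0 estimates equal a brute-force pooled min/max oracle", {
  w <- tiny_world
  tm <- cubeTime(w$cube)
  yrs <- range(w$spec$years)
  for (g in w$geometries) {
    cells <- cellsForGeometry(g, w$cube)
    est <- limitsData(estimateLimits(g, w$cube, period = yrs))
    tmax <- SummarizedExperiment::assay(w$cube, "tmax")[cells, , drop = FALSE]
    ai <- SummarizedExperiment::assay(w$cube, "ppt")[cells, , drop = FALSE] /
      SummarizedExperiment::assay(w$cube, "pet")[cells, , drop = FALSE]
    for (m in 1:12) {
      pool_t <- as.numeric(tmax[, tm$month == m])
      pool_a <- as.numeric(ai[, tm$month == m])
      et <- est[est$variable == "temperature" & est$month == m, ]
      ea <- est[est$variable == "aridity" & est$month == m, ]
      expect_identical(c(et$lower, et$upper), c(min(pool_t), max(pool_t)))
      expect_identical(c(ea$lower, ea$upper), c(min(pool_a), max(pool_a)))
    }
  }
})

test_that("wider tail quantiles give nested, narrower intervals", {
  w <- tiny_world
  g <- w$geometries[[1]]
  qs <- c(0, 0.01, 0.05, 0.1)
  ests <- lapply(qs, function(q)
    limitsData(estimateLimits(g, w$cube, period = range(w$spec$years), q = q)))
  for (i in seq_along(qs)[-1]) {
    expect_true(all(ests[[i]]$lower >= ests[[i - 1]]$lower))
    expect_true(all(ests[[i]]$upper <= ests[[i - 1]]$upper))
  }
})

test_that("adding years never narrows q = 0 limits", {
  w <- tiny_world
  g <- w$geometries[[2]]
  short <- limitsData(estimateLimits(g, w$cube, period = c(1961, 1961)))
  long <- limitsData(estimateLimits(g, w$cube, period = c(1961, 1963)))
  expect_true(all(long$lower <= short$lower))
  expect_true(all(long$upper >= short$upper))
})

test_that("period outside the cube's years is rejected", {
  w <- tiny_world
  expect_error(estimateLimits(w$geometries[[1]], w$cube, period = c(1950, 1963)),
               "outside cube years")
})

test_that("year-average limits are arithmetic means, with skip-and-warn on gaps", {
  tab <- NicheLimitTable(data.frame(
    species = "Testus alpha", month = 1:12, variable = "temperature",
    lower = 1:12, upper = 21:32))
  avg <- limitsData(yearAverageLimits(tab))
  expect_equal(avg$month, 0L)
  expect_equal(avg$lower, 6.5)
  expect_equal(avg$upper, 26.5)

  # constant (0, 10) with one missing month still averages to (0, 10), warning
  df <- data.frame(species = "Testus alpha", month = 1:12,
                   variable = "temperature", lower = 0, upper = 10)
  df$lower[5] <- df$upper[5] <- NA
  expect_warning(avg2 <- limitsData(yearAverageLimits(NicheLimitTable(df))),
                 "skipping")
  expect_equal(c(avg2$lower, avg2$upper), c(0, 10))

  # all months missing is an error
  df$lower <- df$upper <- NA_real_
  expect_error(suppressWarnings(yearAverageLimits(NicheLimitTable(df))),
               "all monthly limits missing")
})

test_that("limit tables enforce their invariants and round-trip through CSV", {
  expect_error(NicheLimitTable(data.frame(
    species = "Testus alpha", month = 1, variable = "temperature",
    lower = 5, upper = 2)), "lower > upper")
  expect_error(NicheLimitTable(data.frame(
    species = "Testus alpha", month = 13, variable = "temperature",
    lower = 1, upper = 2)), "month")
  expect_error(NicheLimitTable(data.frame(
    species = rep("Testus alpha", 2), month = 1, variable = "temperature",
    lower = 1, upper = 2)), "duplicate")

  tab <- speciesLimits(toy_limits(), "Testus alpha", yr_avg = TRUE)
  f <- withr::local_tempfile(fileext = ".csv")
  writeLimits(tab, f)
  back <- readLimits(f)
  expect_equal(limitsData(back), limitsData(tab))
  expect_equal(provenance(back)$quantile, provenance(tab)$quantile)
})
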