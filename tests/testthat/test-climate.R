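test_that("temperature conversion handles C, F, K and rejects bad units", {
  expect_equal(toCelsius(32, "F"), 0)
  expect_equal(toCelsius(273.15, "K"), 0)
  expect_equal(toCelsius(25, "C"), 25)
  expect_error(toCelsius(10, "R"), "accepted units")
  expect_error(toCelsius(-1, "K"), ">= 0")

  # round trip through each unit is exact to 1e-9
  from_c <- list(C = identity, F = function(v) v * 9 / 5 + 32,
                 K = function(v) v + 273.15)
  v <- seq(-40, 45, by = 0.5)
  for (u in names(from_c)) {
    expect_equal(toCelsius(from_c[[u]](v), u), v, tolerance = 1e-9)
  }
})

test_that("aridity index guards division by zero and caps only when asked", {
  expect_equal(aridityIndex(60, 120), data.frame(ai = 0.5, flag = "ok"))
  r0 <- aridityIndex(100, 0)
  expect_true(is.na(r0$ai))
  expect_equal(r0$flag, "undefined")

  # capped value is the cap; the unclamped oracle is the raw ratio
  rc <- aridityIndex(500, 1, cap = 10)
  expect_equal(rc$ai, 10)
  expect_equal(rc$flag, "capped")
  expect_equal(aridityIndex(500, 1)$ai, 500 / 1)

  # no cap: extreme threshold flags but does not alter
  re <- aridityIndex(500, 1, extreme = 100)
  expect_equal(re$ai, 500)
  expect_equal(re$flag, "extreme")

  expect_error(aridityIndex(-1, 10), "non-negative")
})

test_that("aridity index is scale-invariant", {
  set.seed(11)
  ppt <- runif(50, 0, 300)
  pet <- runif(50, 1, 200)
  base <- aridityIndex(ppt, pet)$ai
  for (k in c(0.01, 0.5, 7, 1000)) {
    expect_equal(aridityIndex(k * ppt, k * pet)$ai, base, tolerance = 1e-12)
  }
})

test_that("synthetic cube: degenerate settings give a closed-form surface", {
  cube <- synthesizeCube(lon_range = c(0, 5), lat_range = c(0, 4),
                         cell_size = 1, years = 1961:1962,
                         tmax_baseline = 20, tmax_amplitude = 0,
                         tmax_gradient = 0, tmax_sd = 0,
                         ppt_sd = 0, pet_sd = 0)
  expect_true(all(SummarizedExperiment::assay(cube, "tmax") == 20))
  expect_equal(dim(cube), c(20L, 24L))

  # with a gradient and amplitude the surface is exact cell by cell
  cube2 <- synthesizeCube(lon_range = c(0, 2), lat_range = c(0, 3),
                          cell_size = 1, years = 1961,
                          tmax_baseline = 10, tmax_amplitude = 5,
                          tmax_gradient = -0.5, tmax_sd = 0,
                          ppt_sd = 0, pet_sd = 0)
  cc <- cellCoords(cube2)
  tm <- cubeTime(cube2)
  expected <- outer(10 - 0.5 * cc$lat, 5 * cospi(2 * (tm$month - 7) / 12), `+`)
  expect_equal(unname(SummarizedExperiment::assay(cube2, "tmax")), expected)
})

test_that("synthetic cube is seed-reproducible and respects noise statistics", {
  a <- synthesizeCube(lon_range = c(0, 10), lat_range = c(0, 10), seed = 99,
                      years = 1961:1962)
  b <- synthesizeCube(lon_range = c(0, 10), lat_range = c(0, 10), seed = 99,
                      years = 1961:1962)
  expect_identical(SummarizedExperiment::assay(a, "tmax"),
                   SummarizedExperiment::assay(b, "tmax"))

  # CLT check: 1000+ cells at sd=1, sample mean within 3 standard errors
  big <- synthesizeCube(lon_range = c(0, 40), lat_range = c(0, 25),
                        cell_size = 1, years = 1961,
                        tmax_baseline = 20, tmax_amplitude = 0,
                        tmax_gradient = 0, tmax_sd = 1,
                        ppt_sd = 0, pet_sd = 0, seed = 5)
  jan <- SummarizedExperiment::assay(big, "tmax")[, 1]
  expect_gt(length(jan), 999)
  expect_lt(abs(mean(jan) - 20), 3 / sqrt(length(jan)))
})

test_that("ppt stays non-negative and pet respects its floor", {
  cube <- synthesizeCube(lon_range = c(0, 10), lat_range = c(0, 10),
                         years = 1961, ppt_baseline = 5, ppt_sd = 50,
                         pet_baseline = 1, pet_sd = 50, pet_floor = 0.25,
                         seed = 3)
  expect_true(all(SummarizedExperiment::assay(cube, "ppt") >= 0))
  expect_true(all(SummarizedExperiment::assay(cube, "pet") >= 0.25))
})

test_that("cube constructor enforces its invariants", {
  m <- matrix(1, 2, 2)
  expect_error(ClimateCube(m, m, matrix(1, 2, 3), lon = c(0.5, 1.5),
                           lat = c(0.5, 0.5), year = c(1961, 1961),
                           month = c(1, 2), cell_size = 1),
               "identical dimensions")
  expect_error(ClimateCube(m, -m, m, lon = c(0.5, 1.5), lat = c(0.5, 0.5),
                           year = c(1961, 1961), month = c(1, 2),
                           cell_size = 1),
               "non-negative")
  expect_error(ClimateCube(m, m, m, lon = c(0.5, 1.5), lat = c(0.5, 0.5),
                           year = c(1961, 1961), month = c(2, 1),
                           cell_size = 1),
               "strictly increasing")
  expect_error(ClimateCube(m, m, m, lon = c(0.5, 1.7), lat = c(0.5, 0.5),
                           year = c(1961, 1961), month = c(1, 2),
                           cell_size = 1),
               "lattice")
})

test_that("cube round-trips losslessly through plain-text serialization", {
  cube <- synthesizeCube(lon_range = c(0, 3), lat_range = c(0, 2),
                         cell_size = 1, years = 1961:1962, seed = 8)
  d <- withr::local_tempdir()
  writeCube(cube, d)
  back <- readCube(d)
  for (v in c("tmax", "ppt", "pet")) {
    expect_equal(SummarizedExperiment::assay(back, v),
                 unname(SummarizedExperiment::assay(cube, v)))
  }
  expect_equal(cellCoords(back), cellCoords(cube))
  expect_equal(cubeTime(back), cubeTime(cube))
  expect_equal(cellSize(back), cellSize(cube))

  # missing PET file fails fast at read time
  file.remove(file.path(d, "pet.csv"))
  expect_error(readCube(d), "pet")
})

test_that("reading a cube with a mismatched grid names the offending variable", {
  cube <- synthesizeCube(lon_range = c(0, 2), lat_range = c(0, 2),
                         cell_size = 1, years = 1961, seed = 8)
  d <- withr::local_tempdir()
  writeCube(cube, d)
  ppt <- read.csv(file.path(d, "ppt.csv"))
  ppt$lon <- ppt$lon * 2  # different cell layout
  write.csv(ppt, file.path(d, "ppt.csv"), row.names = FALSE)
  expect_error(readCube(d), "'ppt'")
})
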