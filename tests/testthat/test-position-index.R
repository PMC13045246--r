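test_that("position index anchors at the limits and is linear between them", {
  expect_equal(positionIndex(10, 10, 30), 0)
  expect_equal(positionIndex(30, 10, 30), 1)
  expect_equal(positionIndex(20, 10, 30), 0.5)
  expect_equal(positionIndex(35, 10, 30), 1.25)  # (35 - 10) / 20, beyond niche
  expect_true(is.na(positionIndex(5, 10, 10)))   # degenerate limits

  # strictly increasing in value when upper > lower
  v <- seq(-5, 25, by = 0.5)
  expect_true(all(diff(positionIndex(v, 0, 20)) > 0))
})

test_that("position index is affine-invariant", {
  set.seed(21)
  value <- runif(200, -10, 40)
  lower <- runif(200, -10, 10)
  upper <- lower + runif(200, 0.5, 30)
  base <- positionIndex(value, lower, upper)
  for (tr in list(c(a = 9 / 5, b = 32), c(a = 1, b = 273.15), c(a = -2, b = 7))) {
    shifted <- positionIndex(tr["a"] * value + tr["b"],
                             tr["a"] * lower + tr["b"],
                             tr["a"] * upper + tr["b"])
    expect_equal(shifted, base, tolerance = 1e-12)
  }
})

test_that("averaging monthly indices equals the one-pass computation", {
  set.seed(22)
  for (i in 1:20) {
    lower <- runif(12, 0, 10)
    upper <- lower + runif(12, 1, 10)
    value <- runif(12, lower, upper)
    monthly <- positionIndex(value, lower, upper)
    two_route <- averagePI(monthly)
    one_pass <- sum((value - lower) / (upper - lower)) / 12
    expect_equal(two_route$pi, one_pass, tolerance = 1e-12)
    expect_equal(two_route$n, 12L)
  }
  expect_equal(averagePI(c(0, 1)), list(pi = 0.5, n = 2L))
  expect_warning(r <- averagePI(c(NA, NA)), "no non-missing")
  expect_true(is.na(r$pi))
})

test_that("tpi joins on species x month, converts units, and flags failures", {
  lim <- toy_limits()
  obs <- data.frame(species = c("Testus alpha", "Testus alpha", "Testus alpha"),
                    month = c(6, 13, 6),
                    temperature = c(0, 5, NA))
  r <- tpi(obs, lim)
  expect_equal(nrow(r), 3L)
  expect_equal(r$pi[1], 0)  # value at the lower limit
  expect_true(r$bad_month[2] && is.na(r$pi[2]))
  expect_true(r$bad_value[3] && is.na(r$pi[3]))

  # 32 F against (0, 10) C limits anchors at 0
  rF <- tpi(data.frame(species = "Testus alpha", month = 6, temperature = 32),
            lim, tmp_unit = "F")
  expect_equal(rF$pi, 0)
  expect_error(tpi(obs, lim, tmp_unit = "X"), "accepted units")

  # unknown species flags bad_binomial; a synonym map rescues it
  r2 <- tpi(data.frame(species = "Parus alpha", month = 6, temperature = 5), lim)
  expect_true(r2$bad_binomial)
  sm <- SynonymMap(data.frame(accepted = "Testus alpha",
                              synonym = "Parus alpha"))
  expect_message(
    r3 <- tpi(data.frame(species = "Parus alpha", month = 6, temperature = 5),
              lim, synonyms = sm),
    "resolved")
  expect_equal(r3$pi, 0.5)
  expect_false(r3$bad_binomial)
})

test_that("api flags impossible aridity and keeps out-of-range indices", {
  lim <- toy_limits()
  obs <- data.frame(species = "Testus alpha", month = c(3, 3, 3),
                    aridity = c(1.2, -0.2, 1.7))
  r <- api(obs, lim)
  expect_equal(r$pi[1], 1)  # at the upper limit
  expect_true(r$bad_value[2] && is.na(r$pi[2]))
  expect_equal(r$pi[3], 1.5)  # (1.7 - 0.2) / 1.0, retained
  expect_true(r$out_of_range[3])
})

test_that("degenerate limits flag instead of producing infinities", {
  lim <- NicheLimitTable(data.frame(
    species = "Testus alpha", month = 1:12, variable = "temperature",
    lower = 5, upper = 5))
  r <- tpi(data.frame(species = "Testus alpha", month = 2, temperature = 5), lim)
  expect_true(r$degenerate_limits)
  expect_true(is.na(r$pi))
  expect_false(any(is.infinite(r$pi)))
})

test_that("rows are conserved with flags on; unscorable rows drop with flags off", {
  lim <- toy_limits()
  obs <- data.frame(species = c("Testus alpha", "Nullus nullus", "Testus beta"),
                    month = c(1, 1, 13),
                    temperature = c(5, 5, 5))
  on <- tpi(obs, lim, emit_flags = TRUE)
  expect_equal(nrow(on), 3L)
  flag_cols <- c("bad_binomial", "bad_month", "bad_value", "degenerate_limits")
  blocked <- Reduce(`|`, lapply(flag_cols, function(f) on[[f]]))
  expect_true(all(xor(is.na(on$pi), !blocked)))  # pi xor blocking flag

  off <- tpi(obs, lim, emit_flags = FALSE)
  expect_equal(nrow(off), 1L)
  expect_false(any(flag_cols %in% colnames(off)))
  expect_equal(off$species, "Testus alpha")
})

test_that("multi-column measurements average per-column indices", {
  lim <- toy_limits()
  obs <- data.frame(species = "Testus alpha", month = 1,
                    t1 = 0, t2 = 10, t3 = NA)
  r <- tpi(obs, lim, tmp_var = c("t1", "t2", "t3"))
  expect_equal(r$pi, 0.5)  # mean of 0 and 1, NA column skipped
  expect_false(r$bad_value)
  # all columns missing is bad_value
  r2 <- tpi(data.frame(species = "Testus alpha", month = 1,
                       t1 = NA, t2 = NA), lim, tmp_var = c("t1", "t2"))
  expect_true(r2$bad_value)
})

test_that("Fahrenheit and Kelvin observations reproduce the Celsius indices", {
  w <- full_world
  obs <- w$observations
  ok <- !is.na(obs$temperature)
  base <- suppressMessages(tpi(obs, w$limits, synonyms = w$synonyms))
  obsF <- obs; obsF$temperature <- obs$temperature * 9 / 5 + 32
  obsK <- obs; obsK$temperature <- obs$temperature + 273.15
  rF <- suppressMessages(tpi(obsF, w$limits, tmp_unit = "F", synonyms = w$synonyms))
  rK <- suppressMessages(tpi(obsK, w$limits, tmp_unit = "K", synonyms = w$synonyms))
  expect_equal(rF$pi[ok], base$pi[ok], tolerance = 1e-9)
  expect_equal(rK$pi[ok], base$pi[ok], tolerance = 1e-9)
})
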