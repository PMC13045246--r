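# shared fixtures, built once per test run

# small world for unit tests: 4 species, 3 years
tiny_world <- makeWorld(worldSpec(n_species = 4, years = 1961:1963, seed = 42))

# full-size world under the default study conditions (20 species, 1961-1975)
full_world <- makeWorld(worldSpec(seed = 1))

# hand-built limit table: two species, both variables, all 12 months
toy_limits <- function() {
  NicheLimitTable(data.frame(
    class = rep(c("Aclass", "Bclass"), each = 24),
    order = "Anorder", family = rep(c("Afam", "Bfam"), each = 24),
    species = rep(c("Testus alpha", "Testus beta"), each = 24),
    month = rep(1:12, 4),
    variable = rep(rep(c("temperature", "aridity"), each = 12), 2),
    lower = rep(rep(c(0, 0.2), each = 12), 2),
    upper = rep(rep(c(10, 1.2), each = 12), 2)))
}

expect_flag_match <- function(result, truth, prefix) {
  for (f in c("bad_binomial", "bad_month", "bad_value",
              "degenerate_limits", "out_of_range")) {
    expect_identical(result[[f]], truth[[paste0(prefix, "_", f)]],
                     label = paste(prefix, f))
  }
}
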