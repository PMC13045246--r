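#' Specification of a synthetic species world
#'
#' Describes the synthetic world used for testing and validation: how many
#' species, the per-species block of grid cells each occupies, the span of
#' years, the ranges the true monthly temperature and aridity envelopes are
#' drawn from, and the observation sampling rule. With a fixed seed the
#' whole world — climate, geometries, limits, observations, ground truth —
#' is byte-identical across runs.
#'
#' Species names, taxonomies and synonyms are invented (no real taxa). Each
#' species occupies its own disjoint block of cells, so envelopes can never
#' contradict each other; the constructor validates that the requested
#' counts are feasible.
#'
#' @param n_species number of species (1..40).
#' @param block_dim cells per species block, `c(ncol, nrow)`.
#' @param cell_size grid cell size in degrees.
#' @param years years covered by the climate cube (also the default
#'   reference period of the world's limits).
#' @param inside_fraction fraction of regular observations sampled inside
#'   the species' true envelope; the rest are planted outside (beyond a
#'   limit) and recorded as intended `out_of_range` rows.
#' @param pet_const constant potential evapotranspiration (mm/month) inside
#'   species blocks; a power of two keeps `ppt / pet` bit-exact so planted
#'   aridity extremes are recovered exactly.
#' @param temp_center_range,temp_width_range,temp_amp_range ranges (degrees
#'   C) the species' annual-mean temperature, envelope width and seasonal
#'   amplitude are drawn from.
#' @param ai_lower_range,ai_width_range,ai_amp ranges/amplitude for the
#'   aridity envelopes (dimensionless).
#' @param seed integer seed controlling every random draw.
#' @return a validated list of class `"WorldSpec"`.
#' @seealso [makeWorld()]
#' @export
worldSpec <- function(n_species = 20, block_dim = c(3, 3), cell_size = 1,
                      years = 1961:1975, inside_fraction = 0.8,
                      pet_const = 64,
                      temp_center_range = c(8, 24),
                      temp_width_range = c(6, 12),
                      temp_amp_range = c(2, 6),
                      ai_lower_range = c(0.2, 0.6),
                      ai_width_range = c(0.3, 0.8),
                      ai_amp = 0.05,
                      seed = 1) {
  spec <- list(n_species = as.integer(n_species), block_dim = as.integer(block_dim),
               cell_size = cell_size, years = sort(as.integer(years)),
               inside_fraction = inside_fraction, pet_const = pet_const,
               temp_center_range = temp_center_range,
               temp_width_range = temp_width_range,
               temp_amp_range = temp_amp_range,
               ai_lower_range = ai_lower_range,
               ai_width_range = ai_width_range, ai_amp = ai_amp,
               seed = as.integer(seed))
  stopifnot(spec$n_species >= 1, spec$n_species <= 40,
            length(spec$block_dim) == 2, all(spec$block_dim >= 1),
            length(spec$years) >= 1,
            spec$inside_fraction >= 0, spec$inside_fraction <= 1,
            spec$pet_const > 0,
            spec$temp_width_range[1] > 0, spec$ai_width_range[1] > 0,
            spec$ai_lower_range[1] - spec$ai_amp > 0)
  class(spec) <- "WorldSpec"
  spec
}

.world_names <- function(n) {
  genera <- c("Xenomys", "Calornis", "Thermogale", "Brachysaura", "Leptobatis",
              "Macrotherium", "Micropteryx", "Neocola", "Pseudophaga", "Eudon")
  stems <- c("albus", "niger", "rubeus", "parvus", "magnus",
             "montanus", "aridus", "pluvius", "borealis", "australis")
  epithets <- as.vector(t(outer(c("", "oides", "ensis", "icus"), stems,
                                function(s, e) paste0(e, s))))
  paste(rep_len(genera, n), epithets[seq_len(n)])
}

.season <- function(m) cospi(2 * (m - 7) / 12)

#' Build the synthetic species world
#'
#' Generates, deterministically from the spec's seed: a toy taxonomy and
#' synonym map; a [ClimateCube-class] in which each species' disjoint cell
#' block carries monthly values spanning exactly its true envelopes
#' (one cell-year is planted at the exact lower limit and one at the exact
#' upper limit, so pooled min/max recovery is deterministic, not
#' asymptotic); range polygons for half the species and occurrence points
#' for the other half; the true [NicheLimitTable-class] (including one
#' extra species with degenerate, zero-width limits used only for flag
#' testing); and an observation table whose rows carry known intended
#' outcomes — in-envelope rows, out-of-range rows, a bare-genus binomial,
#' an invalid month, impossible/missing values, a degenerate-limit row and
#' a synonym-submitted row.
#'
#' The ground-truth element records every true envelope, the submitted-name
#' scenario (`n_species` names of which one is a bare genus, so all but one
#' match), and the intended flag pattern of every observation row for both
#' [tpi()] and [api()].
#'
#' @param spec a [worldSpec()].
#' @return a list with elements `cube`, `geometries` (named list of
#'   [SpeciesGeometry-class]), `limits` ([NicheLimitTable-class]),
#'   `taxonomy` (data.frame), `synonyms` ([SynonymMap-class]),
#'   `observations` (data.frame), `truth` (list) and `spec`.
#' @examples
#' w <- makeWorld(worldSpec(n_species = 2, years = 1961:1962))
#' names(w)
#' @export
makeWorld <- function(spec = worldSpec()) {
  stopifnot(inherits(spec, "WorldSpec"))
  .with_seed(spec$seed, .build_world(spec))
}

.build_world <- function(spec) {
  n <- spec$n_species
  bx <- spec$block_dim[1]; by <- spec$block_dim[2]
  cs <- spec$cell_size
  nb_x <- ceiling(sqrt(n)); nb_y <- ceiling(n / nb_x)
  n_lon <- nb_x * bx; n_lat <- nb_y * by
  lon <- (seq_len(n_lon) - 0.5) * cs
  lat <- (seq_len(n_lat) - 0.5) * cs
  cells <- expand.grid(lon = lon, lat = lat, KEEP.OUT.ATTRS = FALSE)
  years <- spec$years
  tm <- expand.grid(month = 1:12, year = years, KEEP.OUT.ATTRS = FALSE)
  nc <- nrow(cells); nt <- nrow(tm)

  tmax <- matrix(15, nc, nt)
  ppt <- matrix(0.5 * spec$pet_const, nc, nt)
  pet <- matrix(spec$pet_const, nc, nt)

  names_ <- .world_names(n)
  genus <- vapply(strsplit(names_, " "), `[`, character(1), 1L)
  classes <- ifelse(seq_len(n) %% 2 == 1, "Synthaves", "Synthomammalia")
  orders <- ifelse(seq_len(n) %% 4 %in% c(1, 2), "Primiformes", "Secundiformes")
  families <- paste0(genus, "idae")

  env_t_lower <- env_t_upper <- matrix(NA_real_, n, 12)
  env_a_lower <- env_a_upper <- matrix(NA_real_, n, 12)
  geoms <- vector("list", n)
  for (s in seq_len(n)) {
    # species block: cells [x0, x0+bx) x [y0, y0+by) in cell units
    bi <- (s - 1) %% nb_x; bj <- (s - 1) %/% nb_x
    xs <- bi * bx + seq_len(bx); ys <- bj * by + seq_len(by)
    cell_idx <- as.vector(outer(xs, (ys - 1) * n_lon, `+`))

    centre <- runif(1, spec$temp_center_range[1], spec$temp_center_range[2])
    width <- runif(1, spec$temp_width_range[1], spec$temp_width_range[2])
    amp <- runif(1, spec$temp_amp_range[1], spec$temp_amp_range[2])
    ai_lo_base <- runif(1, spec$ai_lower_range[1], spec$ai_lower_range[2])
    ai_width <- runif(1, spec$ai_width_range[1], spec$ai_width_range[2])

    for (m in 1:12) {
      tl <- centre + amp * .season(m) - width / 2
      tu <- centre + amp * .season(m) + width / 2
      al <- ai_lo_base + spec$ai_amp * .season(m)
      au <- al + ai_width
      env_t_lower[s, m] <- tl; env_t_upper[s, m] <- tu
      env_a_lower[s, m] <- al; env_a_upper[s, m] <- au

      cols <- which(tm$month == m)
      k <- length(cell_idx) * length(cols)
      tv <- runif(k, tl, tu)
      av <- runif(k, al, au)
      # plant the exact extremes so pooled min/max recovers the envelope
      tv[1] <- tl; tv[k] <- tu
      av[1] <- al; av[k] <- au
      tmax[cell_idx, cols] <- tv
      ppt[cell_idx, cols] <- av * spec$pet_const
    }

    block_lon <- c(bi * bx, (bi + 1) * bx) * cs
    block_lat <- c(bj * by, (bj + 1) * by) * cs
    geoms[[s]] <- if (s %% 2 == 1) {
      SpeciesGeometry(names_[s], polygons = data.frame(
        lon = block_lon[c(1, 2, 2, 1)], lat = block_lat[c(1, 1, 2, 2)]))
    } else {
      SpeciesGeometry(names_[s], points = cells[cell_idx, , drop = FALSE])
    }
  }
  names(geoms) <- names_

  cube <- ClimateCube(tmax = tmax, ppt = ppt, pet = pet,
                      lon = cells$lon, lat = cells$lat,
                      year = tm$year, month = tm$month, cell_size = cs)

  taxonomy <- data.frame(class = classes, order = orders, family = families,
                         genus = genus, species = names_)

  degen_name <- "Degeneratus fixus"
  lim_rows <- rbind(
    do.call(rbind, lapply(seq_len(n), function(s) data.frame(
      class = classes[s], order = orders[s], family = families[s],
      genus = genus[s], species = names_[s],
      month = rep(1:12, 2),
      variable = rep(c("temperature", "aridity"), each = 12),
      lower = c(env_t_lower[s, ], env_a_lower[s, ]),
      upper = c(env_t_upper[s, ], env_a_upper[s, ])))),
    data.frame(class = "Synthaves", order = "Primiformes",
               family = "Degeneratidae", genus = "Degeneratus",
               species = degen_name, month = rep(1:12, 2),
               variable = rep(c("temperature", "aridity"), each = 12),
               lower = rep(c(5, 0.5), each = 12),
               upper = rep(c(5, 0.5), each = 12)))
  limits <- NicheLimitTable(lim_rows, provenance = list(
    period = c(years[1], years[length(years)]), quantile = 0,
    source = "synthetic world: planted envelopes"))

  synonyms <- SynonymMap(data.frame(
    accepted = names_,
    synonym = paste0("Old", tolower(names_))))

  # --- observations with intended outcomes ---------------------------------
  obs <- list(); truth_obs <- list()
  oid <- 0L
  no_flags <- setNames(rep(FALSE, 5), .flag_cols)
  add_obs <- function(species, month, temperature, aridity,
                      tpi_flags = no_flags, api_flags = no_flags,
                      tpi_pi = NA_real_, api_pi = NA_real_, note = "") {
    oid <<- oid + 1L
    obs[[oid]] <<- data.frame(obs_id = oid, species = species, month = month,
                              temperature = temperature, aridity = aridity)
    truth_obs[[oid]] <<- data.frame(
      obs_id = oid, note = note,
      t(setNames(tpi_flags, paste0("tpi_", .flag_cols))),
      t(setNames(api_flags, paste0("api_", .flag_cols))),
      tpi_pi = tpi_pi, api_pi = api_pi)
  }
  flags <- function(...) {
    f <- no_flags
    f[c(...)] <- TRUE
    f
  }
  sample_value <- function(lo, up, inside, allow_below = TRUE) {
    if (inside) return(runif(1, lo, up))
    off <- runif(1, 0.05, 0.5) * (up - lo)
    if (allow_below && runif(1) < 0.5) lo - off else up + off
  }
  for (s in seq_len(n)) {
    for (m in 1:12) {
      t_in <- runif(1) < spec$inside_fraction
      a_in <- runif(1) < spec$inside_fraction
      tv <- sample_value(env_t_lower[s, m], env_t_upper[s, m], t_in)
      # below-limit aridity draws only where they cannot go negative
      a_below_ok <- env_a_lower[s, m] - 0.5 *
        (env_a_upper[s, m] - env_a_lower[s, m]) >= 0
      av <- sample_value(env_a_lower[s, m], env_a_upper[s, m], a_in,
                         allow_below = a_below_ok)
      tpi_pi <- (tv - env_t_lower[s, m]) / (env_t_upper[s, m] - env_t_lower[s, m])
      api_pi <- (av - env_a_lower[s, m]) / (env_a_upper[s, m] - env_a_lower[s, m])
      add_obs(names_[s], m, tv, av,
              tpi_flags = flags(if (!t_in) "out_of_range"),
              api_flags = flags(if (!a_in) "out_of_range"),
              tpi_pi = tpi_pi, api_pi = api_pi,
              note = "regular")
    }
  }
  # planted anomalies
  add_obs(genus[1], 6, 10, 0.5,
          tpi_flags = flags("bad_binomial"), api_flags = flags("bad_binomial"),
          note = "bare genus, unmatchable")
  add_obs(names_[2], 13, 10, 0.5,
          tpi_flags = flags("bad_month"), api_flags = flags("bad_month"),
          note = "invalid month token")
  add_obs(names_[3], 4, NA_real_, -0.2,
          tpi_flags = flags("bad_value"), api_flags = flags("bad_value"),
          note = "missing temperature, impossible negative aridity")
  add_obs(degen_name, 6, 5, 0.5,
          tpi_flags = flags("degenerate_limits"),
          api_flags = flags("degenerate_limits"),
          note = "zero-width limits")
  s4 <- min(4L, n)
  add_obs(names_[s4], 6,
          env_t_upper[s4, 6] + 0.3 * (env_t_upper[s4, 6] - env_t_lower[s4, 6]),
          env_a_upper[s4, 6] + 0.3 * (env_a_upper[s4, 6] - env_a_lower[s4, 6]),
          tpi_flags = flags("out_of_range"), api_flags = flags("out_of_range"),
          tpi_pi = 1.3, api_pi = 1.3,
          note = "planted beyond upper limits")
  s5 <- min(5L, n)
  add_obs(paste0("Old", tolower(names_[s5])), 3,
          (env_t_lower[s5, 3] + env_t_upper[s5, 3]) / 2,
          (env_a_lower[s5, 3] + env_a_upper[s5, 3]) / 2,
          tpi_pi = 0.5, api_pi = 0.5,
          note = "synonym-submitted name, resolvable")

  observations <- do.call(rbind, obs)
  truth_obs <- do.call(rbind, truth_obs)
  rownames(observations) <- rownames(truth_obs) <- NULL

  # the submitted-names scenario: all species names, one degraded to its genus
  submitted <- names_
  submitted[1] <- genus[1]
  truth <- list(
    seed = spec$seed,
    n_species = n,
    species = names_,
    envelopes = list(
      temperature = list(lower = env_t_lower, upper = env_t_upper),
      aridity = list(lower = env_a_lower, upper = env_a_upper)),
    degenerate_species = degen_name,
    submitted_names = submitted,
    expected_matched = submitted %in% names_,
    observation_flags = truth_obs)

  list(cube = cube, geometries = geoms, limits = limits, taxonomy = taxonomy,
       synonyms = synonyms, observations = observations, truth = truth,
       spec = spec)
}

#' Write all world artifacts to a directory
#'
#' Writes the cube (plain-text serialization, see [writeCube()]), the
#' taxonomy, synonym-map, limit and observation CSVs, the point geometries
#' CSV, and the ground-truth JSON (`ground_truth.json`: true envelopes per
#' species x month x variable, the submitted-name scenario, and the
#' intended flag pattern of every observation row).
#'
#' @param world a list from [makeWorld()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeWorld <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCube(world$cube, file.path(dir, "cube"))
  write.csv(world$taxonomy, file.path(dir, "taxonomy.csv"), row.names = FALSE)
  writeSynonymMap(world$synonyms, file.path(dir, "synonyms.csv"))
  writeLimits(world$limits, file.path(dir, "limits.csv"))
  write.csv(world$observations, file.path(dir, "observations.csv"),
            row.names = FALSE)
  pts <- Filter(function(g) geometryKind(g) == "points", world$geometries)
  if (length(pts)) writeSpeciesPoints(pts, file.path(dir, "points.csv"))
  jsonlite::write_json(world$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
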