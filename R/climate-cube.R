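#' Construct a ClimateCube
#'
#' Assembles monthly maximum temperature, precipitation and potential
#' evapotranspiration matrices (grid cells x time steps) into a validated
#' [ClimateCube-class]. All three matrices must share dimensions; rows
#' correspond to `lon`/`lat` cell centers and columns to the `(year, month)`
#' time axis.
#'
#' @param tmax,ppt,pet numeric matrices, cells x time steps. `tmax` in
#'   degrees C, `ppt` and `pet` in mm/month (non-negative where not `NA`).
#' @param lon,lat numeric vectors of cell-center coordinates, one per row.
#' @param year,month integer vectors, one per column; `(year, month)` must
#'   be strictly increasing.
#' @param cell_size grid cell size in degrees.
#' @return a [ClimateCube-class]
#' @examples
#' cube <- ClimateCube(tmax = matrix(20, 1, 1), ppt = matrix(50, 1, 1),
#'                     pet = matrix(100, 1, 1), lon = 0.5, lat = 0.5,
#'                     year = 1961L, month = 1L, cell_size = 1)
#' cellCoords(cube)
#' @export
ClimateCube <- function(tmax, ppt, pet, lon, lat, year, month, cell_size) {
  dims <- lapply(list(tmax = tmax, ppt = ppt, pet = pet), dim)
  if (length(unique(dims)) != 1L) {
    stop("tmax, ppt and pet must have identical dimensions")
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(tmax = tmax, ppt = ppt, pet = pet),
    rowData = S4Vectors::DataFrame(lon = as.numeric(lon), lat = as.numeric(lat)),
    colData = S4Vectors::DataFrame(year = as.integer(year), month = as.integer(month)),
    metadata = list(cell_size = cell_size)
  )
  methods::new("ClimateCube", se)
}

#' @rdname cellCoords
#' @export
setMethod("cellCoords", "ClimateCube", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  data.frame(lon = rd$lon, lat = rd$lat)
})

#' @rdname cubeTime
#' @export
setMethod("cubeTime", "ClimateCube", function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(year = cd$year, month = cd$month)
})

#' @rdname cellSize
#' @export
setMethod("cellSize", "ClimateCube", function(x) {
  S4Vectors::metadata(x)$cell_size
})

setMethod("show", "ClimateCube", function(object) {
  tm <- cubeTime(object)
  cat(sprintf("ClimateCube: %d cells x %d monthly steps (%d-%02d to %d-%02d), cell size %g deg\n",
              nrow(object), ncol(object),
              tm$year[1], tm$month[1],
              tm$year[nrow(tm)], tm$month[nrow(tm)],
              cellSize(object)))
  cat(sprintf("  assays: %s\n",
              paste(SummarizedExperiment::assayNames(object), collapse = ", ")))
  rd <- cellCoords(object)
  cat(sprintf("  extent: lon [%g, %g], lat [%g, %g] (cell centers)\n",
              min(rd$lon), max(rd$lon), min(rd$lat), max(rd$lat)))
})

#' Convert temperatures to degrees Celsius
#'
#' Supported units: `"C"` (pass-through), `"F"` (Fahrenheit,
#' `(v - 32) * 5/9`), `"K"` (Kelvin, `v - 273.15`). Kelvin values below
#' absolute zero are rejected as unphysical.
#'
#' @param value numeric vector of temperatures.
#' @param unit one of `"C"`, `"F"`, `"K"` (case-insensitive).
#' @return numeric vector in degrees C; `NA` values pass through.
#' @examples
#' toCelsius(32, "F")      # 0
#' toCelsius(273.15, "K")  # 0
#' @export
toCelsius <- function(value, unit = "C") {
  if (length(unit) != 1L || !toupper(unit) %in% c("C", "F", "K")) {
    stop("unknown temperature unit '", paste(unit, collapse = ","),
         "'; accepted units are \"C\", \"F\", \"K\"")
  }
  value <- as.numeric(value)
  switch(toupper(unit),
         C = value,
         F = (value - 32) * 5 / 9,
         K = {
           if (any(value < 0, na.rm = TRUE)) {
             stop("Kelvin temperatures must be >= 0")
           }
           value - 273.15
         })
}

#' Aridity index: precipitation over potential evapotranspiration
#'
#' Computes `AI = ppt / pet` per element with explicit guards: cells with
#' `pet == 0` get a missing AI and flag `"undefined"` (never an infinity or
#' an exception); if a `cap` is configured, ratios above it are clamped to
#' the cap and flagged `"capped"`; with no cap, ratios above the optional
#' `extreme` threshold keep their raw value but are flagged `"extreme"`
#' (the index is known to blow up where potential evapotranspiration is
#' very low). Flag-don't-silently-alter is the default contract: `cap` is
#' `NULL` unless set.
#'
#' @param ppt,pet non-negative numeric vectors (mm/month), recycled to a
#'   common length.
#' @param cap optional positive number: clamp AI above this value.
#' @param extreme optional positive number: flag (but do not alter) AI
#'   above this value; ignored when `cap` is set.
#' @return a data.frame with columns `ai` (numeric, `NA` where undefined)
#'   and `flag` (`"ok"`, `"undefined"`, `"capped"` or `"extreme"`).
#' @examples
#' aridityIndex(60, 120)              # ai = 0.5, flag "ok"
#' aridityIndex(100, 0)               # ai = NA,  flag "undefined"
#' aridityIndex(500, 1, cap = 10)     # ai = 10,  flag "capped"
#' @export
aridityIndex <- function(ppt, pet, cap = NULL, extreme = NULL) {
  if (any(ppt < 0, na.rm = TRUE) || any(pet < 0, na.rm = TRUE)) {
    stop("ppt and pet must be non-negative")
  }
  if (!is.null(cap) && (!is.numeric(cap) || cap <= 0)) {
    stop("cap must be a positive number")
  }
  n <- max(length(ppt), length(pet))
  ppt <- rep_len(as.numeric(ppt), n)
  pet <- rep_len(as.numeric(pet), n)
  ai <- ifelse(pet > 0, ppt / pet, NA_real_)
  flag <- rep("ok", n)
  flag[!is.na(pet) & pet == 0] <- "undefined"
  if (!is.null(cap)) {
    over <- !is.na(ai) & ai > cap
    ai[over] <- cap
    flag[over] <- "capped"
  } else if (!is.null(extreme)) {
    over <- !is.na(ai) & ai > extreme
    flag[over] <- "extreme"
  }
  data.frame(ai = ai, flag = flag)
}

#' Per-cell aridity index grid for a cube
#'
#' Applies [aridityIndex()] to the `ppt` and `pet` assays of a cube,
#' returning matching cells x time matrices of AI values and flags.
#'
#' @param cube a [ClimateCube-class]
#' @inheritParams aridityIndex
#' @return a list with matrices `ai` (numeric) and `flag` (character),
#'   dimensioned like the cube's assays.
#' @export
cubeAridity <- function(cube, cap = NULL, extreme = NULL) {
  stopifnot(methods::is(cube, "ClimateCube"))
  ppt <- SummarizedExperiment::assay(cube, "ppt")
  pet <- SummarizedExperiment::assay(cube, "pet")
  res <- aridityIndex(as.numeric(ppt), as.numeric(pet), cap = cap, extreme = extreme)
  list(ai = matrix(res$ai, nrow(ppt), ncol(ppt), dimnames = dimnames(ppt)),
       flag = matrix(res$flag, nrow(ppt), ncol(ppt), dimnames = dimnames(ppt)))
}

# run expr with a temporary RNG state seeded at `seed`; restores caller RNG
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic monthly climate cube
#'
#' Stands in for a remote monthly climatology: maximum temperature is a
#' seasonal sinusoid (peaking in July) plus a linear latitudinal gradient
#' plus Gaussian noise; precipitation and potential evapotranspiration are
#' noisy baselines. Negative precipitation draws are truncated at 0 and
#' PET draws at a small positive floor so the aridity index stays defined
#' unless `pet_floor = 0` is requested explicitly. Deterministic for a
#' fixed `seed`.
#'
#' @param lon_range,lat_range length-2 numeric extents in degrees; cell
#'   centers are laid on a regular lattice of `cell_size` inside them.
#' @param cell_size cell size in degrees.
#' @param years integer vector of years (each contributes 12 monthly steps).
#' @param tmax_baseline annual-mean maximum temperature, degrees C.
#' @param tmax_amplitude seasonal half-range, degrees C (July peak).
#' @param tmax_gradient degrees C per degree latitude.
#' @param tmax_sd,ppt_sd,pet_sd Gaussian noise standard deviations (>= 0).
#' @param ppt_baseline,pet_baseline mm/month baselines.
#' @param pet_floor lower truncation for PET, mm/month.
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @return a [ClimateCube-class]
#' @examples
#' cube <- synthesizeCube(lon_range = c(0, 2), lat_range = c(0, 2),
#'                        cell_size = 1, years = 1961:1962, seed = 1)
#' cube
#' @export
synthesizeCube <- function(lon_range = c(-10, 10), lat_range = c(40, 50),
                           cell_size = 1, years = 1961:1975,
                           tmax_baseline = 20, tmax_amplitude = 8,
                           tmax_gradient = -0.6, tmax_sd = 2,
                           ppt_baseline = 80, ppt_sd = 30,
                           pet_baseline = 100, pet_sd = 20,
                           pet_floor = 0.1, seed = NULL) {
  stopifnot(length(years) >= 1, tmax_sd >= 0, ppt_sd >= 0, pet_sd >= 0)
  lon <- .lattice(lon_range, cell_size)
  lat <- .lattice(lat_range, cell_size)
  if (!length(lon) || !length(lat)) {
    stop("empty extent: no cell centers fit in the requested ranges")
  }
  cells <- expand.grid(lon = lon, lat = lat, KEEP.OUT.ATTRS = FALSE)
  years <- sort(as.integer(years))
  tm <- expand.grid(month = 1:12, year = years, KEEP.OUT.ATTRS = FALSE)
  nc <- nrow(cells); nt <- nrow(tm)
  season <- cospi(2 * (tm$month - 7) / 12)  # +1 in July, -1 in January
  .with_seed(seed, {
    mu_t <- outer(cells$lat * tmax_gradient,
                  tmax_baseline + tmax_amplitude * season, `+`)
    tmax <- mu_t + if (tmax_sd > 0) matrix(rnorm(nc * nt, 0, tmax_sd), nc, nt) else 0
    ppt <- ppt_baseline + if (ppt_sd > 0) matrix(rnorm(nc * nt, 0, ppt_sd), nc, nt) else
      matrix(0, nc, nt)
    pet <- pet_baseline + if (pet_sd > 0) matrix(rnorm(nc * nt, 0, pet_sd), nc, nt) else
      matrix(0, nc, nt)
    ppt <- pmax(ppt, 0)
    pet <- pmax(pet, pet_floor)
    ClimateCube(tmax = tmax, ppt = ppt, pet = pet,
                lon = cells$lon, lat = cells$lat,
                year = tm$year, month = tm$month, cell_size = cell_size)
  })
}

.lattice <- function(range, cell_size) {
  if (diff(range) < cell_size) return(numeric())
  seq(range[1] + cell_size / 2, range[2] - cell_size / 2 + 1e-9, by = cell_size)
}

#' Write / read a ClimateCube as plain text
#'
#' Serializes a cube to a directory with one long-format CSV per variable
#' (`tmax.csv`, `ppt.csv`, `pet.csv`; columns `lon,lat,year,month,value`)
#' and a `meta.json` sidecar carrying the cell size. The round trip is
#' lossless to full double precision. `readCube()` fails fast: a missing
#' variable file (e.g. PET) or a variable whose grid or time axis disagrees
#' with the others is an error naming the offending variable, raised at
#' read time rather than mid-computation.
#'
#' @param cube a [ClimateCube-class]
#' @param path directory to write to / read from (created if needed).
#' @return `writeCube()` returns `path` invisibly; `readCube()` returns a
#'   [ClimateCube-class].
#' @export
writeCube <- function(cube, path) {
  stopifnot(methods::is(cube, "ClimateCube"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cc <- cellCoords(cube); tm <- cubeTime(cube)
  for (v in c("tmax", "ppt", "pet")) {
    a <- SummarizedExperiment::assay(cube, v)
    long <- data.frame(lon = rep(cc$lon, times = ncol(a)),
                       lat = rep(cc$lat, times = ncol(a)),
                       year = rep(tm$year, each = nrow(a)),
                       month = rep(tm$month, each = nrow(a)),
                       value = as.numeric(a))
    write.csv(long, file.path(path, paste0(v, ".csv")), row.names = FALSE)
  }
  jsonlite::write_json(list(cell_size = cellSize(cube)),
                       file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCube
#' @export
readCube <- function(path) {
  meta_f <- file.path(path, "meta.json")
  if (!file.exists(meta_f)) stop("no meta.json found in '", path, "'")
  meta <- jsonlite::read_json(meta_f, simplifyVector = TRUE)
  vars <- c("tmax", "ppt", "pet")
  files <- file.path(path, paste0(vars, ".csv"))
  missing <- !file.exists(files)
  if (any(missing)) {
    stop("missing variable file(s): ", paste(vars[missing], collapse = ", "),
         " (required for aridity-index computation downstream)")
  }
  longs <- lapply(files, read.csv)
  names(longs) <- vars
  keyify <- function(d) list(
    grid = unique(d[order(d$lat, d$lon), c("lon", "lat")]),
    time = unique(d[order(d$year, d$month), c("year", "month")]))
  ref <- keyify(longs$tmax)
  for (v in vars[-1]) {
    k <- keyify(longs[[v]])
    if (!isTRUE(all.equal(ref$grid, k$grid, check.attributes = FALSE)) ||
        !isTRUE(all.equal(ref$time, k$time, check.attributes = FALSE))) {
      stop("variable '", v, "' has a grid or time axis inconsistent with 'tmax'")
    }
  }
  grid <- ref$grid; tm <- ref$time
  cell_id <- function(d) match(paste(d$lon, d$lat), paste(grid$lon, grid$lat))
  time_id <- function(d) match(paste(d$year, d$month), paste(tm$year, tm$month))
  mats <- lapply(longs, function(d) {
    m <- matrix(NA_real_, nrow(grid), nrow(tm))
    m[cbind(cell_id(d), time_id(d))] <- d$value
    m
  })
  ClimateCube(tmax = mats$tmax, ppt = mats$ppt, pet = mats$pet,
              lon = grid$lon, lat = grid$lat,
              year = tm$year, month = tm$month, cell_size = meta$cell_size)
}
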