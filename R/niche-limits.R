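#' Construct a NicheLimitTable
#'
#' @param limits a data.frame with columns `class, order, family, genus,
#'   species, month, variable, lower, upper`. Missing taxonomy columns are
#'   filled with `NA`; `genus`, if absent, is derived from the binomial.
#'   `month` is integer 1..12 (0 marks a year-average row); `variable` is
#'   `"temperature"` or `"aridity"`.
#' @param provenance a list recording how the limits were derived
#'   (typically `period`, `quantile`, `source`).
#' @return a validated [NicheLimitTable-class]
#' @export
NicheLimitTable <- function(limits, provenance = list()) {
  stopifnot(is.data.frame(limits))
  limits$species <- canonicalizeBinomial(limits$species)
  if (!"genus" %in% colnames(limits)) {
    limits$genus <- vapply(strsplit(limits$species, " "), `[`, character(1), 1L)
  }
  for (col in c("class", "order", "family")) {
    if (!col %in% colnames(limits)) limits[[col]] <- NA_character_
  }
  limits$month <- as.integer(limits$month)
  limits <- limits[, .limit_cols, drop = FALSE]
  rownames(limits) <- NULL
  methods::new("NicheLimitTable", limits = limits, provenance = provenance)
}

#' @rdname limitsData
#' @export
setMethod("limitsData", "NicheLimitTable", function(x) x@limits)

#' @rdname provenance
#' @export
setMethod("provenance", "NicheLimitTable", function(x) x@provenance)

#' @export
setMethod("nrow", "NicheLimitTable", function(x) nrow(x@limits))

#' @export
setMethod("as.data.frame", "NicheLimitTable",
          function(x, row.names = NULL, optional = FALSE, ...) x@limits)

setMethod("show", "NicheLimitTable", function(object) {
  df <- object@limits
  cat(sprintf("NicheLimitTable: %d row(s), %d species, variables: %s\n",
              nrow(df), length(unique(df$species)),
              paste(sort(unique(df$variable)), collapse = ", ")))
  if (length(object@provenance)) {
    pv <- object@provenance
    cat("  provenance:",
        paste(names(pv), vapply(pv, function(x) paste(x, collapse = "-"),
                                character(1)),
              sep = "=", collapse = ", "), "\n")
  }
  if (nrow(df)) {
    shown <- head(df, 4)
    shown$month <- ifelse(shown$month == 0L, "ALL", as.character(shown$month))
    print(shown)
    if (nrow(df) > 4) cat("  ...\n")
  }
})

#' Read / write a NicheLimitTable as CSV with a provenance sidecar
#'
#' The CSV has columns `class, order, family, genus, species, month,
#' variable, lower, upper`; year-average rows carry month `"ALL"`. A JSON
#' sidecar `<path>.provenance.json` records the provenance list and is read
#' back when present.
#'
#' @param table a [NicheLimitTable-class]
#' @param path CSV path.
#' @return `writeLimits()` the path invisibly; `readLimits()` a
#'   [NicheLimitTable-class].
#' @export
writeLimits <- function(table, path) {
  df <- limitsData(table)
  df$month <- ifelse(df$month == 0L, "ALL", as.character(df$month))
  write.csv(df, path, row.names = FALSE)
  if (length(provenance(table))) {
    jsonlite::write_json(provenance(table),
                         paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname writeLimits
#' @export
readLimits <- function(path) {
  df <- read.csv(path)
  mo <- toupper(as.character(df$month))
  df$month <- ifelse(mo == "ALL", 0L,
                     suppressWarnings(as.integer(replace(mo, mo == "ALL", NA))))
  side <- paste0(path, ".provenance.json")
  prov <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list()
  NicheLimitTable(df, provenance = prov)
}

#' Grid cells selected by a species geometry
#'
#' Polygon sets select every cell whose *center* falls inside (or on the
#' boundary of) any polygon; point sets select the unique cells containing
#' each point (a point belongs to the cell whose center is within half a
#' cell size in both axes). Points outside the grid extent are dropped with
#' a warning; a geometry that selects no cell at all is an error naming
#' the cube extent, never a silently empty table.
#'
#' @param geom a [SpeciesGeometry-class]
#' @param cube a [ClimateCube-class]
#' @return an integer vector of cube row indices (cells), sorted, unique.
#' @export
cellsForGeometry <- function(geom, cube) {
  stopifnot(methods::is(geom, "SpeciesGeometry"), methods::is(cube, "ClimateCube"))
  cc <- cellCoords(cube)
  cs <- cellSize(cube)
  if (geometryKind(geom) == "polygons") {
    inside <- rep(FALSE, nrow(cc))
    for (poly in geom@geometry) {
      inside <- inside | pracma::inpolygon(cc$lon, cc$lat, poly$lon, poly$lat,
                                           boundary = TRUE)
    }
    cells <- which(inside)
  } else {
    pts <- geom@geometry[[1]]
    half <- cs / 2 + 1e-9
    idx <- vapply(seq_len(nrow(pts)), function(i) {
      hit <- which(abs(cc$lon - pts$lon[i]) <= half &
                   abs(cc$lat - pts$lat[i]) <= half)
      if (length(hit)) hit[1] else NA_integer_
    }, integer(1))
    if (anyNA(idx)) {
      if (all(is.na(idx))) idx <- integer()
      else {
        warning(sum(is.na(idx)), " point(s) outside the cube extent dropped for ",
                geometrySpecies(geom))
        idx <- idx[!is.na(idx)]
      }
    }
    cells <- sort(unique(idx))
  }
  if (!length(cells)) {
    stop(sprintf(
      "geometry for %s selects no grid cell: cube extent is lon [%g, %g], lat [%g, %g]",
      geometrySpecies(geom), min(cc$lon), max(cc$lon), min(cc$lat), max(cc$lat)))
  }
  cells
}

#' Estimate monthly thermal and aridity niche limits for one species
#'
#' For each calendar month, pools the cube's values over all cells selected
#' by the species geometry and all years of the reference period, then takes
#' the `q` and `1 - q` quantiles of the pool as the lower and upper realized
#' limits (`q = 0` gives the exact pooled minimum and maximum). Temperature
#' limits come from the `tmax` assay (degrees C); aridity limits from the
#' aridity index `ppt / pet` computed per cell-month via [aridityIndex()]
#' (undefined cells, where PET is 0, are excluded as missing; an `ai_cap`
#' is applied before pooling when set). Quantiles use linear interpolation
#' between order statistics (R type 7), so results are dialect-stable.
#'
#' A month whose pool is entirely missing yields a row with missing limits
#' and a warning; if no month has any data at all, the function errors.
#'
#' @param geom a [SpeciesGeometry-class]
#' @param cube a [ClimateCube-class]
#' @param period length-2 integer vector `c(start, end)` of years,
#'   inclusive; must lie within the cube's time axis. Default 1961-1975.
#' @param q tail quantile in `[0, 0.5)`; `q = 0` (default) uses the
#'   absolute pooled extremes.
#' @param ai_cap optional cap passed to [aridityIndex()].
#' @param taxonomy optional one-row data.frame with columns among
#'   `class`, `order`, `family`, `genus` to fill the taxonomy fields.
#' @return a [NicheLimitTable-class] with 24 rows (12 months x 2 variables)
#'   for the one species, and provenance `(period, quantile, source)`.
#' @examples
#' cube <- synthesizeCube(lon_range = c(0, 4), lat_range = c(0, 4),
#'                        cell_size = 1, years = 1961:1963,
#'                        tmax_sd = 0, ppt_sd = 0, pet_sd = 0,
#'                        tmax_gradient = 0, tmax_amplitude = 0)
#' geom <- SpeciesGeometry("Testus alpha",
#'                         points = data.frame(lon = 0.5, lat = 0.5))
#' lim <- estimateLimits(geom, cube, period = c(1961, 1963))
#' subset(limitsData(lim), variable == "temperature" & month == 1)
#' @export
estimateLimits <- function(geom, cube, period = c(1961, 1975), q = 0,
                           ai_cap = NULL, taxonomy = NULL) {
  stopifnot(methods::is(cube, "ClimateCube"),
            length(period) == 2, period[1] <= period[2],
            is.numeric(q), length(q) == 1, q >= 0, q < 0.5)
  tm <- cubeTime(cube)
  if (period[1] < min(tm$year) || period[2] > max(tm$year)) {
    stop(sprintf("reference period %d-%d outside cube years %d-%d",
                 period[1], period[2], min(tm$year), max(tm$year)))
  }
  cells <- cellsForGeometry(geom, cube)
  in_period <- tm$year >= period[1] & tm$year <= period[2]
  tmax <- SummarizedExperiment::assay(cube, "tmax")[cells, , drop = FALSE]
  ai <- cubeAridity(cube, cap = ai_cap)$ai[cells, , drop = FALSE]
  pools <- list(temperature = tmax, aridity = ai)

  rows <- list()
  for (v in names(pools)) {
    for (m in 1:12) {
      pool <- as.numeric(pools[[v]][, in_period & tm$month == m])
      pool <- pool[!is.na(pool)]
      if (!length(pool)) {
        warning(sprintf("no non-missing %s values for month %d; limits set missing",
                        v, m))
        lo <- up <- NA_real_
      } else {
        qs <- quantile(pool, probs = c(q, 1 - q), names = FALSE, type = 7)
        lo <- qs[1]; up <- qs[2]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        species = geometrySpecies(geom), month = m, variable = v,
        lower = lo, upper = up)
    }
  }
  df <- do.call(rbind, rows)
  if (all(is.na(df$lower))) {
    stop("no non-missing climate values in any month for ",
         geometrySpecies(geom))
  }
  if (!is.null(taxonomy)) {
    for (col in intersect(c("class", "order", "family", "genus"),
                          colnames(taxonomy))) {
      df[[col]] <- taxonomy[[col]][1]
    }
  }
  NicheLimitTable(df, provenance = list(
    period = c(period[1], period[2]), quantile = q,
    source = "climate-cube pooled cells x years, type-7 quantiles"))
}

#' Year-average limits over the 12 monthly rows
#'
#' Arithmetically averages the monthly lower and upper limits per
#' `(species, variable)`; months with missing limits are skipped with a
#' warning, and a `(species, variable)` group with no usable month at all
#' is an error. Output rows carry month 0, rendered as `"ALL"`.
#'
#' @param table a [NicheLimitTable-class] with monthly rows.
#' @return a [NicheLimitTable-class] of one month-`ALL` row per
#'   `(species, variable)`, provenance inherited.
#' @export
yearAverageLimits <- function(table) {
  df <- limitsData(table)
  df <- df[df$month %in% 1:12, , drop = FALSE]
  if (!nrow(df)) stop("no monthly rows to average")
  key <- interaction(df$species, df$variable, drop = TRUE)
  out <- lapply(split(df, key), function(d) {
    ok <- !is.na(d$lower) & !is.na(d$upper)
    if (!any(ok)) {
      stop("all monthly limits missing for ", d$species[1], " / ", d$variable[1])
    }
    if (any(!ok)) {
      warning(sprintf("skipping %d month(s) with missing limits for %s / %s",
                      sum(!ok), d$species[1], d$variable[1]))
    }
    r <- d[1, , drop = FALSE]
    r$month <- 0L
    r$lower <- mean(d$lower[ok])
    r$upper <- mean(d$upper[ok])
    r
  })
  NicheLimitTable(do.call(rbind, out), provenance = provenance(table))
}
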