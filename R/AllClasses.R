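#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats quantile rnorm runif setNames
#' @importFrom utils read.csv write.csv head
NULL

#' ClimateCube: gridded monthly climate over a span of years
#'
#' A `ClimateCube` holds monthly maximum temperature (`tmax`, degrees C),
#' total precipitation (`ppt`, mm/month) and potential evapotranspiration
#' (`pet`, mm/month) on a regular lon/lat lattice, as a
#' [SummarizedExperiment::SummarizedExperiment] whose rows are grid cells
#' (with cell-center `lon`/`lat` in `rowData`) and whose columns are
#' `(year, month)` time steps (in `colData`). The cell size in degrees is
#' kept in `metadata(x)$cell_size`.
#'
#' Invariants enforced by the validity method: all three assays present and
#' dimension-matched; `ppt` and `pet` non-negative wherever non-missing;
#' the time axis strictly increasing; cell centers on a regular lattice.
#' Missing values are `NA`, never sentinel numbers.
#'
#' @seealso [ClimateCube()], [synthesizeCube()], [readCube()]
#' @export
setClass("ClimateCube", contains = "SummarizedExperiment")

setValidity("ClimateCube", function(object) {
  msgs <- character()
  need <- c("tmax", "ppt", "pet")
  have <- SummarizedExperiment::assayNames(object)
  if (!all(need %in% have)) {
    return(sprintf("missing assay(s): %s",
                   paste(setdiff(need, have), collapse = ", ")))
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("lon", "lat") %in% colnames(rd))) {
    msgs <- c(msgs, "rowData must contain 'lon' and 'lat' cell centers")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("year", "month") %in% colnames(cd))) {
    msgs <- c(msgs, "colData must contain 'year' and 'month'")
  } else {
    if (!all(cd$month %in% 1:12)) {
      msgs <- c(msgs, "months must be integers in 1..12")
    }
    step <- cd$year * 12 + cd$month
    if (length(step) > 1L && any(diff(step) <= 0)) {
      msgs <- c(msgs, "time axis (year, month) must be strictly increasing")
    }
  }
  for (v in c("ppt", "pet")) {
    a <- SummarizedExperiment::assay(object, v)
    if (any(a < 0, na.rm = TRUE)) {
      msgs <- c(msgs, sprintf("assay '%s' must be non-negative", v))
    }
  }
  cs <- S4Vectors::metadata(object)$cell_size
  if (is.null(cs) || !is.numeric(cs) || length(cs) != 1L || cs <= 0) {
    msgs <- c(msgs, "metadata$cell_size must be a single positive number")
  } else if (all(c("lon", "lat") %in% colnames(rd))) {
    for (ax in c("lon", "lat")) {
      u <- sort(unique(rd[[ax]]))
      if (length(u) > 1L) {
        off <- (u - u[1]) / cs
        if (any(abs(off - round(off)) > 1e-6)) {
          msgs <- c(msgs, sprintf("%s centers are not on a regular lattice of size %g", ax, cs))
        }
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' SynonymMap: accepted binomial to synonym pairs
#'
#' Holds pre-flattened (accepted, synonym) binomial pairs used to resolve
#' user-submitted names against the accepted names of a limit table. The
#' validity method rejects maps where a synonym points at two different
#' accepted names, or where an accepted name also appears as a synonym of a
#' *different* accepted name (i.e. synonym chains A -> B -> C must be
#' flattened before loading).
#'
#' @seealso [SynonymMap()], [readSynonymMap()], [resolveSynonyms()]
#' @export
setClass("SynonymMap", representation(map = "data.frame"))

setValidity("SynonymMap", function(object) {
  m <- object@map
  if (!all(c("accepted", "synonym") %in% colnames(m))) {
    return("map must have columns 'accepted' and 'synonym'")
  }
  msgs <- character()
  tab <- unique(m[, c("accepted", "synonym")])
  dup <- tab$synonym[duplicated(tab$synonym)]
  if (length(dup)) {
    msgs <- c(msgs, sprintf("synonym(s) mapped to multiple accepted names: %s",
                            paste(unique(dup), collapse = ", ")))
  }
  # an accepted name listed as a synonym of a *different* accepted name is a chain
  chain <- tab$synonym %in% tab$accepted & tab$synonym != tab$accepted
  if (any(chain)) {
    msgs <- c(msgs, sprintf("synonym chain(s) detected (flatten the map first): %s",
                            paste(unique(tab$synonym[chain]), collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' NicheLimitTable: per species x month x variable realized limits
#'
#' Rows of `(class, order, family, genus, species, month, variable, lower,
#' upper)` with a provenance list (reference period, quantile rule, source).
#' `variable` is `"temperature"` (degrees C) or `"aridity"` (aridity index,
#' dimensionless). `month` is an integer 1..12 for monthly rows; the value
#' `0` marks a year-average ("ALL") row as produced by
#' [yearAverageLimits()]. The validity method enforces `lower <= upper`
#' where both are present and at most one row per
#' `(species, month, variable)`.
#'
#' @seealso [NicheLimitTable()], [estimateLimits()], [speciesLimits()]
#' @export
setClass("NicheLimitTable",
         representation(limits = "data.frame", provenance = "list"))

.limit_cols <- c("class", "order", "family", "genus", "species",
                 "month", "variable", "lower", "upper")

setValidity("NicheLimitTable", function(object) {
  df <- object@limits
  miss <- setdiff(.limit_cols, colnames(df))
  if (length(miss)) {
    return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  }
  msgs <- character()
  if (nrow(df)) {
    if (!all(df$month %in% 0:12)) {
      msgs <- c(msgs, "month must be in 1..12 (0 marks a year-average row)")
    }
    if (!all(df$variable %in% c("temperature", "aridity"))) {
      msgs <- c(msgs, "variable must be 'temperature' or 'aridity'")
    }
    bad <- !is.na(df$lower) & !is.na(df$upper) & df$lower > df$upper
    if (any(bad)) {
      msgs <- c(msgs, sprintf("%d row(s) with lower > upper", sum(bad)))
    }
    key <- paste(df$species, df$month, df$variable)
    if (anyDuplicated(key)) {
      msgs <- c(msgs, "duplicate (species, month, variable) rows")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' SpeciesGeometry: where a species is sampled
#'
#' Either a set of lon/lat polygons (a range map) or a set of lon/lat
#' occurrence points, tagged with the species binomial. Polygons are stored
#' as a list of data frames with `lon`/`lat` vertex columns; points as a
#' single data frame with `lon`/`lat` columns.
#'
#' @seealso [SpeciesGeometry()], [cellsForGeometry()], [readSpeciesGeometry()]
#' @export
setClass("SpeciesGeometry",
         representation(species = "character", kind = "character",
                        geometry = "list"))

setValidity("SpeciesGeometry", function(object) {
  msgs <- character()
  if (length(object@species) != 1L || is.na(object@species) ||
      !nzchar(object@species)) {
    msgs <- c(msgs, "species must be a single non-empty binomial")
  }
  if (!object@kind %in% c("polygons", "points")) {
    msgs <- c(msgs, "kind must be 'polygons' or 'points'")
  }
  g <- object@geometry
  if (!length(g)) {
    msgs <- c(msgs, "geometry must contain at least one polygon or point")
  } else {
    ok <- vapply(g, function(p) {
      is.data.frame(p) && all(c("lon", "lat") %in% colnames(p)) && nrow(p) > 0
    }, logical(1))
    if (!all(ok)) {
      msgs <- c(msgs, "each geometry element must be a data.frame with lon/lat rows")
    } else if (object@kind == "polygons") {
      if (any(vapply(g, nrow, integer(1)) < 3L)) {
        msgs <- c(msgs, "polygons need at least 3 vertices")
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})
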