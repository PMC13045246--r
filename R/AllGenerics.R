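#' Cell-center coordinates of a climate cube
#'
#' @param x a [ClimateCube-class]
#' @return a data.frame with one row per grid cell and columns `lon`, `lat`
#'   (cell centers, degrees).
#' @export
setGeneric("cellCoords", function(x) standardGeneric("cellCoords"))

#' Time axis of a climate cube
#'
#' @param x a [ClimateCube-class]
#' @return a data.frame with one row per time step and columns `year`,
#'   `month`, in strictly increasing calendar order.
#' @export
setGeneric("cubeTime", function(x) standardGeneric("cubeTime"))

#' Grid cell size in degrees
#'
#' @param x a [ClimateCube-class]
#' @return a single positive number (degrees).
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' Limit rows of a NicheLimitTable
#'
#' @param x a [NicheLimitTable-class]
#' @return the underlying data.frame of limit rows (columns class, order,
#'   family, genus, species, month, variable, lower, upper).
#' @export
setGeneric("limitsData", function(x) standardGeneric("limitsData"))

#' Provenance of a NicheLimitTable
#'
#' @param x a [NicheLimitTable-class]
#' @return the provenance list (reference period, quantile rule, source).
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Accepted/synonym pairs of a SynonymMap
#'
#' @param x a [SynonymMap-class]
#' @return a data.frame with columns `accepted` and `synonym`, both in
#'   canonical binomial form.
#' @export
setGeneric("synonymPairs", function(x) standardGeneric("synonymPairs"))

#' Species of a SpeciesGeometry
#'
#' @param x a [SpeciesGeometry-class]
#' @return the species binomial (length-1 character).
#' @export
setGeneric("geometrySpecies", function(x) standardGeneric("geometrySpecies"))

#' Kind of a SpeciesGeometry
#'
#' @param x a [SpeciesGeometry-class]
#' @return `"polygons"` or `"points"`.
#' @export
setGeneric("geometryKind", function(x) standardGeneric("geometryKind"))
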