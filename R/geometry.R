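#' Construct a SpeciesGeometry
#'
#' @param species species binomial (canonicalized on construction).
#' @param polygons a list of data.frames with `lon`/`lat` vertex columns
#'   (a range-map polygon set), or `NULL`.
#' @param points a data.frame with `lon`/`lat` columns (occurrence points),
#'   or `NULL`. Exactly one of `polygons`/`points` must be supplied.
#' @return a [SpeciesGeometry-class]
#' @examples
#' SpeciesGeometry("Testus alpha",
#'                 points = data.frame(lon = c(1, 2), lat = c(3, 4)))
#' @export
SpeciesGeometry <- function(species, polygons = NULL, points = NULL) {
  if (is.null(polygons) == is.null(points)) {
    stop("supply exactly one of 'polygons' or 'points'")
  }
  species <- canonicalizeBinomial(species)
  if (!is.null(polygons)) {
    if (is.data.frame(polygons)) polygons <- list(polygons)
    methods::new("SpeciesGeometry", species = species, kind = "polygons",
                 geometry = lapply(polygons, function(p)
                   data.frame(lon = as.numeric(p$lon), lat = as.numeric(p$lat))))
  } else {
    methods::new("SpeciesGeometry", species = species, kind = "points",
                 geometry = list(data.frame(lon = as.numeric(points$lon),
                                            lat = as.numeric(points$lat))))
  }
}

#' @rdname geometrySpecies
#' @export
setMethod("geometrySpecies", "SpeciesGeometry", function(x) x@species)

#' @rdname geometryKind
#' @export
setMethod("geometryKind", "SpeciesGeometry", function(x) x@kind)

setMethod("show", "SpeciesGeometry", function(object) {
  n <- if (object@kind == "polygons") length(object@geometry)
       else nrow(object@geometry[[1]])
  cat(sprintf("SpeciesGeometry: %s (%s, n = %d)\n",
              object@species, object@kind, n))
})

#' Read species geometries from GeoJSON polygons or a points CSV
#'
#' Dispatches on extension: `.geojson`/`.json` files are parsed as a
#' GeoJSON FeatureCollection of Polygon/MultiPolygon features (lon/lat
#' coordinates; the species binomial is taken from the feature's
#' `properties$species`); `.csv` files are occurrence points with columns
#' `species`, `lon`, `lat`. One [SpeciesGeometry-class] is returned per
#' species found.
#'
#' @param path file path.
#' @return a named list of [SpeciesGeometry-class] objects, keyed by
#'   canonical species binomial.
#' @export
readSpeciesGeometry <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("geojson", "json")) {
    .read_geojson_polygons(path)
  } else if (ext == "csv") {
    pts <- read.csv(path)
    stopifnot(all(c("species", "lon", "lat") %in% colnames(pts)))
    pts$species <- canonicalizeBinomial(pts$species)
    out <- lapply(split(pts, pts$species), function(d)
      SpeciesGeometry(d$species[1], points = d[, c("lon", "lat")]))
    out[sort(names(out))]
  } else {
    stop("unsupported geometry file extension '.", ext,
         "'; use .geojson/.json (polygons) or .csv (points)")
  }
}

.read_geojson_polygons <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection")
  }
  ring_to_df <- function(ring) {
    data.frame(lon = vapply(ring, function(xy) as.numeric(xy[[1]]), numeric(1)),
               lat = vapply(ring, function(xy) as.numeric(xy[[2]]), numeric(1)))
  }
  by_species <- list()
  for (feat in gj$features) {
    sp <- feat$properties$species
    if (is.null(sp)) stop("feature without a 'species' property")
    geom <- feat$geometry
    rings <- switch(geom$type,
      Polygon = list(geom$coordinates[[1]]),           # outer ring only
      MultiPolygon = lapply(geom$coordinates, `[[`, 1L),
      stop("unsupported GeoJSON geometry type '", geom$type, "'"))
    sp <- canonicalizeBinomial(sp)
    by_species[[sp]] <- c(by_species[[sp]], lapply(rings, ring_to_df))
  }
  out <- lapply(names(by_species), function(sp)
    SpeciesGeometry(sp, polygons = by_species[[sp]]))
  names(out) <- names(by_species)
  out[sort(names(out))]
}

#' Write point geometries to CSV
#'
#' @param geoms a list of point-kind [SpeciesGeometry-class] objects.
#' @param path output CSV path (columns `species`, `lon`, `lat`).
#' @return the path, invisibly.
#' @export
writeSpeciesPoints <- function(geoms, path) {
  if (methods::is(geoms, "SpeciesGeometry")) geoms <- list(geoms)
  rows <- do.call(rbind, lapply(geoms, function(g) {
    stopifnot(geometryKind(g) == "points")
    cbind(species = geometrySpecies(g), g@geometry[[1]])
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
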