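#' Parse and canonicalize species binomials
#'
#' The canonical form of a binomial is `"Genus epithet"`: whitespace
#' trimmed and collapsed to a single internal space, genus capitalized,
#' epithet lower-cased. Canonicalization is idempotent. Strings that do not
#' contain exactly two tokens (a bare genus, or a trinomial) keep their
#' genus but get an empty epithet and are marked incomplete so downstream
#' matching reports them unmatched instead of erroring.
#'
#' @param names character vector of raw submitted names.
#' @return `parseBinomial()`: a data.frame with columns `raw`, `genus`,
#'   `epithet`, `canonical`, `complete`; `canonicalizeBinomial()`: the
#'   `canonical` column only.
#' @examples
#' canonicalizeBinomial(" poecile  atricapillus ")  # "Poecile atricapillus"
#' parseBinomial("Empidonax")$complete              # FALSE (bare genus)
#' @export
parseBinomial <- function(names) {
  if (!length(names)) {
    return(data.frame(raw = character(), genus = character(),
                      epithet = character(), canonical = character(),
                      complete = logical()))
  }
  names <- as.character(names)
  squeezed <- gsub("\\s+", " ", trimws(names))
  if (any(is.na(squeezed)) || any(!nzchar(squeezed))) {
    stop("empty or missing binomial string(s) at position(s): ",
         paste(which(is.na(squeezed) | !nzchar(squeezed)), collapse = ", "))
  }
  cap <- function(x) paste0(toupper(substring(x, 1, 1)), tolower(substring(x, 2)))
  tokens <- strsplit(squeezed, " ", fixed = TRUE)
  genus <- cap(vapply(tokens, `[`, character(1), 1L))
  complete <- lengths(tokens) == 2L
  epithet <- ifelse(complete,
                    tolower(vapply(tokens, function(t) t[min(2L, length(t))],
                                   character(1))),
                    "")
  canonical <- ifelse(complete, paste(genus, epithet), genus)
  data.frame(raw = names, genus = genus, epithet = epithet,
             canonical = canonical, complete = complete)
}

#' @rdname parseBinomial
#' @export
canonicalizeBinomial <- function(names) {
  parseBinomial(names)$canonical
}

#' Construct a SynonymMap
#'
#' Canonicalizes both columns, drops duplicate pairs and pairs where the
#' synonym equals its accepted name, and validates: a synonym may point to
#' only one accepted name, and synonym chains (an accepted name listed as a
#' synonym of a different accepted name) are rejected — maps must be
#' flattened before loading.
#'
#' @param pairs a data.frame with columns `accepted` and `synonym` (one
#'   pair per row) — or `accepted_name`/`synonym` as in the CSV interface.
#' @return a [SynonymMap-class]
#' @examples
#' SynonymMap(data.frame(accepted = "Poecile atricapillus",
#'                       synonym  = "Parus atricapillus"))
#' @export
SynonymMap <- function(pairs) {
  if ("accepted_name" %in% colnames(pairs) && !"accepted" %in% colnames(pairs)) {
    colnames(pairs)[colnames(pairs) == "accepted_name"] <- "accepted"
  }
  stopifnot(all(c("accepted", "synonym") %in% colnames(pairs)))
  m <- data.frame(accepted = canonicalizeBinomial(pairs$accepted),
                  synonym = canonicalizeBinomial(pairs$synonym))
  m <- unique(m[m$accepted != m$synonym, , drop = FALSE])
  rownames(m) <- NULL
  methods::new("SynonymMap", map = m)
}

#' @rdname synonymPairs
#' @export
setMethod("synonymPairs", "SynonymMap", function(x) x@map)

setMethod("show", "SynonymMap", function(object) {
  m <- object@map
  cat(sprintf("SynonymMap: %d synonym pair(s), %d accepted name(s)\n",
              nrow(m), length(unique(m$accepted))))
})

#' Read / write a SynonymMap as CSV
#'
#' CSV interface: columns `accepted_name`, `synonym`, one pair per row.
#'
#' @param path CSV file path.
#' @param map a [SynonymMap-class] (for writing).
#' @return `readSynonymMap()` a validated [SynonymMap-class];
#'   `writeSynonymMap()` the path, invisibly.
#' @export
readSynonymMap <- function(path) {
  SynonymMap(read.csv(path))
}

#' @rdname readSynonymMap
#' @export
writeSynonymMap <- function(map, path) {
  m <- synonymPairs(map)
  write.csv(data.frame(accepted_name = m$accepted, synonym = m$synonym),
            path, row.names = FALSE)
  invisible(path)
}

.table_species <- function(table) {
  if (methods::is(table, "NicheLimitTable")) table <- limitsData(table)
  stopifnot(is.data.frame(table), "species" %in% colnames(table))
  unique(canonicalizeBinomial(table$species))
}

#' Check submitted binomials against a limit table
#'
#' Compares each submitted name, after canonicalization, with the accepted
#' species names of a [NicheLimitTable-class] by exact equality — no
#' synonym logic and no spelling correction. One report row per input, in
#' input order.
#'
#' @param names character vector of submitted binomials.
#' @param table a [NicheLimitTable-class] (or a data.frame with a
#'   `species` column) defining the accepted names.
#' @return a data.frame with columns `submitted` (the raw input) and
#'   `matched` (logical).
#' @examples
#' tab <- data.frame(species = "Poecile atricapillus")
#' checkBinomials(c("Poecile atricapillus", "Parus atricapillus"), tab)$matched
#' @export
checkBinomials <- function(names, table) {
  accepted <- .table_species(table)
  if (!length(accepted)) stop("the limit table contains no species")
  p <- parseBinomial(names)
  data.frame(submitted = p$raw,
             matched = p$complete & p$canonical %in% accepted)
}

#' Resolve submitted binomials through a synonym map
#'
#' For each submitted name: an exact match against the table's accepted
#' names resolves to itself; otherwise, if the name is a known synonym
#' whose accepted name is present in the table, it resolves to that
#' accepted name; otherwise it is reported unmatched with an empty
#' `resolved` field. No fuzzy matching: misspellings stay unmatched.
#' Resolution is idempotent — resolving already-resolved names changes
#' nothing.
#'
#' @inheritParams checkBinomials
#' @param map a [SynonymMap-class].
#' @return a data.frame with columns `submitted`, `matched` (logical) and
#'   `resolved` (canonical accepted binomial, or `""` when unmatched).
#' @examples
#' tab <- data.frame(species = "Poecile atricapillus")
#' sm <- SynonymMap(data.frame(accepted = "Poecile atricapillus",
#'                             synonym  = "Parus atricapillus"))
#' resolveSynonyms("Parus atricapillus", sm, tab)$resolved
#' @export
resolveSynonyms <- function(names, map, table) {
  stopifnot(methods::is(map, "SynonymMap"))
  accepted <- .table_species(table)
  p <- parseBinomial(names)
  m <- synonymPairs(map)
  via_syn <- m$accepted[match(p$canonical, m$synonym)]
  resolved <- ifelse(p$complete & p$canonical %in% accepted, p$canonical,
                     ifelse(p$complete & !is.na(via_syn) & via_syn %in% accepted,
                            via_syn, ""))
  data.frame(submitted = p$raw, matched = nzchar(resolved), resolved = resolved)
}

#' List all species taxonomies in a limit table
#'
#' @param table a [NicheLimitTable-class] or compatible data.frame.
#' @return a data.frame of unique `(class, order, family, genus, species)`
#'   rows, sorted lexicographically; zero rows for an empty table.
#' @export
speciesList <- function(table) {
  if (methods::is(table, "NicheLimitTable")) table <- limitsData(table)
  cols <- c("class", "order", "family", "genus", "species")
  stopifnot(all(cols %in% colnames(table)))
  out <- unique(table[, cols, drop = FALSE])
  out <- out[do.call(order, out), , drop = FALSE]
  rownames(out) <- NULL
  out
}
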