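#' Parse month tokens
#'
#' Accepts integers 1..12 or case-insensitive 3-letter English
#' abbreviations (`"Jan"`, `"dec"`, ...). Anything else — full month names,
#' 0, 13, misspelt abbreviations — errors with the accepted forms listed.
#' Duplicate tokens collapse to one month.
#'
#' @param tokens vector of month identifiers (numeric or character).
#' @return an integer vector of unique month indices in 1..12, in first
#'   appearance order.
#' @examples
#' parseMonth(c("Jan", "dec", 12))  # 1 12
#' @export
parseMonth <- function(tokens) {
  if (!length(tokens)) stop("no month tokens supplied")
  one <- function(tok) {
    if (is.numeric(tok) ||
        (is.character(tok) && grepl("^\\s*-?\\d+\\s*$", tok))) {
      m <- as.numeric(tok)
      if (is.finite(m) && m == round(m) && m >= 1 && m <= 12) return(as.integer(m))
    } else if (is.character(tok)) {
      hit <- match(tolower(trimws(tok)), tolower(month.abb))
      if (!is.na(hit)) return(hit)
    }
    stop("unrecognized month token '", tok, "'; accepted forms are integers ",
         "1-12 or 3-letter abbreviations (", paste(month.abb, collapse = ", "), ")")
  }
  unique(vapply(as.list(tokens), one, integer(1)))
}

.filter_limits <- function(df, species, variables, months) {
  df[df$species %in% species & df$variable %in% variables &
       df$month %in% months, , drop = FALSE]
}

#' Extract niche limits for a list of species
#'
#' Filters a limit table down to the requested species, variables and
#' months. By default both variables and all 12 months are returned. With
#' `yr_avg = TRUE`, one year-average row (month `"ALL"`, see
#' [yearAverageLimits()]) per species x variable is appended, computed over
#' all 12 monthly rows regardless of the `months` filter. Species absent
#' from the table are reported in a warning, not an error, so batch
#' workflows survive partial matches.
#'
#' @param table a [NicheLimitTable-class]
#' @param species character vector of binomials (canonicalized before
#'   matching).
#' @param variables subset of `c("temperature", "aridity")`; must be
#'   non-empty.
#' @param months month tokens for [parseMonth()]; default all 12.
#' @param yr_avg logical; append year-average rows.
#' @return a [NicheLimitTable-class] with the selected rows.
#' @export
speciesLimits <- function(table, species,
                          variables = c("temperature", "aridity"),
                          months = 1:12, yr_avg = FALSE) {
  stopifnot(methods::is(table, "NicheLimitTable"))
  if (!length(variables)) stop("variables must be a non-empty subset of temperature/aridity")
  variables <- match.arg(variables, c("temperature", "aridity"), several.ok = TRUE)
  months <- parseMonth(months)
  species <- unique(canonicalizeBinomial(species))
  df <- limitsData(table)
  absent <- setdiff(species, unique(df$species))
  if (length(absent)) {
    warning("species not found in the limit table: ",
            paste(absent, collapse = ", "))
  }
  out <- .filter_limits(df, species, variables, months)
  if (yr_avg) {
    monthly <- .filter_limits(df, species, variables, 1:12)
    if (nrow(monthly)) {
      avg <- yearAverageLimits(
        NicheLimitTable(monthly, provenance = provenance(table)))
      out <- rbind(out, limitsData(avg))
    }
  }
  rownames(out) <- NULL
  NicheLimitTable(out, provenance = provenance(table))
}

#' Extract niche limits for higher taxonomic groups
#'
#' Selects every species whose taxonomy matches any of the requested names
#' at the given level (`"class"`, `"order"`, `"family"` or `"genus"`), then
#' behaves exactly like [speciesLimits()]; the result equals the union of
#' per-species queries over the group members.
#'
#' @inheritParams speciesLimits
#' @param level one of `"class"`, `"order"`, `"family"`, `"genus"`.
#' @param names character vector of taxon names at that level
#'   (case-insensitive).
#' @return a [NicheLimitTable-class]
#' @export
higherTaxaLimits <- function(table, level, names,
                             variables = c("temperature", "aridity"),
                             months = 1:12, yr_avg = FALSE) {
  stopifnot(methods::is(table, "NicheLimitTable"))
  level <- match.arg(level, c("class", "order", "family", "genus"))
  df <- limitsData(table)
  hit <- tolower(df[[level]]) %in% tolower(names)
  member_species <- unique(df$species[hit])
  found_names <- unique(tolower(df[[level]]))
  absent <- setdiff(tolower(names), found_names)
  if (length(absent)) {
    warning(level, " name(s) not found in the limit table: ",
            paste(absent, collapse = ", "))
  }
  if (!length(member_species)) {
    empty <- df[0, , drop = FALSE]
    return(NicheLimitTable(empty, provenance = provenance(table)))
  }
  withCallingHandlers(
    speciesLimits(table, member_species, variables = variables,
                  months = months, yr_avg = yr_avg),
    warning = function(w) {
      # member species come from the table itself; suppress only the
      # species-not-found warning, pass everything else through
      if (grepl("not found in the limit table", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}
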