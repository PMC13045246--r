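#' Position index: rescale a value between niche limits
#'
#' The position index of an environmental measure `N_i` between
#' species-specific lower and upper niche limits `N_min`, `N_max` is
#' `(N_i - N_min) / (N_max - N_min)`: 0 at the lower limit, 1 at the upper
#' limit. Values below 0 or above 1 are returned as-is — they are
#' meaningful, indicating conditions beyond the species' realized niche.
#' Degenerate limits (`N_max == N_min`) make the ratio undefined; the
#' result is `NA`, never an infinity (callers flag it, see [tpi()]).
#'
#' @param value numeric, the environmental measure (degrees C or aridity
#'   index).
#' @param lower,upper numeric niche limits; recycled against `value`.
#' @return numeric vector of indices.
#' @examples
#' positionIndex(10, 10, 30)   # 0
#' positionIndex(30, 10, 30)   # 1
#' positionIndex(35, 10, 30)   # 1.25 (beyond the upper limit)
#' @export
positionIndex <- function(value, lower, upper) {
  n <- max(length(value), length(lower), length(upper))
  value <- rep_len(as.numeric(value), n)
  lower <- rep_len(as.numeric(lower), n)
  upper <- rep_len(as.numeric(upper), n)
  width <- upper - lower
  ifelse(!is.na(width) & width != 0, (value - lower) / width, NA_real_)
}

#' Average position indices over t units
#'
#' Arithmetic mean over the available (non-missing) per-unit indices, e.g.
#' over the 12 months of a year; the count of contributing units is
#' reported alongside.
#'
#' @param pis numeric vector of per-unit position indices.
#' @return a list with `pi` (the mean, `NA` if no unit contributed) and
#'   `n` (number of contributing units). All-missing input warns.
#' @examples
#' averagePI(c(0, 1))  # pi = 0.5, n = 2
#' @export
averagePI <- function(pis) {
  ok <- !is.na(pis)
  if (!any(ok)) {
    warning("no non-missing position indices to average")
    return(list(pi = NA_real_, n = 0L))
  }
  list(pi = mean(pis[ok]), n = sum(ok))
}

.flag_cols <- c("bad_binomial", "bad_month", "bad_value",
                "degenerate_limits", "out_of_range")

# shared scoring engine behind tpi()/api(): join observations to limits on
# (canonical species, month, variable), compute per-row position indices,
# set validity flags
.score_positions <- function(obs, limits, variable, value_cols,
                             convert = identity, allow_negative = TRUE,
                             synonyms = NULL, emit_flags = TRUE) {
  stopifnot(is.data.frame(obs), all(c("species", "month") %in% colnames(obs)))
  missing_cols <- setdiff(value_cols, colnames(obs))
  if (length(missing_cols)) {
    stop("observation table lacks value column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ldf <- limitsData(limits)
  ldf <- ldf[ldf$variable == variable & ldf$month %in% 1:12, , drop = FALSE]
  if (!nrow(ldf)) stop("limit table contains no ", variable, " rows")

  sp <- canonicalizeBinomial(obs$species)
  if (!is.null(synonyms)) {
    res <- resolveSynonyms(obs$species, synonyms, limits)
    changed <- res$matched & res$resolved != sp
    if (any(changed)) {
      msg <- unique(paste(sp[changed], "->", res$resolved[changed]))
      message("resolved ", sum(changed), " observation(s) through synonyms: ",
              paste(msg, collapse = "; "))
      sp[changed] <- res$resolved[changed]
    }
  }
  month <- suppressWarnings(as.integer(obs$month))
  bad_month_token <- is.na(month) | month < 1 | month > 12

  bad_binomial <- !(sp %in% unique(ldf$species))
  hit <- match(paste(sp, month), paste(ldf$species, ldf$month))
  lower <- ldf$lower[hit]
  upper <- ldf$upper[hit]
  no_join <- !bad_binomial & !bad_month_token &
    (is.na(hit) | is.na(lower) | is.na(upper))
  bad_month <- bad_month_token | no_join

  vals <- vapply(value_cols, function(col) convert(obs[[col]]),
                 numeric(nrow(obs)))
  vals <- matrix(vals, nrow = nrow(obs))
  bad_each <- !is.finite(vals)
  if (!allow_negative) bad_each <- bad_each | (is.finite(vals) & vals < 0)
  bad_value <- apply(bad_each, 1L, all)
  vals[bad_each] <- NA_real_

  degenerate <- !bad_binomial & !bad_month & !is.na(hit) &
    !is.na(lower) & !is.na(upper) & lower == upper
  blocking <- bad_binomial | bad_month | bad_value | degenerate

  pi_mat <- positionIndex(vals, lower, upper)
  pi_mat <- matrix(pi_mat, nrow = nrow(obs))
  pi <- rowMeans(pi_mat, na.rm = TRUE)
  pi[!is.finite(pi)] <- NA_real_
  pi[blocking] <- NA_real_
  out_of_range <- !is.na(pi) & (pi < 0 | pi > 1)

  out <- obs
  out$pi <- pi
  if (emit_flags) {
    out$bad_binomial <- bad_binomial
    out$bad_month <- bad_month
    out$bad_value <- bad_value
    out$degenerate_limits <- degenerate
    out$out_of_range <- out_of_range
    out
  } else {
    out <- out[!blocking, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
}

#' Thermal Position Index (TPI) for an observation table
#'
#' Joins each observation to its species' monthly *temperature* niche
#' limits and rescales the observed temperature between them (see
#' [positionIndex()]). Observed temperatures are converted to degrees C
#' first when `tmp_unit` is `"F"` or `"K"` — an invalid unit errors before
#' any row is processed. When a [SynonymMap-class] is supplied,
#' observation binomials are resolved to the table's accepted names before
#' the join (resolutions are logged via `message()`).
#'
#' Validity flags, emitted as logical columns when `emit_flags = TRUE`:
#' `bad_binomial` (species absent from the temperature limits, after
#' synonym resolution), `bad_month` (month not 1..12, or no usable limit
#' row for that species-month), `bad_value` (missing/non-finite
#' measurement), `degenerate_limits` (upper limit equals lower limit),
#' `out_of_range` (index below 0 or above 1 — informative, the index is
#' still reported: such conditions exceed the species' realized niche).
#' Every row gets either an index or at least one blocking flag. With
#' `emit_flags = FALSE` the flag columns are dropped and rows that could
#' not be scored are excluded from the output.
#'
#' @param obs a data.frame with columns `species`, `month`, and the
#'   measurement column(s); extra columns (site, year, abundance, ...) pass
#'   through untouched.
#' @param limits a [NicheLimitTable-class] containing temperature rows.
#' @param tmp_unit temperature unit of the observations: `"C"` (default),
#'   `"F"` or `"K"`.
#' @param tmp_var name(s) of the measurement column(s). `NULL` (default)
#'   means the single column `"temperature"` (or `"value"` if absent).
#'   When several columns are named, a per-column index is computed and the
#'   row's TPI is their mean over non-missing columns ([averagePI()]
#'   semantics).
#' @param synonyms optional [SynonymMap-class] used to resolve binomials
#'   before the join.
#' @param emit_flags logical; see Details.
#' @return the input data.frame with a `pi` column appended (and the flag
#'   columns when `emit_flags = TRUE`).
#' @examples
#' lim <- NicheLimitTable(data.frame(species = "Testus alpha", month = 1:12,
#'                                   variable = "temperature",
#'                                   lower = 0, upper = 10))
#' obs <- data.frame(species = "Testus alpha", month = 6, temperature = 5)
#' tpi(obs, lim)$pi  # 0.5
#' @export
tpi <- function(obs, limits, tmp_unit = "C", tmp_var = NULL,
                synonyms = NULL, emit_flags = TRUE) {
  if (length(tmp_unit) != 1L || !toupper(tmp_unit) %in% c("C", "F", "K")) {
    stop("unknown temperature unit '", paste(tmp_unit, collapse = ","),
         "'; accepted units are \"C\", \"F\", \"K\"")
  }
  if (is.null(tmp_var)) {
    tmp_var <- if ("temperature" %in% colnames(obs)) "temperature" else "value"
  }
  .score_positions(obs, limits, variable = "temperature",
                   value_cols = tmp_var,
                   convert = function(v) toCelsius(v, tmp_unit),
                   allow_negative = TRUE,
                   synonyms = synonyms, emit_flags = emit_flags)
}

#' Aridity Position Index (API) for an observation table
#'
#' As [tpi()], but against the *aridity* niche limits and without unit
#' conversion: observation values are aridity indices (monthly
#' precipitation over potential evapotranspiration, dimensionless).
#' Negative aridity values are impossible and get the `bad_value` flag.
#'
#' @inheritParams tpi
#' @param ar_var name(s) of the measurement column(s); `NULL` means the
#'   single column `"aridity"` (or `"value"` if absent). Multiple columns
#'   are averaged as in [tpi()].
#' @return the input data.frame with a `pi` column appended (and flag
#'   columns when `emit_flags = TRUE`).
#' @export
api <- function(obs, limits, ar_var = NULL, synonyms = NULL,
                emit_flags = TRUE) {
  if (is.null(ar_var)) {
    ar_var <- if ("aridity" %in% colnames(obs)) "aridity" else "value"
  }
  .score_positions(obs, limits, variable = "aridity",
                   value_cols = ar_var,
                   convert = identity, allow_negative = FALSE,
                   synonyms = synonyms, emit_flags = emit_flags)
}
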