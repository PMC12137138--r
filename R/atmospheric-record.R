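# Annual atmospheric 14CO2 series: construction, CSV I/O, linear
# extrapolation past the last measured year, and bomb-curve normalization
# of sample F14C values.

#' Construct an annual atmospheric 14CO2 record
#'
#' An atmospheric record is the annual time series of atmospheric 14CO2
#' expressed as fraction modern, used to normalize river samples to the
#' atmosphere of their collection year. Years must be contiguous (step 1)
#' and strictly increasing; every extrapolated year must follow the last
#' measured one.
#'
#' @param years Integer vector of calendar years CE (contiguous).
#' @param f14c Atmospheric F14C per year (> 0).
#' @param provenance Character vector, `"measured"` or `"extrapolated"`
#'   per year (recycled if length 1).
#' @return A data frame of class `atm_record` with columns `year`, `f14c`,
#'   `provenance`.
#' @examples
#' atmospheric_record(2014:2019, seq(1.03, 1.02, length.out = 6))
#' @export
atmospheric_record <- function(years, f14c, provenance = "measured") {
  years <- as.integer(years)
  if (length(years) == 0) stop("record must contain at least one year")
  if (length(f14c) != length(years)) stop("years and f14c lengths differ")
  if (any(diff(years) != 1L)) {
    stop("years must be strictly increasing and contiguous (step 1)")
  }
  if (any(!is.finite(f14c) | f14c <= 0)) stop("all f14c values must be > 0")
  provenance <- rep_len(as.character(provenance), length(years))
  if (!all(provenance %in% c("measured", "extrapolated"))) {
    stop("provenance must be 'measured' or 'extrapolated'")
  }
  if (any(provenance == "measured") && any(provenance == "extrapolated")) {
    last_measured <- max(years[provenance == "measured"])
    if (any(years[provenance == "extrapolated"] <= last_measured)) {
      stop("extrapolated years must follow the last measured year")
    }
  }
  structure(
    data.frame(year = years, f14c = f14c, provenance = provenance,
               stringsAsFactors = FALSE),
    class = c("atm_record", "data.frame")
  )
}

#' Read an atmospheric record from CSV
#'
#' Expects a header with columns `year` and `f14c` (an optional `sigma`
#' column is carried through, and an optional `provenance` column is
#' honoured). Sub-annual series (repeated years) are averaged to annual
#' means before construction.
#'
#' @param path Path to a CSV file (UTF-8, '.' decimal separator).
#' @return An `atm_record`.
#' @export
read_atmospheric_record <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "f14c")
  if (!all(need %in% names(d))) {
    stop("atmospheric record CSV must have columns: ", paste(need, collapse = ", "))
  }
  yr <- floor(as.numeric(d$year))
  if (anyDuplicated(yr)) {
    f <- tapply(as.numeric(d$f14c), yr, mean)
    d <- data.frame(year = as.integer(names(f)), f14c = as.numeric(f))
  }
  prov <- if ("provenance" %in% names(d)) d$provenance else "measured"
  atmospheric_record(d$year, d$f14c, prov)
}

#' Write an atmospheric record to CSV
#'
#' @param record An `atm_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_atmospheric_record <- function(record, path) {
  stopifnot(inherits(record, "atm_record"))
  utils::write.csv(as.data.frame(record), path, row.names = FALSE)
  invisible(path)
}

#' Extend an atmospheric record past its last measured year
#'
#' Appends years up to `through_year` using an ordinary least-squares line
#' fitted to the annual values of 2014-2019, the period over which the
#' post-bomb decline of atmospheric 14CO2 had flattened to a near-linear
#' trend. Appended years are tagged `"extrapolated"`; measured years are
#' never altered, and extending an already-extended record to the same year
#' is a no-op.
#'
#' @param record An `atm_record` containing all of 2014-2019.
#' @param through_year Final year of the extension (> last measured year).
#' @param fit_years Years the trend is fitted on (default 2014:2019).
#' @return The extended `atm_record`, with the fitted slope and intercept in
#'   attribute `extrapolation`.
#' @examples
#' r <- atmospheric_record(2010:2019, seq(1.05, 1.02, length.out = 10))
#' extend_record(r, 2023)
#' @export
extend_record <- function(record, through_year, fit_years = 2014:2019) {
  stopifnot(inherits(record, "atm_record"))
  through_year <- as.integer(through_year)
  measured <- record[record$provenance == "measured", , drop = FALSE]
  if (!all(fit_years %in% measured$year)) {
    stop("insufficient record: measured years ", min(fit_years), "-",
         max(fit_years), " are required for extrapolation")
  }
  last <- max(record$year)
  if (through_year <= last) {
    if (through_year <= max(measured$year)) {
      stop("through_year must exceed the last measured year")
    }
    return(record) # already covers the request: idempotent
  }
  fit_d <- measured[measured$year %in% fit_years, ]
  fit <- stats::lm(f14c ~ year, data = fit_d)
  new_years <- seq.int(last + 1L, through_year)
  new_vals <- unname(stats::predict(fit, data.frame(year = new_years)))
  if (any(new_vals <= 0)) stop("extrapolation produced non-positive F14C")
  out <- atmospheric_record(
    c(record$year, new_years),
    c(record$f14c, new_vals),
    c(record$provenance, rep("extrapolated", length(new_years)))
  )
  attr(out, "extrapolation") <- list(
    method = "OLS on annual means",
    fit_years = fit_years,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1])
  )
  out
}

#' Look up atmospheric F14C for given years
#'
#' @param record An `atm_record`.
#' @param year Integer vector of years; every year must be covered by the
#'   record (no silent clamping).
#' @return Numeric vector of atmospheric F14C values.
#' @export
atm_value_at <- function(record, year) {
  stopifnot(inherits(record, "atm_record"))
  idx <- match(as.integer(year), record$year)
  if (anyNA(idx)) {
    bad <- unique(year[is.na(idx)])
    stop("year(s) outside atmospheric record: ", paste(bad, collapse = ", "),
         " (record covers ", min(record$year), "-", max(record$year), ")")
  }
  record$f14c[idx]
}

#' Normalize a sample to the atmosphere of its collection year
#'
#' Computes `F14C_atm = Fm_sample / Fm_atmosphere`, the sample's fraction
#' modern divided by the atmospheric 14CO2 F14C of its collection year.
#' This removes the imprint of the bomb-curve on samples collected in
#' different years, so values can be compared across decades.
#'
#' @param sample A `radiocarbon_value`, or a numeric F14C (then `year` is
#'   required).
#' @param record An `atm_record` covering the collection year.
#' @param year Collection year when `sample` is a bare numeric.
#' @return A list of class `normalized_value`: `f14c_atm`, `source_year`,
#'   `record_provenance`.
#' @examples
#' r <- atmospheric_record(2000:2005, rep(1.25, 6))
#' normalize_f14c(1.0, r, year = 2003)$f14c_atm # 0.8
#' @export
normalize_f14c <- function(sample, record, year = NULL) {
  if (inherits(sample, "radiocarbon_value")) {
    f14c <- sample$f14c
    year <- sample$year_collected
  } else {
    stopifnot(is.numeric(sample))
    if (is.null(year)) stop("year is required for a bare numeric sample")
    f14c <- sample
  }
  atm <- atm_value_at(record, year)
  idx <- match(as.integer(year), record$year)
  structure(
    list(
      f14c_atm = f14c / atm,
      source_year = as.integer(year),
      record_provenance = record$provenance[idx]
    ),
    class = "normalized_value"
  )
}

#' Linear trend of normalized F14C against year
#'
#' Ordinary least-squares fit of bomb-curve-normalized F14C values on the
#' calendar year of collection, with the usual t-test on the slope. Used to
#' ask whether rivers track, lead or lag the atmospheric decline.
#'
#' @param year Numeric vector of collection years (>= 3 distinct values).
#' @param f14c_atm Numeric vector of normalized values, same length.
#' @return A list with `slope` (per year), `intercept`, `r_squared`,
#'   `p_value`, `slope_se` and `n`.
#' @export
trend_f14c_atm <- function(year, f14c_atm) {
  stopifnot(is.numeric(year), is.numeric(f14c_atm),
            length(year) == length(f14c_atm))
  keep <- is.finite(year) & is.finite(f14c_atm)
  year <- year[keep]; f14c_atm <- f14c_atm[keep]
  if (length(unique(year)) < 3) {
    stop("degenerate fit: need >= 3 distinct years with non-zero variance")
  }
  fit <- stats::lm(f14c_atm ~ year)
  s <- summary(fit)
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = s$r.squared,
    p_value = unname(s$coefficients["year", "Pr(>|t|)"]),
    slope_se = unname(s$coefficients["year", "Std. Error"]),
    n = length(year)
  )
}
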