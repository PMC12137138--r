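# Radiocarbon unit conversions and conventional-age arithmetic.
#
# Two decay constants coexist in radiocarbon work and must never be mixed up:
#  * the "true" decay constant lambda = 1/8267 yr^-1, used when correcting
#    Delta14C for decay between collection year and 1950;
#  * the Libby mean life 8033 yr, fixed by convention for reporting
#    conventional 14C ages (age = -8033 * ln(F14C)).

#' Radiocarbon conversion constants
#'
#' Fixed constants used throughout the package: the true radiocarbon decay
#' constant (1/8,267 per year) used in the F14C/Delta14C inter-conversion,
#' the Libby mean life (8,033 years) fixed by convention for conventional
#' radiocarbon ages, and the 1950 CE reference year.
#'
#' @return A named list with elements `lambda_true`, `libby_mean_life` and
#'   `reference_year`.
#' @examples
#' rc_constants()$libby_mean_life
#' @export
rc_constants <- function() {
  list(
    lambda_true = 1 / 8267,
    libby_mean_life = 8033,
    reference_year = 1950
  )
}

#' Convert fraction modern to conventional radiocarbon age
#'
#' Computes the conventional radiocarbon age `-8033 * log(f14c)` in 14C years
#' before present. Samples with F14C > 1 post-date the 1955 bomb spike: no
#' conventional age exists for them and they are returned as `NA` and flagged
#' "modern" (see the `modern` attribute) rather than as a negative age.
#'
#' @param f14c Numeric vector of fraction-modern values (> 0).
#' @return Numeric vector of ages in 14C years; `NA` where `f14c > 1`.
#'   The logical attribute `modern` marks those entries.
#' @examples
#' f14c_to_age(c(1, 0.914, 0.961))
#' f14c_to_age(1.2) # modern, NA
#' @seealso [age_sigma()] for first-order uncertainty propagation.
#' @export
f14c_to_age <- function(f14c) {
  stopifnot(is.numeric(f14c))
  if (any(!is.na(f14c) & f14c <= 0)) {
    stop("invalid measurement: f14c must be > 0", call. = FALSE)
  }
  modern <- !is.na(f14c) & f14c > 1
  age <- -rc_constants()$libby_mean_life * log(f14c)
  age[modern] <- NA_real_
  attr(age, "modern") <- modern
  age
}

#' First-order uncertainty of a conventional age
#'
#' Delta-method propagation of an analytical F14C uncertainty onto the
#' conventional-age scale: `sigma_age = 8033 * sigma_f14c / f14c`.
#'
#' @param f14c Fraction modern (> 0).
#' @param sigma_f14c 1-sigma analytical uncertainty in fraction modern.
#' @return 1-sigma age uncertainty in 14C years.
#' @export
age_sigma <- function(f14c, sigma_f14c) {
  stopifnot(is.numeric(f14c), is.numeric(sigma_f14c))
  if (any(!is.na(f14c) & f14c <= 0)) {
    stop("invalid measurement: f14c must be > 0", call. = FALSE)
  }
  rc_constants()$libby_mean_life * sigma_f14c / f14c
}

#' Age-equivalent offset between two fraction-modern values
#'
#' The absolute difference, in conventional 14C years, between two F14C
#' values: `|8033 * (log(a) - log(b))|`. Symmetric in its arguments and
#' defined even when one or both values exceed 1 (where no conventional age
#' exists on its own), which is how paired DIC/CO2 offsets are expressed on
#' an age scale.
#'
#' @param f14c_a,f14c_b Fraction-modern values (> 0); vectors recycle.
#' @return Absolute age-equivalent offset(s) in 14C years.
#' @examples
#' age_equivalent_offset(1.0, 0.98) # ~162 yr
#' @export
age_equivalent_offset <- function(f14c_a, f14c_b) {
  stopifnot(is.numeric(f14c_a), is.numeric(f14c_b))
  if (any(!is.na(f14c_a) & f14c_a <= 0) || any(!is.na(f14c_b) & f14c_b <= 0)) {
    stop("invalid measurement: f14c must be > 0", call. = FALSE)
  }
  abs(rc_constants()$libby_mean_life * (log(f14c_a) - log(f14c_b)))
}

#' Convert fraction modern to Delta14C
#'
#' `Delta14C = 1000 * (F14C * exp(-lambda * (y - 1950)) - 1)` with
#' `lambda = 1/8267` per year: the per-mil deviation from the modern
#' standard after correcting for decay between the collection year and 1950.
#'
#' @param f14c Fraction modern (> 0).
#' @param year Calendar year of sample collection (CE). A warning is issued
#'   outside 1950-2030; the conversion itself is still performed.
#' @return Delta14C in per mil.
#' @examples
#' f14c_to_delta14c(1.0, 1950) # 0
#' f14c_to_delta14c(1.0, 2000) # about -6.03
#' @export
f14c_to_delta14c <- function(f14c, year) {
  stopifnot(is.numeric(f14c), is.numeric(year))
  if (any(!is.na(f14c) & f14c <= 0)) {
    stop("invalid measurement: f14c must be > 0", call. = FALSE)
  }
  if (any(!is.na(year) & (year < 1950 | year > 2030))) {
    warning("year outside 1950-2030; Delta14C decay correction extrapolated")
  }
  k <- rc_constants()
  1000 * (f14c * exp(-k$lambda_true * (year - k$reference_year)) - 1)
}

#' Convert Delta14C to fraction modern
#'
#' Inverse of [f14c_to_delta14c()]:
#' `F14C = ((Delta14C/1000) + 1) * exp(lambda * (y - 1950))`.
#'
#' @param delta14c Delta14C in per mil (> -1000).
#' @param year Calendar year of sample collection (CE).
#' @return Fraction modern (strictly positive).
#' @examples
#' delta14c_to_f14c(0, 1950) # 1
#' @export
delta14c_to_f14c <- function(delta14c, year) {
  stopifnot(is.numeric(delta14c), is.numeric(year))
  if (any(!is.na(delta14c) & delta14c <= -1000)) {
    stop("invalid measurement: delta14c <= -1000 implies non-positive F14C",
         call. = FALSE)
  }
  k <- rc_constants()
  ((delta14c / 1000) + 1) * exp(k$lambda_true * (year - k$reference_year))
}

#' Construct a validated radiocarbon measurement
#'
#' Bundles one measurement's isotopic state: fraction modern, analytical
#' uncertainty, collection year, and the derived Delta14C and conventional
#' age. The derived fields always satisfy the conversion identities; the age
#' is `NA` (flagged modern) when F14C > 1.
#'
#' @param f14c Fraction modern (> 0).
#' @param sigma_f14c Optional 1-sigma analytical uncertainty (>= 0).
#' @param year_collected Calendar year CE.
#' @return An object of class `radiocarbon_value`: a list with fields
#'   `f14c`, `sigma_f14c`, `year_collected`, `delta14c`, `age_14c`,
#'   `sigma_age` and the logical `modern`.
#' @examples
#' radiocarbon_value(0.914, 0.01, 2005)
#' @export
radiocarbon_value <- function(f14c, sigma_f14c = NA_real_, year_collected) {
  stopifnot(length(f14c) == 1, length(year_collected) == 1)
  if (!is.finite(f14c) || f14c <= 0) {
    stop("invalid measurement: f14c must be > 0", call. = FALSE)
  }
  if (!is.na(sigma_f14c) && sigma_f14c < 0) {
    stop("sigma_f14c must be >= 0", call. = FALSE)
  }
  age <- suppressWarnings(f14c_to_age(f14c))
  structure(
    list(
      f14c = f14c,
      sigma_f14c = sigma_f14c,
      year_collected = year_collected,
      delta14c = f14c_to_delta14c(f14c, year_collected),
      age_14c = as.numeric(age),
      sigma_age = if (is.na(sigma_f14c) || f14c > 1) NA_real_
                  else age_sigma(f14c, sigma_f14c),
      modern = f14c > 1
    ),
    class = "radiocarbon_value"
  )
}

#' @export
print.radiocarbon_value <- function(x, ...) {
  cat(sprintf("F14C %.4f", x$f14c))
  if (!is.na(x$sigma_f14c)) cat(sprintf(" +/- %.4f", x$sigma_f14c))
  cat(sprintf(" (%d CE): Delta14C %.1f permil, ", x$year_collected, x$delta14c))
  if (x$modern) cat("modern (no conventional age)\n")
  else cat(sprintf("age %d 14C yr BP\n", round(x$age_14c)))
  invisible(x)
}
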