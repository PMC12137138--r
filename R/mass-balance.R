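# Petrogenic-constrained global DIC mass balance and the Monte Carlo
# partition of river CO2 emissions into decadal, millennial and petrogenic
# sources.
#
# The chain per Monte Carlo run:
#   1. draw petrogenic flux P ~ U(low, high) and the two endmember F14C
#      values (uniform over their stated ranges);
#   2. residual F14C of the non-petrogenic pool:
#        F_resid = F_river * T / (T - P)        (petrogenic F14C = 0)
#   3. two-endmember split of the residual:
#        a_raw = (F_resid - F_mil) / (F_dec - F_mil),  b_raw = 1 - a_raw
#   4. petrogenic proportion c = P / T; final a = a_raw (1 - c),
#      b = b_raw (1 - c), so a + b + c = 1 per run.

#' Global river DIC flux budget
#'
#' Container for the global flux constants of the mass balance: lateral DIC
#' export to the ocean, vertical CO2 emission from the water surface,
#' carbonate precipitation (negligible globally, default 0), and the
#' bounds on petrogenic DIC inputs from carbonate and rock organic matter
#' weathering. All in Pg C per year.
#'
#' @param lateral_dic_export Lateral export mean (default 0.52).
#' @param lateral_sigma Its 1-sigma (default 0.17).
#' @param vertical_co2_emission Vertical emission mean (default 2.0).
#' @param vertical_sigma Its 1-sigma (default 0.2).
#' @param carbonate_precipitation Default 0.
#' @param petrogenic_low,petrogenic_high Bounds on petrogenic weathering
#'   inputs (defaults 0.150 and 0.218).
#' @return A list of class `flux_budget`; `total_dic_flux()` gives the
#'   derived total.
#' @export
flux_budget <- function(lateral_dic_export = 0.52, lateral_sigma = 0.17,
                        vertical_co2_emission = 2.0, vertical_sigma = 0.2,
                        carbonate_precipitation = 0,
                        petrogenic_low = 0.150, petrogenic_high = 0.218) {
  b <- list(
    lateral_dic_export = lateral_dic_export,
    lateral_sigma = lateral_sigma,
    vertical_co2_emission = vertical_co2_emission,
    vertical_sigma = vertical_sigma,
    carbonate_precipitation = carbonate_precipitation,
    petrogenic_low = petrogenic_low,
    petrogenic_high = petrogenic_high
  )
  if (any(unlist(b) < 0)) stop("all fluxes and sigmas must be >= 0")
  if (petrogenic_low > petrogenic_high) {
    stop("petrogenic_low must be <= petrogenic_high")
  }
  total <- lateral_dic_export + vertical_co2_emission + carbonate_precipitation
  if (petrogenic_high > 0 && petrogenic_high >= total) {
    stop("petrogenic inputs must be smaller than the total DIC flux")
  }
  structure(b, class = "flux_budget")
}

#' Total river DIC flux with quadrature uncertainty
#'
#' Sum of lateral export, vertical emission and carbonate precipitation;
#' the 1-sigma is combined in quadrature from the lateral and vertical
#' terms.
#'
#' @param budget A `flux_budget`.
#' @return List with `mean` and `sigma` (Pg C per year).
#' @examples
#' total_dic_flux(flux_budget()) # 2.52 +/- 0.26
#' @export
total_dic_flux <- function(budget) {
  stopifnot(inherits(budget, "flux_budget"))
  list(
    mean = budget$lateral_dic_export + budget$vertical_co2_emission +
      budget$carbonate_precipitation,
    sigma = sqrt(budget$lateral_sigma^2 + budget$vertical_sigma^2)
  )
}

#' Endmember F14C distributions
#'
#' The three carbon-source endmembers of the mixing model. The decadal
#' endmember is the 1950-2023 atmospheric 14CO2 distribution (recent
#' photosynthate); the millennial endmember is the carbon-weighted mean age
#' of global mineral soil carbon in the upper 0-30 cm; the petrogenic
#' endmember is 14C-dead rock carbon, F14C = 0 exactly. Ranges equal
#' mean +/- 1 sigma (to printed rounding) and are the uniform sampling
#' windows of the Monte Carlo.
#'
#' @param decadal_mean,decadal_sigma,decadal_range Decadal endmember
#'   (defaults 1.226, 0.216, c(1.011, 1.442)).
#' @param millennial_mean,millennial_sigma,millennial_range Millennial
#'   endmember (defaults 0.841, 0.033, c(0.808, 0.874)).
#' @return A list of class `endmember_set` (petrogenic fixed at 0).
#' @export
endmember_set <- function(decadal_mean = 1.226, decadal_sigma = 0.216,
                          decadal_range = c(1.011, 1.442),
                          millennial_mean = 0.841, millennial_sigma = 0.033,
                          millennial_range = c(0.808, 0.874)) {
  stopifnot(length(decadal_range) == 2, length(millennial_range) == 2,
            decadal_range[1] < decadal_range[2],
            millennial_range[1] < millennial_range[2])
  if (millennial_range[2] >= decadal_range[1]) {
    stop("endmember ranges must not overlap (millennial below decadal)")
  }
  structure(
    list(
      decadal_mean = decadal_mean, decadal_sigma = decadal_sigma,
      decadal_range = decadal_range,
      millennial_mean = millennial_mean, millennial_sigma = millennial_sigma,
      millennial_range = millennial_range,
      petrogenic = 0
    ),
    class = "endmember_set"
  )
}

#' Residual F14C of the non-petrogenic DIC pool
#'
#' Removes the 14C-dead petrogenic contribution from the bulk river signal:
#' with petrogenic F14C = 0, the isotope mass balance
#' `F_river * T = F_resid * (T - P) + 0 * P` gives
#' `F_resid = F_river * T / (T - P)`.
#'
#' @param f14c_river Bulk river F14C (fraction modern).
#' @param total_flux Total river DIC flux T (Pg C per year).
#' @param petrogenic_flux Petrogenic input P, `0 <= P < T`.
#' @return Residual (non-petrogenic) F14C.
#' @examples
#' residual_f14c(0.919, 2.5, 0.150) # ~0.978
#' residual_f14c(0.919, 2.5, 0.218) # ~1.007
#' @export
residual_f14c <- function(f14c_river, total_flux, petrogenic_flux) {
  stopifnot(is.numeric(f14c_river), is.numeric(total_flux),
            is.numeric(petrogenic_flux))
  if (any(petrogenic_flux < 0)) stop("petrogenic flux must be >= 0")
  if (any(petrogenic_flux >= total_flux)) {
    stop("mass-balance violation: petrogenic flux must be < total flux")
  }
  f14c_river * total_flux / (total_flux - petrogenic_flux)
}

#' Two-endmember mixing proportions
#'
#' Inverts the linear mixture `F = a * F_dec + b * F_mil` with `a + b = 1`
#' for the raw decadal and millennial proportions of the non-petrogenic
#' pool. Values outside [0, 1] (residual outside the endmember bracket) are
#' returned as-is and flagged, never clamped.
#'
#' @param residual Non-petrogenic F14C.
#' @param f_decadal,f_millennial Endmember F14C values (must differ).
#' @return List with `a_raw`, `b_raw` and logical `out_of_range`.
#' @export
two_endmember_proportions <- function(residual, f_decadal, f_millennial) {
  if (any(f_decadal == f_millennial)) {
    stop("degenerate mixture: endmember F14C values are equal")
  }
  a_raw <- (residual - f_millennial) / (f_decadal - f_millennial)
  list(a_raw = a_raw, b_raw = 1 - a_raw,
       out_of_range = a_raw < 0 | a_raw > 1)
}

# inverse-CDF truncated normal draw
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  p <- stats::runif(n, stats::pnorm(lower, mean, sd),
                    stats::pnorm(upper, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Monte Carlo partition of river CO2 sources
#'
#' Propagates the uncertainty of the petrogenic flux and of the two
#' endmember F14C values through the mass-balance chain (see
#' [residual_f14c()] and [two_endmember_proportions()]). Each of `n_runs`
#' runs independently draws the petrogenic flux and the decadal and
#' millennial endmember F14C values - by default uniformly over their
#' stated ranges - computes the residual, splits it between the two
#' biospheric endmembers, and rescales by one minus that run's petrogenic
#' proportion `c = P / T` so the three proportions sum to 1 exactly.
#'
#' The total DIC flux is held at its mean during the simulation; only the
#' three listed quantities vary. Fully reproducible given `seed`.
#'
#' @param budget A `flux_budget`.
#' @param endmembers An `endmember_set`.
#' @param f14c_river Bulk river F14C; default 0.919, the database mean
#'   across DIC, CO2 and CH4 (recompute from an observation set to
#'   override).
#' @param n_runs Number of runs (default 10000).
#' @param seed Integer seed (default 20250604).
#' @param distribution `"uniform"` (default) draws over the ranges;
#'   `"truncnorm"` draws a normal with the endmember mean/sigma truncated
#'   to the range (petrogenic flux stays uniform between its bounds).
#' @return An object of class `mixing_result`: list with `draws` (per-run
#'   data frame: petro_flux, f_dec, f_mil, residual, a_raw, b_raw, a, b, c,
#'   out_of_range), `summary` (data frame: source, mean, sd), `old_carbon`
#'   (mean and sd of b + c), `n_runs`, `seed`, `f14c_river`, `total_flux`,
#'   `distribution`.
#' @examples
#' mc <- monte_carlo_partition(flux_budget(), endmember_set(), n_runs = 1000)
#' mc$summary
#' @export
monte_carlo_partition <- function(budget = flux_budget(),
                                  endmembers = endmember_set(),
                                  f14c_river = 0.919,
                                  n_runs = 10000,
                                  seed = 20250604,
                                  distribution = c("uniform", "truncnorm")) {
  stopifnot(inherits(budget, "flux_budget"),
            inherits(endmembers, "endmember_set"),
            n_runs >= 1, f14c_river > 0)
  distribution <- match.arg(distribution)
  total <- total_dic_flux(budget)$mean

  old_rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_rng))
    assign(".Random.seed", old_rng, envir = globalenv()))
  set.seed(seed)

  petro <- stats::runif(n_runs, budget$petrogenic_low, budget$petrogenic_high)
  if (distribution == "uniform") {
    f_dec <- stats::runif(n_runs, endmembers$decadal_range[1],
                          endmembers$decadal_range[2])
    f_mil <- stats::runif(n_runs, endmembers$millennial_range[1],
                          endmembers$millennial_range[2])
  } else {
    f_dec <- .rtruncnorm(n_runs, endmembers$decadal_mean,
                         endmembers$decadal_sigma,
                         endmembers$decadal_range[1],
                         endmembers$decadal_range[2])
    f_mil <- .rtruncnorm(n_runs, endmembers$millennial_mean,
                         endmembers$millennial_sigma,
                         endmembers$millennial_range[1],
                         endmembers$millennial_range[2])
  }

  res <- residual_f14c(f14c_river, total, petro)
  mix <- two_endmember_proportions(res, f_dec, f_mil)
  cc <- petro / total
  a <- mix$a_raw * (1 - cc)
  b <- mix$b_raw * (1 - cc)

  draws <- data.frame(
    petro_flux = petro, f_dec = f_dec, f_mil = f_mil, residual = res,
    a_raw = mix$a_raw, b_raw = mix$b_raw, a = a, b = b, c = cc,
    out_of_range = mix$out_of_range
  )
  summ <- data.frame(
    source = c("decadal", "millennial", "petrogenic"),
    mean = c(mean(a), mean(b), mean(cc)),
    sd = c(stats::sd(a), stats::sd(b), stats::sd(cc)),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      draws = draws,
      summary = summ,
      old_carbon = list(mean = mean(b + cc), sd = stats::sd(b + cc)),
      n_runs = n_runs, seed = seed, f14c_river = f14c_river,
      total_flux = total, distribution = distribution
    ),
    class = "mixing_result"
  )
}

#' @export
print.mixing_result <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo source partition (n = %d, seed = %d, F14C_river = %.3f)\n",
    x$n_runs, x$seed, x$f14c_river))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-10s %.2f +/- %.2f\n", x$summary$source[i],
                x$summary$mean[i], x$summary$sd[i]))
  }
  cat(sprintf("  old carbon %.2f +/- %.2f\n",
              x$old_carbon$mean, x$old_carbon$sd))
  invisible(x)
}

#' Convert source proportions to vertical CO2 emission fluxes
#'
#' Multiplies the per-run source proportions by the global vertical river
#' CO2 emission flux to obtain per-source emission fluxes in Pg C per year.
#' Each run draws the emission flux from Normal(mean, sigma), so the
#' reported 1-sigma includes both the spread of the proportions and the
#' emission-flux uncertainty; the proportion-only spread (emission held at
#' its mean) is reported alongside as `sd_proportion_only`.
#'
#' @param result A `mixing_result`.
#' @param vertical_mean Global vertical CO2 emission (default 2.0 Pg C/yr).
#' @param vertical_sigma Its 1-sigma (default 0.2); set 0 for a fixed flux.
#' @param seed Seed for the emission draws (default: result seed + 1).
#' @return Data frame with rows decadal, millennial, petrogenic, old
#'   (millennial + petrogenic) and columns `mean`, `sd`,
#'   `sd_proportion_only` (Pg C per year).
#' @export
partition_to_fluxes <- function(result, vertical_mean = 2.0,
                                vertical_sigma = 0.2, seed = NULL) {
  stopifnot(inherits(result, "mixing_result"))
  if (is.null(seed)) seed <- result$seed + 1L
  old_rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_rng))
    assign(".Random.seed", old_rng, envir = globalenv()))
  set.seed(seed)
  n <- result$n_runs
  emis <- stats::rnorm(n, vertical_mean, vertical_sigma)
  p <- result$draws
  comp <- list(
    decadal = p$a, millennial = p$b, petrogenic = p$c, old = p$b + p$c
  )
  out <- do.call(rbind, lapply(names(comp), function(nm) {
    fl <- comp[[nm]] * emis
    fixed <- comp[[nm]] * vertical_mean
    data.frame(source = nm, mean = mean(fl), sd = stats::sd(fl),
               sd_proportion_only = stats::sd(fixed),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Steady-state residence-time range from a stock and a loss flux
#'
#' Bounds the turnover time of a carbon stock drained by a loss flux,
#' combining the 1-sigma bounds pessimistically:
#' `low = (stock - sigma_stock) / (flux + sigma_flux)` and
#' `high = (stock + sigma_stock) / (flux - sigma_flux)`. Display values are
#' rounded to the nearest 100 years.
#'
#' @param stock_mean,stock_sigma Carbon stock (Pg C), mean > sigma.
#' @param flux_mean,flux_sigma Loss flux (Pg C per year), mean > sigma > 0
#'   (a zero sigma degenerates to the single value stock/flux).
#' @return List with `low`, `high` (years), and `low_display`,
#'   `high_display` rounded to the nearest 100.
#' @examples
#' residence_time_range(840, 280, 1.1, 0.3) # about 400-1400 yr
#' @export
residence_time_range <- function(stock_mean, stock_sigma,
                                 flux_mean, flux_sigma) {
  stopifnot(stock_mean > 0, flux_mean > 0, stock_sigma >= 0, flux_sigma >= 0)
  if (stock_sigma >= stock_mean) stop("stock sigma must be < stock mean")
  if (flux_sigma > 0 && flux_mean - flux_sigma <= 0) {
    stop("unbounded range: flux mean must exceed its sigma")
  }
  low <- (stock_mean - stock_sigma) / (flux_mean + flux_sigma)
  high <- (stock_mean + stock_sigma) / (flux_mean - flux_sigma)
  list(low = low, high = high,
       low_display = round(low / 100) * 100,
       high_display = round(high / 100) * 100)
}
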