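# Three-endmember Bayesian source apportionment of the bulk river F14C
# signal, with no flux prior: the independent cross-check of the
# petrogenic-constrained Monte Carlo.
#
# Model: (a, b, c) on the 2-simplex with a flat Dirichlet(1,1,1) prior;
# endmember F14C values as truncated normals over their stated ranges;
# likelihood  F14C_river_obs ~ Normal(a F_dec + b F_mil + c * 0, sigma).
# Sampler: random-walk Metropolis in mixture-mean coordinates (the fitted
# mean and the petrogenic share) with per-parameter warm-up adaptation;
# convergence is policed with potential scale reduction (must be <= the
# configured limit) and effective sample size via coda.

#' Configuration for the Bayesian mixing model
#'
#' @param endmembers An [endmember_set()]; the decadal and millennial priors
#'   are normals with the set's means/sigmas truncated to the set's ranges,
#'   and the petrogenic endmember is fixed at F14C = 0.
#' @param likelihood_sigma Gaussian likelihood sigma for the observed bulk
#'   F14C (default 0.03, the order of the millennial endmember sigma);
#'   override with an observation-set standard error when available.
#' @param chains Number of chains (>= 2; default 4).
#' @param iterations Total iterations per chain (default 8000).
#' @param warmup Warm-up iterations discarded and used for proposal
#'   adaptation (default 3000).
#' @param seed Integer seed (default 20250604).
#' @param fix_petrogenic Optional fixed petrogenic proportion in [0, 1);
#'   when given, only the decadal/millennial split is sampled.
#' @param sample_endmembers Marginalize over endmember uncertainty
#'   (default TRUE); FALSE fixes them at their means.
#' @param use_likelihood FALSE drops the likelihood term, so the posterior
#'   is the prior (prior-predictive check).
#' @param rhat_limit Convergence limit on the potential scale reduction
#'   factor (default 1.05).
#' @return A list of class `bayesian_config`.
#' @export
bayesian_config <- function(endmembers = endmember_set(),
                            likelihood_sigma = 0.03,
                            chains = 4, iterations = 8000, warmup = 3000,
                            seed = 20250604,
                            fix_petrogenic = NULL,
                            sample_endmembers = TRUE,
                            use_likelihood = TRUE,
                            rhat_limit = 1.05) {
  if (chains < 2) stop("config error: chains must be >= 2")
  if (iterations <= warmup) stop("config error: iterations must exceed warmup")
  if (likelihood_sigma <= 0) stop("config error: likelihood_sigma must be > 0")
  if (!is.null(fix_petrogenic) &&
      (fix_petrogenic < 0 || fix_petrogenic >= 1)) {
    stop("config error: fix_petrogenic must be in [0, 1)")
  }
  structure(
    list(endmembers = endmembers, likelihood_sigma = likelihood_sigma,
         chains = chains, iterations = iterations, warmup = warmup,
         seed = seed, fix_petrogenic = fix_petrogenic,
         sample_endmembers = sample_endmembers,
         use_likelihood = use_likelihood, rhat_limit = rhat_limit),
    class = "bayesian_config"
  )
}

# One chain of adaptive random-walk Metropolis; returns post-warmup draws.
#
# The chain is run in mixture-mean coordinates (mu, c) rather than on raw
# proportions: mu = a F_dec + b F_mil + c * 0 is the direction the
# likelihood constrains, and c indexes the ridge of simplex points sharing
# that mu. Given the endmember values the map (mu, c) -> (a, b, c) is
# linear, so the flat Dirichlet prior stays flat (up to a 1/(F_dec - F_mil)
# factor that only matters while the endmembers are being sampled), and the
# posterior is nearly independent in the two coordinates - a geometry
# componentwise random-walk Metropolis handles well even when sigma is
# tiny.
.run_chain <- function(obs, sigma, cfg, chain_seed) {
  set.seed(chain_seed)
  em <- cfg$endmembers
  fixed_c <- !is.null(cfg$fix_petrogenic)
  samp_em <- cfg$sample_endmembers && em$decadal_sigma > 0

  # theta: mu, then c (unless fixed), then Fd, Fm (if sampled)
  i_c <- if (fixed_c) 0L else 2L
  i_em <- if (fixed_c) 1L else 2L
  start <- .rdirichlet_one()
  theta <- c(start[1] * em$decadal_mean + start[2] * em$millennial_mean,
             if (!fixed_c) start[3],
             if (samp_em) c(em$decadal_mean, em$millennial_mean))
  n_par <- length(theta)
  step <- c(max(sigma, 0.01),
            if (!fixed_c) 0.15,
            if (samp_em) c(em$decadal_sigma, em$millennial_sigma) * 0.5)

  props <- function(th) {
    fd <- if (samp_em) th[i_em + 1] else em$decadal_mean
    fm <- if (samp_em) th[i_em + 2] else em$millennial_mean
    cc <- if (fixed_c) cfg$fix_petrogenic else th[2]
    a <- (th[1] - (1 - cc) * fm - cc * em$petrogenic) / (fd - fm)
    c(a, 1 - cc - a, cc)
  }
  log_post <- function(th) {
    fd <- if (samp_em) th[i_em + 1] else em$decadal_mean
    fm <- if (samp_em) th[i_em + 2] else em$millennial_mean
    if (fd <= fm) return(-Inf)
    p <- props(th)
    if (any(p < 0) || p[3] >= 1) return(-Inf)
    # flat Dirichlet prior: constant over the simplex; the (mu, c) -> (a, c)
    # change of variables contributes 1/(fd - fm)
    lp <- -log(fd - fm)
    if (samp_em) {
      if (fd < em$decadal_range[1] || fd > em$decadal_range[2] ||
          fm < em$millennial_range[1] || fm > em$millennial_range[2]) {
        return(-Inf)
      }
      lp <- lp + stats::dnorm(fd, em$decadal_mean, em$decadal_sigma,
                              log = TRUE) +
        stats::dnorm(fm, em$millennial_mean, em$millennial_sigma, log = TRUE)
    }
    if (cfg$use_likelihood) {
      lp <- lp + sum(stats::dnorm(obs, th[1], sigma, log = TRUE))
    }
    lp
  }

  cur_lp <- log_post(theta)
  while (!is.finite(cur_lp)) { # rare: resample a feasible start
    start <- .rdirichlet_one()
    theta[1] <- start[1] * em$decadal_mean + start[2] * em$millennial_mean
    if (!fixed_c) theta[2] <- start[3]
    cur_lp <- log_post(theta)
  }
  n_keep <- cfg$iterations - cfg$warmup
  out <- matrix(NA_real_, n_keep, 5,
                dimnames = list(NULL, c("a", "b", "c", "f_dec", "f_mil")))
  acc <- numeric(n_par); tries <- numeric(n_par)
  for (it in seq_len(cfg$iterations)) {
    for (j in seq_len(n_par)) {
      prop <- theta
      prop[j] <- prop[j] + stats::rnorm(1, 0, step[j])
      lp <- log_post(prop)
      tries[j] <- tries[j] + 1
      if (log(stats::runif(1)) < lp - cur_lp) {
        theta <- prop; cur_lp <- lp; acc[j] <- acc[j] + 1
      }
    }
    # independence move from the flat Dirichlet prior: its proposal
    # density cancels the prior term exactly (the endmember values are
    # left untouched), so the acceptance ratio reduces to the likelihood
    # ratio - this kernel jumps across the whole simplex and keeps the
    # chain mixing when the random walk is pinned to a narrow ridge
    pstar <- .rdirichlet_one()
    prop <- theta
    if (fixed_c) {
      c0 <- cfg$fix_petrogenic
      u <- pstar[1] / (pstar[1] + pstar[2])
      pstar <- c((1 - c0) * u, (1 - c0) * (1 - u), c0)
    }
    fd <- if (samp_em) theta[i_em + 1] else em$decadal_mean
    fm <- if (samp_em) theta[i_em + 2] else em$millennial_mean
    prop[1] <- pstar[1] * fd + pstar[2] * fm + pstar[3] * em$petrogenic
    if (!fixed_c) prop[2] <- pstar[3]
    if (cfg$use_likelihood) {
      ll_ratio <- sum(stats::dnorm(obs, prop[1], sigma, log = TRUE)) -
        sum(stats::dnorm(obs, theta[1], sigma, log = TRUE))
    } else {
      ll_ratio <- 0
    }
    if (log(stats::runif(1)) < ll_ratio) {
      theta <- prop
      cur_lp <- log_post(theta)
    }
    if (it <= cfg$warmup && it %% 50 == 0) {
      rate <- acc / pmax(tries, 1)
      step <- step * exp(rate - 0.35)   # aim near the RW optimum
      acc[] <- 0; tries[] <- 0
    }
    if (it > cfg$warmup) {
      p <- props(theta)
      fd <- if (samp_em) theta[i_em + 1] else em$decadal_mean
      fm <- if (samp_em) theta[i_em + 2] else em$millennial_mean
      out[it - cfg$warmup, ] <- c(p, fd, fm)
    }
  }
  out
}

# single flat-Dirichlet draw on the 2-simplex
.rdirichlet_one <- function() {
  g <- stats::rexp(3)
  g / sum(g)
}

#' Fit the three-endmember Bayesian mixing model
#'
#' Samples the posterior of the decadal/millennial/petrogenic proportions
#' (a, b, c) of the observed bulk river F14C under a flat Dirichlet prior
#' on the simplex, marginalizing over the endmember F14C uncertainty.
#' Unlike the Monte Carlo mass balance, no flux information constrains the
#' petrogenic share here - only the endmember F14C ranges do.
#'
#' Fails loudly if the potential scale reduction factor of any sampled
#' parameter exceeds `config$rhat_limit`.
#'
#' @param f14c_river Observed bulk river F14C (scalar, or a vector of
#'   observations sharing the same likelihood sigma).
#' @param sigma Likelihood sigma; defaults to `config$likelihood_sigma`.
#' @param config A [bayesian_config()].
#' @return An object of class `posterior_summary`: list with `summary`
#'   (data frame: parameter, mean, sd, ci5, ci95, rhat, ess), `draws`
#'   (matrix of pooled post-warmup draws), `chains`, `seed`, `config`.
#' @examples
#' \donttest{
#' fit <- fit_bayesian_mixture(0.919,
#'   config = bayesian_config(iterations = 3000, warmup = 1000))
#' fit$summary
#' }
#' @export
fit_bayesian_mixture <- function(f14c_river, sigma = NULL,
                                 config = bayesian_config()) {
  stopifnot(inherits(config, "bayesian_config"))
  if (is.null(sigma)) sigma <- config$likelihood_sigma
  if (sigma <= 0) stop("sigma must be > 0")
  if (any(f14c_river <= 0)) stop("f14c_river must be > 0")

  old_rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_rng))
    assign(".Random.seed", old_rng, envir = globalenv()))

  chains <- lapply(seq_len(config$chains), function(k) {
    .run_chain(f14c_river, sigma, config, chain_seed = config$seed + k)
  })

  sampled <- c("a", "b", "c", "f_dec", "f_mil")
  varying <- vapply(sampled, function(p) {
    stats::var(chains[[1]][, p]) > 0
  }, logical(1))
  mc_list <- coda::mcmc.list(lapply(chains, function(m) {
    coda::mcmc(m[, sampled[varying], drop = FALSE])
  }))
  gd <- coda::gelman.diag(mc_list, autoburnin = FALSE, multivariate = FALSE)
  rhat <- stats::setNames(rep(NA_real_, length(sampled)), sampled)
  rhat[sampled[varying]] <- gd$psrf[, "Point est."]
  ess <- stats::setNames(rep(NA_real_, length(sampled)), sampled)
  ess[sampled[varying]] <- coda::effectiveSize(mc_list)[sampled[varying]]

  bad <- sampled[varying][rhat[sampled[varying]] > config$rhat_limit]
  if (length(bad) > 0) {
    stop("non-convergence: potential scale reduction > ",
         config$rhat_limit, " for: ", paste(bad, collapse = ", "))
  }

  pooled <- do.call(rbind, chains)
  summ <- data.frame(
    parameter = sampled,
    mean = colMeans(pooled[, sampled]),
    sd = apply(pooled[, sampled], 2, stats::sd),
    ci5 = apply(pooled[, sampled], 2, stats::quantile, probs = 0.05),
    ci95 = apply(pooled[, sampled], 2, stats::quantile, probs = 0.95),
    rhat = rhat, ess = ess,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(summary = summ, draws = pooled, chains = config$chains,
         seed = config$seed, config = config),
    class = "posterior_summary"
  )
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("Bayesian mixing posterior (%d chains, seed %d)\n",
              x$chains, x$seed))
  print(transform(x$summary,
                  mean = round(mean, 3), sd = round(sd, 3),
                  ci5 = round(ci5, 3), ci95 = round(ci95, 3),
                  rhat = round(rhat, 3), ess = round(ess)))
  invisible(x)
}

#' Compare Monte Carlo and Bayesian source apportionments
#'
#' Per source: absolute difference of the posterior/Monte Carlo means and
#' whether the two mean +/- 1 sigma intervals overlap. Non-overlap is
#' flagged per source and in the `agree` field.
#'
#' @param mc A `mixing_result`.
#' @param bayes A `posterior_summary` fitted on the same bulk F14C.
#' @return A list with `table` (source, mc_mean, mc_sd, bayes_mean,
#'   bayes_sd, abs_diff, overlap_1sigma) and `agree` (all sources overlap).
#' @export
compare_mc_bayes <- function(mc, bayes) {
  stopifnot(inherits(mc, "mixing_result"),
            inherits(bayes, "posterior_summary"))
  src <- c("decadal", "millennial", "petrogenic")
  par <- c("a", "b", "c")
  bm <- bayes$summary[match(par, bayes$summary$parameter), ]
  mm <- mc$summary[match(src, mc$summary$source), ]
  overlap <- (mm$mean - mm$sd) <= (bm$mean + bm$sd) &
             (bm$mean - bm$sd) <= (mm$mean + mm$sd)
  tab <- data.frame(
    source = src,
    mc_mean = mm$mean, mc_sd = mm$sd,
    bayes_mean = bm$mean, bayes_sd = bm$sd,
    abs_diff = abs(mm$mean - bm$mean),
    overlap_1sigma = overlap,
    stringsAsFactors = FALSE
  )
  list(table = tab, agree = all(overlap))
}
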