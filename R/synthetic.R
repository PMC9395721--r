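#' Parameters of the WHAS-like synthetic survival generator
#'
#' Bundles everything the generator needs: cohort size, the Weibull
#' baseline hazard, log-linear covariate effects, covariate marginal
#' distributions, and the censoring mechanism (administrative study end
#' plus exponential dropout). The shipped defaults are calibrated so that a
#' cohort of 1,638 subjects reproduces the two marginal statistics reported
#' for the Worcester Heart Attack Study cohort: an observed death fraction
#' of about 42.1% and a median observed death time of about 516 days.
#'
#' The event model is a Weibull proportional-hazards model,
#' \deqn{\lambda(t \mid x) = \lambda_0 k t^{k-1} e^{\beta^T (x - x_{ref})},}
#' with shape `weibull_shape` (k) and rate scale `weibull_scale`
#' (\eqn{\lambda_0}, units 1/days^k). Covariates are age (years), sex (0/1),
#' BMI (kg/m^2), CHF (0/1, left-heart-failure complication) and MIORD
#' (0/1, recurrent myocardial infarction).
#'
#' @param n Number of subjects (default 1638).
#' @param weibull_shape Weibull shape k > 0.
#' @param weibull_scale Weibull rate scale > 0 (1/days^k).
#' @param beta Named numeric vector of log-hazard ratios for
#'   (age, sex, bmi, chf, miord).
#' @param x_ref Reference covariate vector subtracted before applying
#'   `beta`, keeping `weibull_scale` interpretable as the hazard of a
#'   typical subject.
#' @param age_mean,age_sd Age marginal: Normal truncated to \[30, 100\].
#' @param bmi_mean,bmi_sd BMI marginal: Normal truncated to \[15, 60\].
#' @param p_sex,p_chf,p_miord Bernoulli probabilities of the binary
#'   covariates.
#' @param censor_admin_days Administrative censoring time (study end), days;
#'   `Inf` disables it.
#' @param censor_dropout_rate Exponential dropout rate (1/days); 0 disables
#'   dropout.
#' @param seed Integer seed driving all randomness of a generation call.
#' @return An object of class `generator_params` (a named list).
#' @seealso [generate_whas_like()], [calibrate_generator()]
#' @export
generator_params <- function(n = 1638,
                             weibull_shape = 1.1,
                             weibull_scale = 1.2961539326e-04,
                             beta = c(age = 0.035, sex = 0.30, bmi = -0.035,
                                      chf = 0.90, miord = 0.45),
                             x_ref = c(age = 70, sex = 0, bmi = 27,
                                       chf = 0, miord = 0),
                             age_mean = 70, age_sd = 12,
                             bmi_mean = 27.5, bmi_sd = 5.2,
                             p_sex = 0.40, p_chf = 0.45, p_miord = 0.30,
                             censor_admin_days = 2000,
                             censor_dropout_rate = 5.6904838407e-04,
                             seed = 1L) {
  if (!is_count(n) || n < 2) {
    stop_memsurv("n must be an integer >= 2", "memsurv_parameter_error")
  }
  for (nm in c("weibull_shape", "weibull_scale")) {
    v <- get(nm)
    if (!is_scalar_num(v) || v <= 0) {
      stop_memsurv(sprintf("%s must be a strictly positive number", nm),
                   "memsurv_parameter_error")
    }
  }
  covs <- c("age", "sex", "bmi", "chf", "miord")
  if (!all(covs %in% names(beta)) || !all(covs %in% names(x_ref))) {
    stop_memsurv("beta and x_ref must be named with age, sex, bmi, chf, miord",
                 "memsurv_parameter_error")
  }
  if (censor_admin_days <= 0 || censor_dropout_rate < 0) {
    stop_memsurv("censoring parameters must be positive (admin) / non-negative (rate)",
                 "memsurv_parameter_error")
  }
  structure(list(
    n = as.integer(n),
    weibull_shape = weibull_shape, weibull_scale = weibull_scale,
    beta = beta[covs], x_ref = x_ref[covs],
    age_mean = age_mean, age_sd = age_sd,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    p_sex = p_sex, p_chf = p_chf, p_miord = p_miord,
    censor_admin_days = censor_admin_days,
    censor_dropout_rate = censor_dropout_rate,
    seed = as.integer(seed)
  ), class = "generator_params")
}

# Truncated-normal sampling by inverse-CDF; avoids rejection loops so the
# number of RNG draws per subject is fixed (keeps seeding reproducible).
rtnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

sample_covariates <- function(n, params) {
  data.frame(
    age = rtnorm(n, params$age_mean, params$age_sd, 30, 100),
    sex = stats::rbinom(n, 1L, params$p_sex),
    bmi = rtnorm(n, params$bmi_mean, params$bmi_sd, 15, 60),
    chf = stats::rbinom(n, 1L, params$p_chf),
    miord = stats::rbinom(n, 1L, params$p_miord)
  )
}

linear_predictor <- function(x, params) {
  xm <- as.matrix(x[, names(params$beta), drop = FALSE])
  drop(sweep(xm, 2L, params$x_ref) %*% params$beta)
}

#' Generate a WHAS-like right-censored survival dataset
#'
#' Draws covariates from the configured marginals, event times from the
#' Weibull proportional-hazards model, and censoring times independently as
#' the minimum of an administrative study end and exponential dropout. The
#' observed time is the minimum of the event and censoring times; the event
#' indicator records whether death was observed.
#'
#' @param params A [generator_params()] object.
#' @return A `survival_dataset`: a data frame with columns
#'   `age, sex, bmi, chf, miord, time, event` and the generating seed in
#'   `attr(, "seed")`.
#' @examples
#' d <- generate_whas_like(generator_params(n = 200, seed = 7))
#' mean(d$event)
#' @export
generate_whas_like <- function(params) {
  if (!inherits(params, "generator_params")) {
    params <- do.call(generator_params, as.list(params))
  }
  n <- params$n
  with_seed(params$seed, {
    x <- sample_covariates(n, params)
    lp <- linear_predictor(x, params)
    u <- stats::runif(n)
    t_event <- (-log(u) / (params$weibull_scale * exp(lp)))^(1 / params$weibull_shape)
    t_cens <- rep(params$censor_admin_days, n)
    if (params$censor_dropout_rate > 0) {
      t_cens <- pmin(t_cens, stats::rexp(n, params$censor_dropout_rate))
    }
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    out <- cbind(x, time = time, event = event)
    attr(out, "seed") <- params$seed
    class(out) <- c("survival_dataset", "data.frame")
    out
  })
}

#' Calibrate the generator to target observed marginals
#'
#' Adjusts the Weibull rate scale and the exponential dropout rate so that
#' the generator's Monte-Carlo observed event fraction and median observed
#' death time match the requested targets. Calibration uses common random
#' numbers (one fixed set of n >= 10,000 draws from `params$seed`), so the
#' marginals are deterministic functions of the two free parameters and the
#' solve is reproducible: the dropout rate is found by root bisection for
#' the event fraction inside an outer root solve of the rate scale for the
#' median death time.
#'
#' @param target_event_fraction Target observed death fraction in (0, 1).
#' @param target_median_death Target median observed death time (days).
#' @param params Starting [generator_params()]; its covariate marginals,
#'   shape, administrative censoring and seed are kept fixed.
#' @param tol_fraction Absolute tolerance on the event fraction
#'   (default 0.01).
#' @param tol_median Relative tolerance on the median death time
#'   (default 0.05).
#' @param n_cal Monte-Carlo size used during calibration (>= 10,000).
#' @return A `generator_params` object with calibrated `weibull_scale` and
#'   `censor_dropout_rate`, carrying the achieved marginals in
#'   `attr(, "calibration")`.
#' @export
calibrate_generator <- function(target_event_fraction, target_median_death,
                                params = generator_params(),
                                tol_fraction = 0.01, tol_median = 0.05,
                                n_cal = 10000L) {
  if (!is_scalar_num(target_event_fraction) ||
      target_event_fraction <= 0 || target_event_fraction >= 1) {
    stop_memsurv("target event fraction must lie strictly in (0, 1)",
                 "memsurv_calibration_error")
  }
  if (!is_scalar_num(target_median_death) || target_median_death <= 0) {
    stop_memsurv("target median death time must be > 0",
                 "memsurv_calibration_error")
  }
  n_cal <- max(as.integer(n_cal), 10000L)

  draws <- with_seed(params$seed, {
    x <- sample_covariates(n_cal, params)
    list(lp = linear_predictor(x, params),
         u_event = stats::runif(n_cal),
         u_drop = stats::runif(n_cal))
  })

  simulate_marginals <- function(scale, rate) {
    t_event <- (-log(draws$u_event) / (scale * exp(draws$lp)))^(1 / params$weibull_shape)
    t_cens <- rep(params$censor_admin_days, n_cal)
    if (rate > 0) t_cens <- pmin(t_cens, -log(draws$u_drop) / rate)
    ev <- t_event <= t_cens
    list(fraction = mean(ev),
         median = if (any(ev)) stats::median(t_event[ev]) else NA_real_)
  }

  # Inner solve: dropout rate for the event fraction at a given scale.
  # The fraction is monotone non-increasing in the dropout rate.
  solve_rate <- function(scale) {
    f0 <- simulate_marginals(scale, 0)$fraction
    if (f0 < target_event_fraction) {
      return(structure(NA_real_, max_fraction = f0))
    }
    lo <- 1e-8
    if (simulate_marginals(scale, lo)$fraction <= target_event_fraction) {
      return(lo)
    }
    hi <- 1e-3
    while (simulate_marginals(scale, hi)$fraction > target_event_fraction &&
           hi < 1e6) {
      hi <- hi * 10
    }
    exp(stats::uniroot(
      function(lr) simulate_marginals(scale, exp(lr))$fraction - target_event_fraction,
      lower = log(lo), upper = log(hi), tol = 1e-10
    )$root)
  }

  median_residual <- function(lscale) {
    scale <- exp(lscale)
    rate <- solve_rate(scale)
    if (is.na(rate)) {
      # Fraction unreachable here: push the solver toward slower hazards.
      return(1)
    }
    log(simulate_marginals(scale, rate)$median) - log(target_median_death)
  }

  root <- tryCatch(
    stats::uniroot(median_residual, lower = log(1e-9), upper = log(1),
                   tol = 1e-10),
    error = function(e) NULL
  )
  if (is.null(root)) {
    stop_memsurv(
      "calibration failed: no (scale, dropout) pair reaches the requested marginals",
      "memsurv_calibration_error"
    )
  }
  scale <- exp(root$root)
  rate <- solve_rate(scale)
  if (is.na(rate)) {
    stop_memsurv(
      sprintf(paste0(
        "calibration failed: administrative censoring caps the event ",
        "fraction at %.3f < target %.3f"),
        attr(rate, "max_fraction") %||% NA_real_, target_event_fraction),
      "memsurv_calibration_error"
    )
  }
  achieved <- simulate_marginals(scale, rate)
  if (abs(achieved$fraction - target_event_fraction) > tol_fraction ||
      abs(achieved$median - target_median_death) / target_median_death > tol_median) {
    stop_memsurv(
      sprintf(paste0(
        "calibration did not converge: achieved fraction %.4f (target %.4f), ",
        "median %.1f d (target %.1f d)"),
        achieved$fraction, target_event_fraction,
        achieved$median, target_median_death),
      "memsurv_calibration_error"
    )
  }
  out <- params
  out$weibull_scale <- scale
  out$censor_dropout_rate <- rate
  attr(out, "calibration") <- list(
    achieved_event_fraction = achieved$fraction,
    achieved_median_death = achieved$median,
    n_cal = n_cal
  )
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
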