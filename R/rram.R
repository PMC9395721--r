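level_ids <- paste0("L", 1:9)

normalize_level <- function(level) {
  if (is.numeric(level)) level <- paste0("L", level)
  if (!level %in% level_ids) {
    stop_memsurv(sprintf("unknown conductance level '%s'", level),
                 "memsurv_parameter_error")
  }
  level
}

#' Programming targets of the nine conductance levels
#'
#' L1 (the reset state) sits at 25 uS; the set-programmed levels L2-L9 are
#' linearly spaced from 50 to 225 uS in 25 uS steps.
#'
#' @return Named numeric vector, uS.
#' @export
level_targets <- function() {
  stats::setNames(seq(25, 225, by = 25), level_ids)
}

#' Load a device model configuration
#'
#' Reads the YAML description of the per-level conductance distributions
#' for the two multilevel programming algorithms (ML-Set and ML-Hybrid),
#' validates it, and returns a `device_config`. The shipped default
#' (`inst/extdata/device_defaults.yaml`) is a qualitative calibration, not
#' a device measurement; program-and-verify recipe fields are carried as
#' annotation only.
#'
#' @param path YAML path; `NULL` loads the packaged default.
#' @return A `device_config` list.
#' @export
device_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "device_defaults.yaml", package = "memsurv")
  }
  cfg <- yaml::read_yaml(path)
  targets <- level_targets()
  cfg_levels <- as.numeric(unlist(cfg$levels)[level_ids])
  if (length(cfg_levels) != 9 || any(cfg_levels != unname(targets))) {
    stop_memsurv("device config level targets must be L1=25 ... L9=225 uS",
                 "memsurv_format_error")
  }
  for (alg in c("ml_set", "ml_hybrid")) {
    if (is.null(cfg$algorithms[[alg]])) {
      stop_memsurv(sprintf("device config missing algorithm '%s'", alg),
                   "memsurv_format_error")
    }
    for (lid in level_ids) {
      lm <- cfg$algorithms[[alg]]$levels[[lid]]
      req <- c("sigma0", "mu_inf", "tau_d", "sigma_growth", "p_drift", "sign")
      if (is.null(lm) || !all(req %in% names(lm))) {
        stop_memsurv(sprintf("device config %s/%s incomplete", alg, lid),
                     "memsurv_format_error")
      }
      if (lm$sigma0 <= 0 || lm$tau_d <= 0 || lm$sigma_growth <= 0 ||
          lm$p_drift < 0 || lm$p_drift > 1 || !lm$sign %in% c(-1, 1)) {
        stop_memsurv(sprintf("device config %s/%s has invalid parameters",
                             alg, lid),
                     "memsurv_format_error")
      }
    }
  }
  # L6-L9 come from the same set procedure in both algorithms.
  for (lid in paste0("L", 6:9)) {
    if (!identical(cfg$algorithms$ml_set$levels[[lid]],
                   cfg$algorithms$ml_hybrid$levels[[lid]])) {
      stop_memsurv(sprintf("L6-L9 models must be identical across algorithms (%s differs)",
                           lid),
                   "memsurv_format_error")
    }
  }
  cfg$targets <- targets
  class(cfg) <- "device_config"
  cfg
}

#' Scale the variability and drift of a device configuration
#'
#' Utility for stress studies: multiplies every level's `sigma0` by
#' `sigma_mult` and its drift amplitude (`mu_inf` and `p_drift`, the
#' latter capped at 1) by `drift_mult`.
#'
#' @param config A [device_config()].
#' @param sigma_mult,drift_mult Non-negative multipliers.
#' @return A modified `device_config`.
#' @export
scale_device_config <- function(config, sigma_mult = 1, drift_mult = 1) {
  for (alg in c("ml_set", "ml_hybrid")) {
    for (lid in level_ids) {
      lm <- config$algorithms[[alg]]$levels[[lid]]
      lm$sigma0 <- lm$sigma0 * sigma_mult
      lm$mu_inf <- lm$mu_inf * drift_mult
      lm$p_drift <- min(lm$p_drift * drift_mult, 1)
      config$algorithms[[alg]]$levels[[lid]] <- lm
    }
  }
  config
}

get_level_model <- function(level, algorithm, config) {
  level <- normalize_level(level)
  if (!algorithm %in% c("ml_set", "ml_hybrid")) {
    stop_memsurv(sprintf("unknown algorithm '%s'", algorithm),
                 "memsurv_parameter_error")
  }
  c(config$algorithms[[algorithm]]$levels[[level]],
    list(target = unname(config$targets[level]), level = level))
}

#' Conductance distribution of a programmed level at time t
#'
#' Two-component Gaussian mixture: a non-drifting component centered on
#' the programming target `G_trg` with spread `sigma0`, and a drifting
#' component (weight `p_drift`) whose mean shifts by
#' `sign * mu_inf * (1 - exp(-t / tau_d))` with spread
#' `sigma0 * sigma_growth`. At t = 0 both component means coincide at
#' `G_trg`; as t grows the mean shift saturates at `sign * mu_inf`.
#'
#' @param level `"L1"`-`"L9"` (or 1-9).
#' @param algorithm `"ml_set"` or `"ml_hybrid"`.
#' @param t Time since programming, hours (>= 0).
#' @param config A [device_config()].
#' @return List with `components` (data frame of mean/sd/weight), the
#'   analytic mixture `mean` and `sd`, and the level `target` (all uS).
#'   The moments are those of the untruncated mixture; [sample_conductance()]
#'   truncates at 0 uS, which only matters when a drifted component sits
#'   within a few sigma of 0 (relevant for heavily drifted L1).
#' @export
distribution_at <- function(level, algorithm, t, config = device_config()) {
  if (!is_scalar_num(t) || t < 0) {
    stop_memsurv("time t must be a non-negative number of hours",
                 "memsurv_parameter_error")
  }
  lm <- get_level_model(level, algorithm, config)
  shift <- lm$sign * lm$mu_inf * (1 - exp(-t / lm$tau_d))
  comp <- data.frame(
    mean = c(lm$target, lm$target + shift),
    sd = c(lm$sigma0, lm$sigma0 * lm$sigma_growth),
    weight = c(1 - lm$p_drift, lm$p_drift)
  )
  mixture_mean <- sum(comp$weight * comp$mean)
  mixture_var <- sum(comp$weight * (comp$sd^2 + comp$mean^2)) - mixture_mean^2
  list(components = comp, mean = mixture_mean, sd = sqrt(mixture_var),
       target = lm$target, level = lm$level, algorithm = algorithm, t = t)
}

# Vectorized mixture sampler shared by sample_conductance() and the
# crossbar Monte Carlo. Truncates at 0 uS by resampling (conductance is
# physically non-negative). Assumes the caller seeded the RNG.
draw_mixture <- function(dist, n) {
  comp <- dist$components
  is_drift <- stats::rbinom(n, 1L, comp$weight[2]) == 1L
  x <- ifelse(is_drift,
              stats::rnorm(n, comp$mean[2], comp$sd[2]),
              stats::rnorm(n, comp$mean[1], comp$sd[1]))
  # Truncate at 0 by resampling; if a component sits essentially below 0
  # (extreme drift), clamp after a bounded number of attempts so the
  # sampler always terminates.
  for (attempt in seq_len(50L)) {
    bad <- which(x < 0)
    if (length(bad) == 0L) break
    x[bad] <- ifelse(is_drift[bad],
                     stats::rnorm(length(bad), comp$mean[2], comp$sd[2]),
                     stats::rnorm(length(bad), comp$mean[1], comp$sd[1]))
  }
  pmax(x, 0)
}

#' Sample programmed-cell conductances
#'
#' i.i.d. draws from [distribution_at()], truncated at 0 uS.
#'
#' @inheritParams distribution_at
#' @param n Number of cells to sample (>= 1).
#' @param seed Integer seed.
#' @return Numeric vector of conductances (uS) with the sampling context
#'   in attributes.
#' @export
sample_conductance <- function(level, algorithm, t, n, seed,
                               config = device_config()) {
  if (!is_count(n)) {
    stop_memsurv("n must be a positive integer", "memsurv_parameter_error")
  }
  dist <- distribution_at(level, algorithm, t, config)
  x <- with_seed(seed, draw_mixture(dist, n))
  structure(x, level = dist$level, algorithm = algorithm, t = t, seed = seed)
}

#' Relative programming energy of a level assignment
#'
#' Weighted sum of per-cell programming costs. ML-Hybrid reaches L2-L5 by
#' a reset followed by a set, doubling the per-cell cost there; L1 and
#' L6-L9 cost the same in both algorithms.
#'
#' @param counts Named non-negative vector of cell counts per level
#'   (names `"L1"`-`"L9"`; missing levels count 0).
#' @param algorithm `"ml_set"` or `"ml_hybrid"`.
#' @param config A [device_config()].
#' @return Relative energy (unitless).
#' @export
programming_energy <- function(counts, algorithm, config = device_config()) {
  if (!algorithm %in% c("ml_set", "ml_hybrid")) {
    stop_memsurv(sprintf("unknown algorithm '%s'", algorithm),
                 "memsurv_parameter_error")
  }
  if (any(counts < 0)) {
    stop_memsurv("cell counts must be non-negative", "memsurv_parameter_error")
  }
  full <- stats::setNames(numeric(9), level_ids)
  full[names(counts)] <- counts
  cost <- unlist(config$algorithms[[algorithm]]$programming_cost)[level_ids]
  sum(full * cost)
}
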