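#' The 17-level differential weight grid
#'
#' Quantized weights live on a symmetric uniform grid. With the default
#' step of 0.25 weight units the grid is \{-2.00, -1.75, ..., +2.00\}: 17
#' values, the number of distinct differences representable by two 9-level
#' RRAM cells programmed between 25 and 225 uS in 25 uS steps. One weight
#' unit corresponds to `conductance_scale` = 100 uS of differential
#' conductance, so the grid step is 25 uS.
#'
#' @param step Grid spacing in weight units (default 0.25).
#' @param conductance_scale Conductance per weight unit, uS (default 100).
#' @param wmax Grid end point (default 2.0 weight units).
#' @return A `quant_grid` with the sorted level vector in `$levels`.
#' @export
quant_grid <- function(step = 0.25, conductance_scale = 100, wmax = 2.0) {
  if (step <= 0 || conductance_scale <= 0 || wmax <= 0 ||
      abs(wmax / step - round(wmax / step)) > 1e-9) {
    stop_memsurv("grid requires positive step dividing wmax exactly",
                 "memsurv_parameter_error")
  }
  structure(list(levels = seq(-wmax, wmax, by = step), step = step,
                 conductance_scale = conductance_scale),
            class = "quant_grid")
}

#' Round weights onto the quantization grid
#'
#' Each value maps to the nearest grid level; exact midpoints break toward
#' the level of smaller absolute value, and values beyond the grid ends
#' clamp to the end levels.
#'
#' @param w Numeric vector (or matrix) of weights.
#' @param grid A [quant_grid()].
#' @return Quantized values, same shape as `w`.
#' @export
quantize_value <- function(w, grid = quant_grid()) {
  lv <- grid$levels
  idx <- findInterval(w, lv)
  lo <- pmin(pmax(idx, 1L), length(lv))
  hi <- pmin(idx + 1L, length(lv))
  dlo <- abs(w - lv[lo])
  dhi <- abs(w - lv[hi])
  pick_hi <- dhi < dlo | (dhi == dlo & abs(lv[hi]) < abs(lv[lo]))
  out <- ifelse(pick_hi, lv[hi], lv[lo])
  if (is.matrix(w)) dim(out) <- dim(w)
  out
}

#' Quantization error of a weight
#'
#' Absolute difference between a weight and its nearest grid level; at
#' most half the grid step for in-range weights.
#'
#' @inheritParams quantize_value
#' @return Non-negative values, same shape as `w`.
#' @export
quantization_error <- function(w, grid = quant_grid()) {
  abs(w - quantize_value(w, grid))
}

#' Incremental quantization schedule
#'
#' @param fractions Strictly increasing cumulative fractions of weights to
#'   lock per step, ending at 1; default `c(0.50, 0.75, 0.87, 1.00)`.
#' @param policy Weight-selection policy: `"greatest_abs"`, `"lowest_abs"`
#'   (default: the most training-stable choice), or `"lowest_quant_error"`.
#' @param epochs_per_step Retraining epochs after each lock step.
#' @param seed Integer seed for the retraining randomness.
#' @return An `inq_plan`.
#' @export
inq_plan <- function(fractions = c(0.50, 0.75, 0.87, 1.00),
                     policy = c("lowest_abs", "greatest_abs",
                                "lowest_quant_error"),
                     epochs_per_step = 100L, seed = 1L) {
  policy <- match.arg(policy)
  if (any(diff(fractions) <= 0) || abs(fractions[length(fractions)] - 1) > 1e-12 ||
      any(fractions <= 0)) {
    stop_memsurv("fractions must be strictly increasing and end at 1.0",
                 "memsurv_parameter_error")
  }
  structure(list(fractions = fractions, policy = policy,
                 epochs_per_step = as.integer(epochs_per_step),
                 seed = as.integer(seed)),
            class = "inq_plan")
}

policy_rank_key <- function(w, policy, grid) {
  switch(policy,
         greatest_abs = -abs(w),
         lowest_abs = abs(w),
         lowest_quant_error = quantization_error(w, grid),
         stop_memsurv(sprintf("unknown policy '%s'", policy),
                      "memsurv_parameter_error"))
}

#' Select weights to lock onto the grid
#'
#' Per layer, ranks the weights by the policy criterion and locks the top
#' `ceiling(fraction * count)`; weights already locked in `previous` stay
#' locked and count toward the quota. Ranking ties break in storage
#' (column-major index) order for determinism.
#'
#' @param weights List of per-layer weight matrices.
#' @param fraction Cumulative fraction in (0, 1].
#' @param policy One of `"greatest_abs"`, `"lowest_abs"`,
#'   `"lowest_quant_error"`.
#' @param grid A [quant_grid()] (needed by the error policy).
#' @param previous Optional previous mask list (monotone growth).
#' @return List of per-layer logical matrices (the quantization mask).
#' @export
select_for_quantization <- function(weights, fraction, policy,
                                    grid = quant_grid(), previous = NULL) {
  if (!is_scalar_num(fraction) || fraction <= 0 || fraction > 1) {
    stop_memsurv("fraction must lie in (0, 1]", "memsurv_parameter_error")
  }
  lapply(seq_along(weights), function(l) {
    w <- weights[[l]]
    prev <- if (is.null(previous)) {
      matrix(FALSE, nrow(w), ncol(w))
    } else {
      previous[[l]]
    }
    quota <- ceiling(fraction * length(w))
    need <- quota - sum(prev)
    if (need <= 0) return(prev)
    key <- policy_rank_key(w, policy, grid)
    key[prev] <- Inf  # already locked: never re-picked
    picked <- order(key, seq_along(key))[seq_len(need)]
    mask <- prev
    mask[picked] <- TRUE
    mask
  })
}

#' Incremental network quantization (INQ) training
#'
#' Starting from a trained float network, repeats for each schedule step:
#' grow the locked-weight mask to the step's cumulative fraction using the
#' plan's selection policy, then retrain for `epochs_per_step` epochs,
#' re-projecting the locked weights onto the grid at the end of every
#' epoch while the remaining weights keep training freely. Locked weights
#' still receive gradient between projections; only the end-of-epoch
#' projection pins them. After the final step (fraction 1.0) every weight
#' lies exactly on a grid level.
#'
#' @param network A trained `dense_network` (see [train()]).
#' @param dataset The training `survival_dataset`.
#' @param plan An [inq_plan()].
#' @param config A [train_config()] supplying optimizer settings; its
#'   `epochs` field is ignored in favor of `plan$epochs_per_step`.
#' @param grid A [quant_grid()].
#' @return The quantized `dense_network`, with the grid stored in `$grid`
#'   and the per-step mask fractions in `attr(, "mask_fractions")`.
#' @export
inq_train <- function(network, dataset, plan = inq_plan(),
                      config = train_config(), grid = quant_grid()) {
  validate_network(network)
  dm <- dataset_matrices(dataset)
  std <- standardize(dm$x, network$center, network$scale)
  step_config <- config
  step_config$epochs <- plan$epochs_per_step
  with_seed(plan$seed, {
    x_aug <- augment_inputs(std$x, network$layer_dims[1L])
    mask <- NULL
    observed_fractions <- numeric(0)
    for (s in seq_along(plan$fractions)) {
      mask <- select_for_quantization(network$weights, plan$fractions[s],
                                      plan$policy, grid, previous = mask)
      observed_fractions <- c(observed_fractions,
                              sum(vapply(mask, sum, 0)) /
                                sum(vapply(mask, length, 0)))
      for (l in seq_along(network$weights)) {
        w <- network$weights[[l]]
        w[mask[[l]]] <- quantize_value(w[mask[[l]]], grid)
        network$weights[[l]] <- w
      }
      network <- tryCatch(
        run_training(network, x_aug, dm$times, dm$events, step_config,
                     mask = mask, grid = grid,
                     context = sprintf("INQ step %d (policy %s)", s,
                                       plan$policy)),
        memsurv_training_error = function(e) stop(e)
      )
    }
    network$grid <- grid
    attr(network, "mask_fractions") <- observed_fractions
    network
  })
}
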