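#' Ideal analog matrix-vector multiply
#'
#' Ohm/Kirchhoff crossbar primitive: with wordline voltages `V` (volts)
#' applied to a conductance matrix `G` (uS, wordlines x bitlines), each
#' bitline current is `I_j = sum_i G_ij V_i` (microamperes). Wires and
#' sensing are ideal.
#'
#' @param conductance Non-negative conductance matrix, uS.
#' @param voltages Voltage vector, length = number of wordlines.
#' @return Bitline current vector, uA.
#' @export
analog_mvm <- function(conductance, voltages) {
  if (length(voltages) != nrow(conductance)) {
    stop_memsurv(sprintf("voltage length %d does not match %d wordlines",
                         length(voltages), nrow(conductance)),
                 "memsurv_shape_error")
  }
  drop(crossprod(conductance, voltages))
}

crossbar_capacity <- 64L

sample_level_matrix <- function(idx, dists) {
  g <- numeric(length(idx))
  for (lid in unique(as.vector(idx))) {
    cells <- idx == lid
    g[cells] <- draw_mixture(dists[[lid]], sum(cells))
  }
  matrix(g, nrow(idx), ncol(idx))
}

#' Build the four-crossbar mapped network
#'
#' Populates the physical realization of the survival network: four RRAM
#' crossbars (positive and negative polarity for each of the two 48-neuron
#' layers) plus a digital tail holding the final 48-to-1 linear neuron and
#' all additive biases. In `"ideal"` mode cells take their level target
#' conductances; in `"sample"` mode each cell is drawn independently from
#' its level's distribution at time `t`.
#'
#' @param assignment A [assign_pairs()] result covering layers 1 and 2.
#' @param network The quantized `dense_network` the assignment was built
#'   from (supplies the digital tail and input scaling).
#' @param mode `"ideal"` or `"sample"`.
#' @param t Hours since programming (sample mode).
#' @param seed Integer seed (sample mode).
#' @param config A [device_config()].
#' @param v_read_max Full-scale read voltage, volts (default 0.3).
#' @return A `mapped_network` with exactly four `crossbars`.
#' @export
build_mapped_network <- function(assignment, network,
                                 mode = c("ideal", "sample"),
                                 t = 0, seed = 1L,
                                 config = device_config(),
                                 v_read_max = 0.3) {
  mode <- match.arg(mode)
  validate_network(network)
  if (length(assignment$layers) != length(network$weights) - 1L) {
    stop_memsurv("assignment must cover every crossbar layer of the network",
                 "memsurv_parameter_error")
  }
  targets <- level_targets()
  build_all <- function() {
    crossbars <- list()
    for (l in seq_along(assignment$layers)) {
      lay <- assignment$layers[[l]]
      if (nrow(lay$pos) > crossbar_capacity ||
          ncol(lay$pos) > crossbar_capacity) {
        stop_memsurv(sprintf(
          "layer %d (%dx%d) exceeds the %dx%d crossbar capacity",
          l, nrow(lay$pos), ncol(lay$pos),
          crossbar_capacity, crossbar_capacity),
          "memsurv_capacity_error")
      }
      if (mode == "ideal") {
        g_pos <- matrix(targets[lay$pos], nrow(lay$pos), ncol(lay$pos))
        g_neg <- matrix(targets[lay$neg], nrow(lay$neg), ncol(lay$neg))
      } else {
        dists <- lapply(seq_len(9L), function(k) {
          distribution_at(level_ids[k], assignment$algorithm, t, config)
        })
        g_pos <- sample_level_matrix(lay$pos, dists)
        g_neg <- sample_level_matrix(lay$neg, dists)
      }
      crossbars <- c(crossbars, list(
        list(layer = l, polarity = "positive", conductance = g_pos),
        list(layer = l, polarity = "negative", conductance = g_neg)
      ))
    }
    crossbars
  }
  crossbars <- if (mode == "sample") with_seed(seed, build_all()) else build_all()
  n_layers <- length(network$weights)
  structure(list(
    crossbars = crossbars,
    tail_weights = network$weights[[n_layers]],
    biases = network$biases,
    center = network$center, scale = network$scale,
    layer_dims = network$layer_dims,
    conductance_scale = assignment$grid$conductance_scale,
    v_read_max = v_read_max,
    mode = mode, t = t,
    algorithm = assignment$algorithm, base_level = assignment$base_level
  ), class = "mapped_network")
}

get_crossbar <- function(mapped, layer, polarity) {
  for (cb in mapped$crossbars) {
    if (cb$layer == layer && cb$polarity == polarity) return(cb$conductance)
  }
  stop_memsurv("crossbar not found", "memsurv_parameter_error")
}

# Shared analog forward pass. Per layer: activations are scaled so the
# largest maps to v_read_max (negative activations clip to 0 V at the
# DAC), the two polarity crossbars are read, and the DSP subtracts the
# currents, undoes the voltage scaling and the weight-to-conductance
# scale digitally, adds the bias, and applies the rectifier. The read
# scale cancels exactly, so risks are invariant to v_read_max.
crossbar_forward <- function(mapped, covariates, keep_activations = FALSE) {
  if (inherits(covariates, "survival_dataset") || is.data.frame(covariates)) {
    covariates <- as.matrix(covariates[, c("age", "sex", "bmi", "chf", "miord")])
  }
  a <- as.matrix(covariates)
  if (!is.null(mapped$center)) {
    a <- sweep(sweep(a, 2L, mapped$center), 2L, mapped$scale, "/")
  }
  a <- cbind(a, 1)  # constant bias input
  n_crossbar_layers <- length(mapped$layer_dims) - 2L
  voltages <- vector("list", n_crossbar_layers)
  for (l in seq_len(n_crossbar_layers)) {
    v <- pmax(a, 0)
    s <- max(v)
    s <- if (s > 0) mapped$v_read_max / s else 1
    v <- v * s
    voltages[[l]] <- v
    i_pos <- v %*% get_crossbar(mapped, l, "positive")
    i_neg <- v %*% get_crossbar(mapped, l, "negative")
    z <- (i_pos - i_neg) / (s * mapped$conductance_scale)
    z <- sweep(z, 2L, mapped$biases[[l]], "+")
    a <- relu(z)
  }
  risks <- drop(sweep(a %*% mapped$tail_weights, 2L,
                      mapped$biases[[length(mapped$biases)]], "+"))
  if (keep_activations) list(risks = risks, voltages = voltages) else risks
}

#' Analog crossbar inference
#'
#' Runs the full four-crossbar inference chain -- DAC voltage encoding,
#' analog MVM per polarity, digital subtraction, bias add and rectifier,
#' then the digital output neuron -- and returns per-subject log-risks.
#' With an ideal-mode mapping this reproduces the quantized digital
#' forward pass exactly.
#'
#' @param mapped A [build_mapped_network()] result.
#' @param covariates n x 5 covariate matrix or `survival_dataset`.
#' @return Numeric vector of log-risk scores.
#' @export
crossbar_inference <- function(mapped, covariates) {
  crossbar_forward(mapped, covariates)
}

#' Average MVM read power of a mapped network
#'
#' Joule dissipation in the cells: `P = sum_ij V_i^2 G_ij` accumulated
#' over all four crossbars, averaged over the dataset's inference inputs.
#' Layer-2 read voltages are taken from the ideal-device activations, so
#' power reflects the programmed conductance pattern rather than one
#' Monte-Carlo draw. The alternative supply-referenced convention
#' `P = V_supply * sum V_i G_ij` is available via `convention`.
#'
#' @param mapped A `mapped_network`.
#' @param covariates Inference inputs (n x 5 matrix or dataset).
#' @param convention `"joule"` (default, V^2 G) or `"supply"`
#'   (V_supply x sum of currents, with `v_supply`).
#' @param v_supply Supply voltage for the `"supply"` convention, volts.
#' @return Mean MVM power per inference, watts.
#' @export
mvm_power <- function(mapped, covariates, convention = c("joule", "supply"),
                      v_supply = 0.3) {
  convention <- match.arg(convention)
  fw <- crossbar_forward(mapped, covariates, keep_activations = TRUE)
  total <- 0
  for (l in seq_along(fw$voltages)) {
    v <- fw$voltages[[l]]
    g_row <- rowSums(get_crossbar(mapped, l, "positive")) +
      rowSums(get_crossbar(mapped, l, "negative"))
    per_subject <- if (convention == "joule") {
      (v^2) %*% g_row
    } else {
      v_supply * (v %*% g_row)
    }
    total <- total + mean(per_subject)
  }
  # uS * V^2 -> uW -> W
  unname(total * 1e-6)
}

#' Monte-Carlo concordance of the crossbar implementation
#'
#' Repeats `n_runs` times: redraw every cell conductance from its level
#' distribution at time `t`, rebuild the mapped network, run crossbar
#' inference on the dataset, and score Harrell's concordance index. The
#' spread of the resulting distribution measures how device variability
#' and drift degrade the survival ranking.
#'
#' @param assignment A [assign_pairs()] result.
#' @param network The quantized `dense_network`.
#' @param dataset Evaluation `survival_dataset`.
#' @param t Hours since programming.
#' @param n_runs Number of Monte-Carlo device realizations (default 1000).
#' @param seed Integer seed; run r uses a child seed derived from it.
#' @param config A [device_config()].
#' @param v_read_max Full-scale read voltage, volts.
#' @return An `mc_result`: list with `cindex` (length `n_runs`), the run
#'   context, and the ideal-device reference concordance `ideal_cindex`.
#' @export
monte_carlo_cindex <- function(assignment, network, dataset, t = 0,
                               n_runs = 1000L, seed = 1L,
                               config = device_config(), v_read_max = 0.3) {
  if (!is_count(n_runs)) {
    stop_memsurv("n_runs must be a positive integer", "memsurv_parameter_error")
  }
  dm <- dataset_matrices(dataset)
  ideal <- build_mapped_network(assignment, network, mode = "ideal",
                                config = config, v_read_max = v_read_max)
  ideal_c <- concordance_index(crossbar_inference(ideal, dm$x),
                               dm$times, dm$events)
  cvals <- vapply(seq_len(n_runs), function(r) {
    mapped <- build_mapped_network(assignment, network, mode = "sample",
                                   t = t, seed = child_seed(seed, r),
                                   config = config, v_read_max = v_read_max)
    concordance_index(crossbar_inference(mapped, dm$x), dm$times, dm$events)
  }, 0)
  structure(list(cindex = cvals, n_runs = n_runs, t = t,
                 algorithm = assignment$algorithm,
                 base_level = assignment$base_level,
                 seed = seed, ideal_cindex = ideal_c),
            class = "mc_result")
}
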