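#' Construct a DeepSurv-style dense network
#'
#' The default architecture is the survival network used throughout the
#' package: 6 inputs (the 5 patient covariates plus a constant bias input
#' of 1), two rectifier hidden layers of 48 neurons, and a single linear
#' output neuron whose value is the log-risk h(x) of the Cox model.
#' Per-layer additive biases are kept in addition to the bias input; in the
#' crossbar implementation they are applied digitally.
#'
#' @param layer_dims Integer vector of layer sizes, default `c(6, 48, 48, 1)`.
#' @param seed Integer seed for the He-uniform weight initialization; if
#'   `NULL`, weights are all zero.
#' @return A `dense_network` object: lists of weight matrices and bias
#'   vectors plus activation tags (`"relu"` hidden, `"linear"` output).
#' @export
dense_network <- function(layer_dims = c(6L, 48L, 48L, 1L), seed = NULL) {
  if (length(layer_dims) < 2 || any(layer_dims < 1)) {
    stop_memsurv("layer_dims must contain at least two positive sizes",
                 "memsurv_parameter_error")
  }
  n_layers <- length(layer_dims) - 1L
  make_weights <- function() {
    lapply(seq_len(n_layers), function(l) {
      fan_in <- layer_dims[l]
      lim <- sqrt(6 / fan_in)
      matrix(stats::runif(fan_in * layer_dims[l + 1L], -lim, lim),
             nrow = fan_in, ncol = layer_dims[l + 1L])
    })
  }
  weights <- if (is.null(seed)) {
    lapply(seq_len(n_layers), function(l) {
      matrix(0, nrow = layer_dims[l], ncol = layer_dims[l + 1L])
    })
  } else {
    with_seed(seed, make_weights())
  }
  biases <- lapply(seq_len(n_layers), function(l) numeric(layer_dims[l + 1L]))
  structure(list(
    layer_dims = as.integer(layer_dims),
    weights = weights,
    biases = biases,
    hidden_activation = "relu",
    output_activation = "linear"
  ), class = "dense_network")
}

validate_network <- function(network) {
  if (!inherits(network, "dense_network")) {
    stop_memsurv("expected a dense_network object", "memsurv_parameter_error")
  }
  dims <- network$layer_dims
  for (l in seq_along(network$weights)) {
    w <- network$weights[[l]]
    if (!all(dim(w) == c(dims[l], dims[l + 1L]))) {
      stop_memsurv(sprintf("weight matrix %d has shape %dx%d, expected %dx%d",
                           l, nrow(w), ncol(w), dims[l], dims[l + 1L]),
                   "memsurv_shape_error")
    }
    if (length(network$biases[[l]]) != dims[l + 1L]) {
      stop_memsurv(sprintf("bias vector %d has wrong length", l),
                   "memsurv_shape_error")
    }
  }
  invisible(network)
}

relu <- function(x) pmax(x, 0)

# Append the constant "+1" bias input as the last covariate column.
augment_inputs <- function(covariates, n_inputs) {
  x <- as.matrix(covariates)
  dimnames(x) <- NULL
  if (ncol(x) != n_inputs - 1L) {
    stop_memsurv(sprintf("covariate matrix has %d columns, expected %d",
                         ncol(x), n_inputs - 1L),
                 "memsurv_shape_error")
  }
  cbind(x, 1)
}

# Forward pass returning all layer activations (used by both the risk
# computation and backpropagation). `dropout_masks`, when given, are
# multiplied into the hidden activations (inverted-dropout convention).
forward_pass <- function(network, x_aug, dropout_masks = NULL) {
  n_layers <- length(network$weights)
  activations <- vector("list", n_layers + 1L)
  pre <- vector("list", n_layers)
  activations[[1L]] <- x_aug
  for (l in seq_len(n_layers)) {
    z <- activations[[l]] %*% network$weights[[l]]
    z <- sweep(z, 2L, network$biases[[l]], "+")
    pre[[l]] <- z
    a <- if (l < n_layers) relu(z) else z
    if (l < n_layers && !is.null(dropout_masks)) {
      a <- a * dropout_masks[[l]]
    }
    activations[[l + 1L]] <- a
  }
  list(activations = activations, pre = pre)
}

#' Compute per-subject log-risk scores
#'
#' Deterministic inference-mode forward pass (dropout disabled): the 5
#' covariates are augmented with the constant bias input 1, passed through
#' the rectifier hidden layers, and the linear output neuron returns the
#' log-risk h(x). The Cox risk score is `exp(h(x))`; Harrell's concordance
#' only uses the ordering, so log-risks are returned.
#'
#' @param network A `dense_network`.
#' @param covariates Numeric matrix (n x 5) of patient covariates, or a
#'   `survival_dataset`.
#' @return Numeric vector of n log-risk scores.
#' @export
risk_score <- function(network, covariates) {
  validate_network(network)
  if (inherits(covariates, "survival_dataset") || is.data.frame(covariates)) {
    covariates <- as.matrix(covariates[, c("age", "sex", "bmi", "chf", "miord")])
  }
  if (!is.null(network$center)) {
    covariates <- sweep(sweep(as.matrix(covariates), 2L, network$center),
                        2L, network$scale, "/")
  }
  x_aug <- augment_inputs(covariates, network$layer_dims[1L])
  fp <- forward_pass(network, x_aug)
  risks <- drop(fp$activations[[length(fp$activations)]])
  if (any(!is.finite(risks))) {
    stop_memsurv("non-finite risk scores produced by forward pass",
                 "memsurv_numeric_error")
  }
  risks
}

#' Serialize a network to JSON / restore it
#'
#' The JSON schema stores the layer sizes, row-major weight lists, biases,
#' activation tags, and (for quantized models) the grid metadata under
#' `grid`. A `schema` version field guards future changes.
#'
#' @param network A `dense_network`.
#' @param path Output JSON path.
#' @return `path` invisibly (`write_network_json`); a `dense_network`
#'   (`read_network_json`).
#' @export
write_network_json <- function(network, path) {
  validate_network(network)
  obj <- list(
    schema = 1L,
    layer_dims = network$layer_dims,
    weights = lapply(network$weights, function(w) as.vector(t(w))),
    biases = network$biases,
    hidden_activation = network$hidden_activation,
    output_activation = network$output_activation
  )
  if (!is.null(network$center)) {
    obj$input_center <- network$center
    obj$input_scale <- network$scale
  }
  if (!is.null(network$grid)) {
    obj$grid <- list(step = network$grid$step,
                     conductance_scale = network$grid$conductance_scale,
                     levels = network$grid$levels)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dims <- as.integer(obj$layer_dims)
  net <- dense_network(dims)
  net$weights <- lapply(seq_along(net$weights), function(l) {
    matrix(obj$weights[[l]], nrow = dims[l], ncol = dims[l + 1L], byrow = TRUE)
  })
  net$biases <- lapply(obj$biases, as.numeric)
  if (!is.null(obj$input_center)) {
    net$center <- unlist(obj$input_center)
    net$scale <- unlist(obj$input_scale)
  }
  if (!is.null(obj$grid)) {
    net$grid <- quant_grid(step = obj$grid$step,
                           conductance_scale = obj$grid$conductance_scale)
  }
  validate_network(net)
  net
}
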