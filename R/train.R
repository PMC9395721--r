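#' Training configuration
#'
#' Hyper-parameters of the Cox partial-likelihood trainer. The network is
#' trained full-batch with a momentum-free adaptive optimizer (RMSprop);
#' after every optimizer step the weights are hard-clipped to
#' `[-clip, +clip]` so the final weights stay inside the range the
#' 17-level differential conductance grid can represent.
#'
#' @param epochs Number of training epochs (default 500).
#' @param learning_rate RMSprop step size (default 1e-3).
#' @param dropout_rate Per-hidden-layer dropout probability during
#'   training (default 0.2); inference is always dropout-free.
#' @param clip Weight-range clip bound in weight units (default 2.0).
#' @param seed Integer seed controlling initialization order, dropout
#'   masks, and any other randomness of a training run.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 500L, learning_rate = 1e-3,
                         dropout_rate = 0.2, clip = 2.0, seed = 1L) {
  if (!is_count(epochs)) {
    stop_memsurv("epochs must be a positive integer", "memsurv_parameter_error")
  }
  if (clip <= 0) {
    stop_memsurv("clip bound must be > 0", "memsurv_parameter_error")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_memsurv("dropout_rate must lie in [0, 1)", "memsurv_parameter_error")
  }
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 dropout_rate = dropout_rate, clip = clip,
                 seed = as.integer(seed)),
            class = "train_config")
}

dataset_matrices <- function(dataset) {
  df <- as.data.frame(dataset)
  list(x = as.matrix(df[, c("age", "sex", "bmi", "chf", "miord")]),
       times = df$time, events = df$event)
}

# Min-max scale covariates to [0, 1] (binary columns pass through
# unchanged). Keeping the network inputs non-negative matters downstream:
# the crossbar DACs emit non-negative read voltages only. The scaling
# constants are stored on the network so risk_score() reapplies them.
standardize <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- apply(x, 2, min)
  if (is.null(scale)) {
    scale <- apply(x, 2, max) - center
    scale[scale == 0] <- 1
  }
  list(x = sweep(sweep(x, 2L, center), 2L, scale, "/"),
       center = center, scale = scale)
}

# One backpropagation pass; returns gradients for all weights and biases.
backprop <- function(network, x_aug, times, events, dropout_masks) {
  fp <- forward_pass(network, x_aug, dropout_masks)
  n_layers <- length(network$weights)
  risks <- drop(fp$activations[[n_layers + 1L]])
  if (any(!is.finite(risks))) return(NULL)
  n_events <- sum(events)
  delta <- matrix(cox_partial_gradient(risks, times, events) / n_events,
                  ncol = 1L)
  gw <- vector("list", n_layers)
  gb <- vector("list", n_layers)
  for (l in rev(seq_len(n_layers))) {
    gw[[l]] <- crossprod(fp$activations[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(network$weights[[l]])
      if (!is.null(dropout_masks)) delta <- delta * dropout_masks[[l - 1L]]
      delta <- delta * (fp$pre[[l - 1L]] > 0)
    }
  }
  list(gw = gw, gb = gb)
}

# Core optimizer loop shared by train() and inq_train(). `mask` (optional)
# is a per-layer logical matrix of weights to re-project onto `grid` at the
# end of every epoch. Assumes the RNG is already seeded by the caller.
run_training <- function(network, x_aug, times, events, config,
                         mask = NULL, grid = NULL, context = "training") {
  n_layers <- length(network$weights)
  n <- nrow(x_aug)
  sq_w <- lapply(network$weights, function(w) w * 0)
  sq_b <- lapply(network$biases, function(b) b * 0)
  rho <- 0.9
  eps <- 1e-8
  lr <- config$learning_rate
  for (epoch in seq_len(config$epochs)) {
    masks <- NULL
    if (config$dropout_rate > 0) {
      keep <- 1 - config$dropout_rate
      masks <- lapply(seq_len(n_layers - 1L), function(l) {
        matrix(stats::rbinom(n * network$layer_dims[l + 1L], 1L, keep) / keep,
               nrow = n)
      })
    }
    g <- backprop(network, x_aug, times, events, masks)
    if (is.null(g)) {
      stop_memsurv(sprintf("%s diverged (non-finite loss) at epoch %d",
                           context, epoch),
                   "memsurv_training_error")
    }
    for (l in seq_len(n_layers)) {
      sq_w[[l]] <- rho * sq_w[[l]] + (1 - rho) * g$gw[[l]]^2
      sq_b[[l]] <- rho * sq_b[[l]] + (1 - rho) * g$gb[[l]]^2
      network$weights[[l]] <- network$weights[[l]] -
        lr * g$gw[[l]] / sqrt(sq_w[[l]] + eps)
      network$biases[[l]] <- network$biases[[l]] -
        lr * g$gb[[l]] / sqrt(sq_b[[l]] + eps)
      network$weights[[l]][network$weights[[l]] > config$clip] <- config$clip
      network$weights[[l]][network$weights[[l]] < -config$clip] <- -config$clip
    }
    if (!is.null(mask)) {
      for (l in seq_len(n_layers)) {
        w <- network$weights[[l]]
        w[mask[[l]]] <- quantize_value(w[mask[[l]]], grid)
        network$weights[[l]] <- w
      }
    }
  }
  network
}

#' Train a DeepSurv network by Cox partial likelihood
#'
#' Full-batch gradient descent (RMSprop) on the Breslow negative log
#' partial likelihood, with per-hidden-layer dropout during training and
#' hard weight clipping to `[-clip, +clip]` after every step. Covariates
#' are standardized internally (constants folded into the network object),
#' and all randomness derives from `config$seed`, so identical calls give
#' bit-identical weights.
#'
#' @param network Starting `dense_network`; if `NULL`, a fresh default
#'   6-48-48-1 network is initialized from the seed.
#' @param dataset A `survival_dataset` with at least one observed event.
#' @param config A [train_config()].
#' @return The trained `dense_network`. The evaluation-mode loss before and
#'   after training is attached as `attr(, "loss")`.
#' @export
train <- function(network = NULL, dataset, config = train_config()) {
  dm <- dataset_matrices(dataset)
  if (sum(dm$events) < 1) {
    stop_memsurv("training requires at least one observed event",
                 "memsurv_parameter_error")
  }
  with_seed(config$seed, {
    if (is.null(network)) network <- dense_network(seed = config$seed)
    validate_network(network)
    std <- standardize(dm$x, network$center, network$scale)
    network$center <- std$center
    network$scale <- std$scale
    x_aug <- augment_inputs(std$x, network$layer_dims[1L])
    loss0 <- cox_partial_loss(drop(forward_pass(network, x_aug)$activations[[
      length(network$weights) + 1L]]), dm$times, dm$events)
    network <- run_training(network, x_aug, dm$times, dm$events, config)
    loss1 <- cox_partial_loss(drop(forward_pass(network, x_aug)$activations[[
      length(network$weights) + 1L]]), dm$times, dm$events)
    attr(network, "loss") <- c(initial = loss0, final = loss1)
    network
  })
}
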