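#' Enumerate differential conductance pairs for a target weight
#'
#' A signed synaptic weight is realized as the difference W = G+ - G- of
#' two programmed cells. For any target that is a multiple of 25 uS in
#' [-200, 200] this enumerates every ordered level pair (L1-L9 on both
#' sides) whose programming-target difference equals the target: e.g.
#' 125 uS is reachable as (150, 25), (175, 50), (200, 75) or (225, 100),
#' while +200 uS forces the single pair (225, 25).
#'
#' @param target Target differential conductance, uS.
#' @return Data frame with columns `pos`, `neg` (level ids), `g_pos`,
#'   `g_neg`, `midpoint`, `total` (uS).
#' @export
differential_pairs <- function(target) {
  if (!is_scalar_num(target) || abs(target) > 200 ||
      target %% 25 != 0) {
    stop_memsurv("target must be a multiple of 25 uS in [-200, 200]",
                 "memsurv_parameter_error")
  }
  g <- level_targets()
  grid <- expand.grid(pos = level_ids, neg = level_ids,
                      stringsAsFactors = FALSE)
  grid$g_pos <- unname(g[grid$pos])
  grid$g_neg <- unname(g[grid$neg])
  out <- grid[grid$g_pos - grid$g_neg == target, , drop = FALSE]
  out$midpoint <- (out$g_pos + out$g_neg) / 2
  out$total <- out$g_pos + out$g_neg
  rownames(out) <- NULL
  out[order(out$g_pos), ]
}

# Pick the pair for one grid target under the base-level strategy:
# midpoint closest to the base level's conductance, ties toward the lower
# total conductance (read energy). L1 is only admissible where it is
# unavoidable (|target| = 200 uS).
choose_pair <- function(target, base_g) {
  pairs <- differential_pairs(target)
  if (abs(target) < 200) {
    pairs <- pairs[pairs$pos != "L1" & pairs$neg != "L1", , drop = FALSE]
  }
  score <- abs(pairs$midpoint - base_g)
  best <- which(score == min(score))
  if (length(best) > 1) best <- best[which.min(pairs$total[best])]
  pairs[best, , drop = FALSE]
}

#' Assign differential conductance pairs to a quantized network
#'
#' Maps every weight of the two crossbar layers (6x48 and 48x48) to a
#' (G+, G-) level pair under a base-level strategy: among all pairs whose
#' difference realizes the weight's conductance target exactly, the pair
#' whose midpoint is closest to the base level's target is chosen, with
#' ties broken toward the lower total conductance. A zero weight maps to
#' (base, base); the extreme weights of +-2 weight units (+-200 uS)
#' necessarily pair L9 with L1. L1 itself is never a base level (it is
#' too unstable a state to center the mapping on).
#'
#' @param network A fully quantized `dense_network` (every mapped weight
#'   on the grid).
#' @param grid The [quant_grid()] (defaults to the one carried by the
#'   network).
#' @param base_level Base level `"L2"`-`"L9"`.
#' @param algorithm `"ml_set"` or `"ml_hybrid"`.
#' @return A `differential_assignment`: per-layer matrices of positive and
#'   negative level indices plus the strategy metadata.
#' @export
assign_pairs <- function(network, grid = NULL, base_level, algorithm) {
  validate_network(network)
  grid <- grid %||% network$grid
  if (is.null(grid)) {
    stop_memsurv("no quantization grid: pass `grid` or quantize the network first",
                 "memsurv_parameter_error")
  }
  base_level <- normalize_level(base_level)
  if (base_level == "L1") {
    stop_memsurv("L1 cannot serve as the base level", "memsurv_parameter_error")
  }
  if (!algorithm %in% c("ml_set", "ml_hybrid")) {
    stop_memsurv(sprintf("unknown algorithm '%s'", algorithm),
                 "memsurv_parameter_error")
  }
  g <- level_targets()
  base_g <- unname(g[base_level])
  lookup <- lapply(grid$levels, function(w) {
    choose_pair(w * grid$conductance_scale, base_g)
  })
  names(lookup) <- format(grid$levels)
  mapped_layers <- seq_len(length(network$weights) - 1L)
  layers <- lapply(mapped_layers, function(l) {
    w <- network$weights[[l]]
    off <- quantization_error(w, grid)
    if (any(off > 1e-9)) {
      stop_memsurv(sprintf("layer %d is not fully on the quantization grid", l),
                   "memsurv_parameter_error")
    }
    idx <- match(round(w / grid$step), round(grid$levels / grid$step))
    pos <- matrix(vapply(lookup[idx], function(p) match(p$pos, level_ids), 0L),
                  nrow(w), ncol(w))
    neg <- matrix(vapply(lookup[idx], function(p) match(p$neg, level_ids), 0L),
                  nrow(w), ncol(w))
    list(pos = pos, neg = neg)
  })
  structure(list(layers = layers, base_level = base_level,
                 algorithm = algorithm, grid = grid),
            class = "differential_assignment")
}

#' Count assigned cells per conductance level
#'
#' Tallies how many physical cells (both polarities of every mapped
#' synapse) each conductance level receives in an assignment; input for
#' [programming_energy()].
#'
#' @param assignment A [assign_pairs()] result.
#' @return Named count vector over `"L1"`-`"L9"`.
#' @export
assignment_level_counts <- function(assignment) {
  idx <- unlist(lapply(assignment$layers, function(l) c(l$pos, l$neg)))
  counts <- tabulate(idx, nbins = 9L)
  stats::setNames(counts, level_ids)
}

pair_map_skeleton <- function(algorithm, t, stat) {
  lv <- paste0("L", 2:9)
  m <- matrix(NA_real_, 8, 8, dimnames = list(pos = lv, neg = lv))
  structure(m, algorithm = algorithm, t = t, stat = stat,
            class = c("pair_stat_map", "matrix"))
}

# Draw one independent conductance sample per (level, polarity role);
# reused across the 64 pairs of a map so a map costs 16 x n_mc draws while
# G+ and G- stay independent within every pair (including the diagonal).
draw_role_samples <- function(algorithm, t, n_mc, config) {
  lv <- paste0("L", 2:9)
  list(
    pos = lapply(stats::setNames(lv, lv), function(l) {
      draw_mixture(distribution_at(l, algorithm, t, config), n_mc)
    }),
    neg = lapply(stats::setNames(lv, lv), function(l) {
      draw_mixture(distribution_at(l, algorithm, t, config), n_mc)
    })
  )
}

#' Monte-Carlo sigma map of differential conductances
#'
#' For every ordered pair (G+, G-) of the usable levels L2-L9, draws
#' `n_mc` independent paired conductance samples at time `t` and records
#' the standard deviation of the difference. High levels drift least, so
#' the map shrinks toward the high-level corner; drift only widens it
#' over time.
#'
#' @param algorithm `"ml_set"` or `"ml_hybrid"`.
#' @param t Hours since programming.
#' @param n_mc Monte-Carlo draws per pair (default 2000).
#' @param seed Integer seed.
#' @param config A [device_config()].
#' @return An 8x8 `pair_stat_map` (rows G+, columns G-), uS.
#' @export
sigma_map <- function(algorithm, t, n_mc = 2000L, seed = 1L,
                      config = device_config()) {
  if (!is_count(n_mc) || n_mc < 2) {
    stop_memsurv("n_mc must be an integer >= 2", "memsurv_parameter_error")
  }
  m <- pair_map_skeleton(algorithm, t, "sigma")
  samples <- with_seed(seed, draw_role_samples(algorithm, t, n_mc, config))
  for (a in rownames(m)) {
    for (b in colnames(m)) {
      m[a, b] <- stats::sd(samples$pos[[a]] - samples$neg[[b]])
    }
  }
  m
}

#' Monte-Carlo quantization-error-rate map
#'
#' Same sampling scheme as [sigma_map()], but recording the fraction of
#' differential samples falling farther than `bound` (default 12.5 uS,
#' half the 25 uS grid step) from the pair's target difference -- i.e. the
#' probability that a programmed weight reads closer to a neighboring
#' quantization level than to its own.
#'
#' @inheritParams sigma_map
#' @param bound Error bound, uS (default 12.5).
#' @return An 8x8 `pair_stat_map` of rates in \[0, 1\].
#' @export
quant_error_rate_map <- function(algorithm, t, n_mc = 2000L, seed = 1L,
                                 config = device_config(), bound = 12.5) {
  if (!is_count(n_mc)) {
    stop_memsurv("n_mc must be a positive integer", "memsurv_parameter_error")
  }
  g <- level_targets()
  m <- pair_map_skeleton(algorithm, t, "error_rate")
  samples <- with_seed(seed, draw_role_samples(algorithm, t, n_mc, config))
  for (a in rownames(m)) {
    for (b in colnames(m)) {
      target <- g[a] - g[b]
      m[a, b] <- mean(abs(samples$pos[[a]] - samples$neg[[b]] - target) > bound)
    }
  }
  m
}

#' Write a pair statistic map as CSV
#'
#' Serializes an 8x8 [sigma_map()] / [quant_error_rate_map()] result with
#' level-id row and column headers.
#'
#' @param map A `pair_stat_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_map_csv <- function(map, path) {
  df <- data.frame(level = rownames(map), as.data.frame(unclass(map)[, ]))
  names(df) <- c("level", colnames(map))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
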