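test_that("level targets are 25 uS (L1) plus 50-225 uS in 25 uS steps", {
  g <- level_targets()
  expect_equal(unname(g["L1"]), 25)
  expect_equal(unname(g["L9"]), 225)
  expect_equal(unique(diff(g[paste0("L", 2:9)])), 25)
  expect_equal(25, (225 - 50) / 7)
})

test_that("the mixture mean sits on target at t = 0 and saturates as t grows", {
  cfg <- device_config()
  for (alg in c("ml_set", "ml_hybrid")) {
    for (l in paste0("L", 1:9)) {
      d0 <- distribution_at(l, alg, 0, cfg)
      expect_equal(d0$mean, d0$target, tolerance = 1e-12)
      lm <- cfg$algorithms[[alg]]$levels[[l]]
      dinf <- distribution_at(l, alg, 1e6, cfg)
      expect_equal(dinf$mean, d0$target + lm$sign * lm$mu_inf * lm$p_drift,
                   tolerance = 1e-9)
    }
  }
})

test_that("ML-Set L5 drifts downward over a week", {
  d <- distribution_at("L5", "ml_set", 168, device_config())
  expect_lt(d$mean, d$target)
})

test_that("drift displacement is monotone in time and decreasing across L2-L5", {
  cfg <- device_config()
  disp <- function(l, t) abs(distribution_at(l, "ml_set", t, cfg)$mean -
                               level_targets()[l])
  for (l in paste0("L", 2:5)) {
    d_t <- vapply(c(0, 24, 72, 168), function(t) disp(l, t), 0)
    expect_true(all(diff(d_t) >= 0))
  }
  d_168 <- vapply(paste0("L", 2:5), function(l) disp(l, 168), 0)
  expect_true(all(diff(d_168) <= 0))
})

test_that("ML-Hybrid mitigates the week-long drift of the low levels", {
  cfg <- device_config()
  for (l in paste0("L", 2:5)) {
    tgt <- level_targets()[l]
    set_disp <- abs(distribution_at(l, "ml_set", 168, cfg)$mean - tgt)
    hyb_disp <- abs(distribution_at(l, "ml_hybrid", 168, cfg)$mean - tgt)
    expect_lt(hyb_disp, set_disp)
  }
})

test_that("sampling is seed-reproducible and respects degenerate configs", {
  s1 <- sample_conductance("L4", "ml_set", 168, 500, seed = 8)
  s2 <- sample_conductance("L4", "ml_set", 168, 500, seed = 8)
  expect_identical(as.numeric(s1), as.numeric(s2))
  expect_true(all(s1 >= 0))
  cfg <- degenerate_config()
  s <- sample_conductance("L3", "ml_hybrid", 100, 200, seed = 1, config = cfg)
  expect_equal(as.numeric(s), rep(75, 200), tolerance = 1e-6)
})

test_that("sample moments match the analytic mixture moments", {
  # all 18 level/algorithm combinations at t = 0, and the drifted state at
  # 168 h for L2-L9 (L1's drifted component nears the 0 uS truncation
  # bound, where the untruncated analytic moments no longer apply)
  n <- 20000
  cases <- rbind(
    expand.grid(alg = c("ml_set", "ml_hybrid"), l = paste0("L", 1:9), t = 0),
    expand.grid(alg = c("ml_set", "ml_hybrid"), l = paste0("L", 2:9), t = 168)
  )
  for (k in seq_len(nrow(cases))) {
    d <- distribution_at(as.character(cases$l[k]), as.character(cases$alg[k]),
                         cases$t[k], device_config())
    s <- sample_conductance(as.character(cases$l[k]),
                            as.character(cases$alg[k]),
                            cases$t[k], n, seed = 400 + k)
    expect_lt(abs(mean(s) - d$mean), 4 * d$sd / sqrt(n))
    expect_lt(abs(sd(s) - d$sd) / d$sd, 0.05)
  }
})

test_that("programming energy doubles only for the hybrid low levels", {
  high <- c(L6 = 100, L7 = 50, L8 = 25, L9 = 10)
  expect_equal(programming_energy(high, "ml_set"),
               programming_energy(high, "ml_hybrid"))
  low <- c(L2 = 40, L3 = 30, L4 = 20, L5 = 10)
  expect_equal(programming_energy(low, "ml_hybrid") /
                 programming_energy(low, "ml_set"), 2.0)
  expect_equal(programming_energy(c(L2 = 0), "ml_set"), 0)
})

test_that("invalid levels, algorithms and counts are rejected", {
  expect_error(distribution_at("L10", "ml_set", 0),
               class = "memsurv_parameter_error")
  expect_error(distribution_at("L2", "ml_fast", 0),
               class = "memsurv_parameter_error")
  expect_error(sample_conductance("L2", "ml_set", 0, n = 0, seed = 1),
               class = "memsurv_parameter_error")
  expect_error(distribution_at("L2", "ml_set", -1),
               class = "memsurv_parameter_error")
  expect_error(programming_energy(c(L2 = -1), "ml_set"),
               class = "memsurv_parameter_error")
})

test_that("the config loader enforces the shared L6-L9 models", {
  cfg <- yaml::read_yaml(system.file("extdata", "device_defaults.yaml",
                                     package = "memsurv"))
  cfg$algorithms$ml_hybrid$levels$L7$sigma0 <- 9.9
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  expect_error(device_config(path), class = "memsurv_format_error")
})
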