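test_that("analog MVM obeys Ohm and Kirchhoff", {
  g <- matrix(100, 1, 1)
  expect_equal(analog_mvm(g, 0.2), 20)          # 100 uS x 0.2 V = 20 uA
  expect_equal(analog_mvm(matrix(5, 3, 4), rep(0, 3)), rep(0, 4))
  set.seed(41)
  G <- matrix(runif(48 * 48, 0, 225), 48, 48)
  v <- runif(48, 0, 0.3)
  oracle <- as.vector(t(G) %*% v)
  expect_equal(analog_mvm(G, v), oracle, tolerance = 1e-12)
  expect_error(analog_mvm(G, runif(10)), class = "memsurv_shape_error")
})

test_that("the survival network maps onto exactly four crossbars within 64x64", {
  m <- build_mapped_network(fix_assign, fix_qnet, mode = "ideal")
  expect_length(m$crossbars, 4)
  for (cb in m$crossbars) {
    expect_lte(nrow(cb$conductance), 64)
    expect_lte(ncol(cb$conductance), 64)
    expect_true(all(cb$conductance >= 0))
  }
})

test_that("an oversized layer raises a capacity error", {
  big <- dense_network(c(70L, 48L, 48L, 1L))
  for (l in 1:3) big$weights[[l]][] <- 0
  big$grid <- quant_grid()
  a <- assign_pairs(big, base_level = "L6", algorithm = "ml_set")
  expect_error(build_mapped_network(a, big, mode = "ideal"),
               class = "memsurv_capacity_error")
})

test_that("ideal-device crossbar inference equals the quantized forward pass", {
  m <- build_mapped_network(fix_assign, fix_qnet, mode = "ideal")
  r_analog <- crossbar_inference(m, fix_data)
  r_digital <- risk_score(fix_qnet, fix_data)
  expect_equal(r_analog, r_digital, tolerance = 1e-9)
})

test_that("risks are invariant to the read voltage while power scales with its square", {
  m1 <- build_mapped_network(fix_assign, fix_qnet, mode = "ideal",
                             v_read_max = 0.3)
  m2 <- build_mapped_network(fix_assign, fix_qnet, mode = "ideal",
                             v_read_max = 0.15)
  expect_equal(crossbar_inference(m1, fix_data),
               crossbar_inference(m2, fix_data), tolerance = 1e-12)
  p1 <- mvm_power(m1, fix_data)
  p2 <- mvm_power(m2, fix_data)
  expect_equal(p1 / p2, 4, tolerance = 1e-9)
})

test_that("read power ranks the operation modes P > S > H", {
  pw <- vapply(c("P", "S", "H"), function(md) {
    om <- operation_mode(md)
    a <- assign_pairs(fix_qnet, base_level = om$base_level,
                      algorithm = om$algorithm)
    mvm_power(build_mapped_network(a, fix_qnet, mode = "ideal"), fix_data)
  }, 0)
  expect_gt(pw["P"], pw["S"])
  expect_gt(pw["S"], pw["H"])
})

test_that("a single cell dissipates V^2 G and zero voltage draws nothing", {
  v <- 0.2
  i <- analog_mvm(matrix(100, 1, 1), v)   # 20 uA
  expect_equal(v * i, 4)                  # 4 uW
  expect_equal(analog_mvm(matrix(100, 1, 1), 0), 0)
})

test_that("zero-variability sampling reproduces the quantized concordance", {
  mc <- monte_carlo_cindex(fix_assign, fix_qnet, fix_data, t = 168,
                           n_runs = 5, seed = 2,
                           config = degenerate_config())
  expect_equal(mc$cindex, rep(mc$ideal_cindex, 5), tolerance = 1e-6)
})

test_that("Monte-Carlo concordance degrades and widens as device sigma grows", {
  med <- iqr <- numeric(3)
  for (i in seq_along(c(1, 2, 4))) {
    cfg <- scale_device_config(device_config(), sigma_mult = c(1, 2, 4)[i])
    mc <- monte_carlo_cindex(fix_assign, fix_qnet, fix_data, t = 0,
                             n_runs = 25, seed = 13, config = cfg)
    med[i] <- median(mc$cindex)
    iqr[i] <- IQR(mc$cindex)
  }
  expect_true(all(diff(med) < 0))
  expect_true(all(diff(iqr) > 0))
})

test_that("drift stress at a low base level breaks ML-Set before ML-Hybrid", {
  stress <- drift_amplitude_config(4)
  mins <- vapply(c("ml_set", "ml_hybrid"), function(alg) {
    a <- assign_pairs(fix_qnet, base_level = "L2", algorithm = alg)
    mc <- monte_carlo_cindex(a, fix_qnet, fix_data, t = 168, n_runs = 40,
                             seed = 11, config = stress)
    min(mc$cindex)
  }, 0)
  expect_lt(mins["ml_set"], 0.5)
  expect_gte(mins["ml_hybrid"], 0.5)
})

test_that("Monte-Carlo runs are reproducible per seed", {
  mc1 <- monte_carlo_cindex(fix_assign, fix_qnet, fix_data, t = 168,
                            n_runs = 4, seed = 6)
  mc2 <- monte_carlo_cindex(fix_assign, fix_qnet, fix_data, t = 168,
                            n_runs = 4, seed = 6)
  expect_identical(mc1$cindex, mc2$cindex)
})
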