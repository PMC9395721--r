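test_that("differential pairs enumerate the worked 125 uS example", {
  p <- differential_pairs(125)
  key <- paste(p$g_pos, p$g_neg)
  expect_true(all(c("150 25", "200 75") %in% key))
  expect_setequal(key, c("150 25", "175 50", "200 75", "225 100"))
})

test_that("extreme and zero targets have the expected pair sets", {
  expect_equal(nrow(differential_pairs(0)), 9)     # the nine same-level pairs
  p200 <- differential_pairs(200)
  expect_equal(nrow(p200), 1)
  expect_equal(c(p200$g_pos, p200$g_neg), c(225, 25))
})

test_that("pair counts over the 17 targets partition the 81 level pairs", {
  targets <- seq(-200, 200, by = 25)
  expect_length(targets, 17)
  counts <- vapply(targets, function(t) nrow(differential_pairs(t)), 0)
  expect_equal(sum(counts), 81)
})

test_that("off-grid targets are rejected", {
  expect_error(differential_pairs(130), class = "memsurv_parameter_error")
  expect_error(differential_pairs(225), class = "memsurv_parameter_error")
})

test_that("base-level assignment follows the midpoint rule with energy ties", {
  # base L6 (150 uS), weight +25 uS: midpoints 137.5 and 162.5 tie at
  # distance 12.5; the lower-conductance pair (150, 125) wins
  net <- dense_network()
  net$weights[[1]][] <- 0.25
  net$weights[[2]][] <- 0
  net$weights[[3]][] <- 0
  net$grid <- quant_grid()
  a <- assign_pairs(net, base_level = "L6", algorithm = "ml_set")
  expect_true(all(a$layers[[1]]$pos == 6))  # G+ = L6 = 150 uS
  expect_true(all(a$layers[[1]]$neg == 5))  # G- = L5 = 125 uS
  # zero weights map to (base, base)
  expect_true(all(a$layers[[2]]$pos == 6))
  expect_true(all(a$layers[[2]]$neg == 6))
})

test_that("full-scale weights are forced onto the unique L9/L1 pair", {
  net <- dense_network()
  net$weights[[1]][] <- 2.0
  net$weights[[2]][] <- -2.0
  net$grid <- quant_grid()
  for (bl in c("L2", "L6", "L9")) {
    a <- assign_pairs(net, base_level = bl, algorithm = "ml_set")
    expect_true(all(a$layers[[1]]$pos == 9) && all(a$layers[[1]]$neg == 1))
    expect_true(all(a$layers[[2]]$pos == 1) && all(a$layers[[2]]$neg == 9))
  }
})

test_that("assignments hit every synapse's conductance target exactly", {
  g <- level_targets()
  for (l in seq_along(fix_assign$layers)) {
    lay <- fix_assign$layers[[l]]
    realized <- matrix(g[lay$pos] - g[lay$neg], nrow(lay$pos), ncol(lay$pos))
    expected <- fix_qnet$weights[[l]] * fix_qnet$grid$conductance_scale
    expect_equal(realized, expected, tolerance = 1e-12, ignore_attr = TRUE)
  }
  # L1 appears only where +-200 uS forces it
  counts <- assignment_level_counts(fix_assign)
  w_all <- unlist(fix_qnet$weights[1:2])
  expect_equal(unname(counts["L1"]), sum(abs(w_all) == 2))
})

test_that("L1 is rejected as a base level", {
  expect_error(assign_pairs(fix_qnet, base_level = "L1", algorithm = "ml_set"),
               class = "memsurv_parameter_error")
})

test_that("sigma map matches the Gaussian closed form without drift", {
  sig <- c(L2 = 2.0, L3 = 2.5, L4 = 3.0, L5 = 3.5, L6 = 1.5, L7 = 1.8,
           L8 = 2.2, L9 = 2.6)
  cfg <- scale_device_config(device_config(), drift_mult = 0)
  for (alg in c("ml_set", "ml_hybrid")) {
    for (l in names(sig)) cfg$algorithms[[alg]]$levels[[l]]$sigma0 <- unname(sig[l])
  }
  n_mc <- 2000
  m <- sigma_map("ml_set", t = 0, n_mc = n_mc, seed = 17, config = cfg)
  for (a in rownames(m)) for (b in colnames(m)) {
    closed <- sqrt(sig[a]^2 + sig[b]^2)
    se <- closed / sqrt(2 * (n_mc - 1))
    expect_lt(abs(m[a, b] - closed), 5 * se)
  }
})

test_that("drift only widens the sigma map over a week", {
  m0 <- sigma_map("ml_set", t = 0, n_mc = 2000, seed = 19)
  m168 <- sigma_map("ml_set", t = 168, n_mc = 2000, seed = 19)
  expect_true(all(m168 >= m0 - 0.2))        # elementwise, within MC noise
  expect_gt(mean(m168 - m0), 0)
})

test_that("a noise-free config collapses both maps to zero", {
  cfg <- degenerate_config()
  m <- sigma_map("ml_set", t = 168, n_mc = 500, seed = 3, config = cfg)
  expect_true(all(m < 1e-6))
  r <- quant_error_rate_map("ml_set", t = 168, n_mc = 500, seed = 3,
                            config = cfg)
  expect_true(all(r == 0))
})

test_that("a 12.5 uS differential sigma gives the 2*Phi(-1) error rate", {
  cfg <- gaussian_config(12.5 / sqrt(2))
  r <- quant_error_rate_map("ml_set", t = 0, n_mc = 2000, seed = 23,
                            config = cfg)
  expect_lt(abs(mean(r) - 2 * pnorm(-1)), 0.01)
  expect_true(all(abs(r - 2 * pnorm(-1)) < 0.06))
})

test_that("hybrid error rates on the drift-prone rows beat ML-Set at 168 h", {
  rs <- quant_error_rate_map("ml_set", t = 168, n_mc = 2000, seed = 29)
  rh <- quant_error_rate_map("ml_hybrid", t = 168, n_mc = 2000, seed = 29)
  low <- paste0("L", 2:5)
  expect_lt(mean(rh[low, ]), mean(rs[low, ]))
})

test_that("the sigma map is symmetric in distribution", {
  m <- sigma_map("ml_hybrid", t = 168, n_mc = 2000, seed = 31)
  for (a in rownames(m)) for (b in colnames(m)) {
    avg <- (m[a, b] + m[b, a]) / 2
    expect_lt(abs(m[a, b] - m[b, a]), 5 * avg / sqrt(2 * (2000 - 1)) + 1e-9)
  }
})

test_that("pair maps serialize to labeled CSV", {
  m <- sigma_map("ml_set", t = 0, n_mc = 100, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pair_map_csv(m, path)
  back <- utils::read.csv(path)
  expect_equal(back$level, paste0("L", 2:9))
  expect_equal(as.matrix(back[, -1]), unclass(m)[, ],
               ignore_attr = TRUE, tolerance = 1e-6)
})
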