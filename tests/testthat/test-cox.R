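# Exhaustive enumeration oracles, independent of the package internals.
oracle_loss <- function(h, tm, ev) {
  -sum(sapply(which(ev == 1), function(i) {
    h[i] - log(sum(exp(h[tm >= tm[i]])))
  }))
}

oracle_cindex <- function(h, tm, ev) {
  num <- den <- 0
  n <- length(h)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    if (ev[i] == 1 && (tm[i] < tm[j] || (tm[i] == tm[j] && ev[j] == 0))) {
      den <- den + 1
      num <- num + if (h[i] > h[j]) 1 else if (h[i] == h[j]) 0.5 else 0
    }
  }
  num / den
}

test_that("two equal-risk subjects with one early event give loss log 2", {
  expect_equal(cox_partial_loss(c(0, 0), c(1, 2), c(1, 0)), log(2),
               tolerance = 1e-12)
})

test_that("partial loss equals risk-set enumeration on a worked case", {
  h <- c(1, 0, -1); tm <- c(1, 2, 3); ev <- c(1, 1, 0)
  expect_equal(cox_partial_loss(h, tm, ev), oracle_loss(h, tm, ev),
               tolerance = 1e-12)
})

test_that("partial loss matches the oracle with tied event times", {
  set.seed(7)
  for (rep in 1:20) {
    n <- 25
    tm <- sample(1:8, n, replace = TRUE)
    ev <- rbinom(n, 1, 0.6); ev[1] <- 1
    h <- rnorm(n)
    expect_equal(cox_partial_loss(h, tm, ev), oracle_loss(h, tm, ev),
                 tolerance = 1e-9)
  }
})

test_that("partial loss is invariant to shifting all risks", {
  set.seed(3)
  h <- rnorm(40); tm <- rexp(40) + 0.1; ev <- rbinom(40, 1, 0.5); ev[1] <- 1
  expect_equal(cox_partial_loss(h + 5.3, tm, ev),
               cox_partial_loss(h, tm, ev), tolerance = 1e-10)
})

test_that("raising an event subject's risk above its risk set lowers the loss", {
  h <- c(0, 0, 0, 0); tm <- c(1, 2, 3, 4); ev <- c(1, 0, 1, 0)
  l0 <- cox_partial_loss(h, tm, ev)
  h[1] <- 2
  expect_lt(cox_partial_loss(h, tm, ev), l0)
})

test_that("zero events raise an undefined-loss error", {
  expect_error(cox_partial_loss(c(1, 2), c(1, 2), c(0, 0)),
               class = "memsurv_undefined_loss_error")
})

test_that("perfectly anti-ordered risks give C = 1 and ties give 0.5", {
  tm <- 1:6; ev <- rep(1, 6)
  expect_equal(concordance_index(rev(tm), tm, ev), 1)
  expect_equal(concordance_index(rep(0, 6), tm, ev), 0.5)
})

test_that("concordance equals exhaustive pair enumeration with censoring", {
  h <- c(2, 1, 3, 0); tm <- c(1, 2, 2.5, 4); ev <- c(1, 1, 0, 1)
  expect_equal(concordance_index(h, tm, ev), oracle_cindex(h, tm, ev))
  set.seed(11)
  for (rep in 1:20) {
    n <- 10
    tm <- sample(1:6, n, replace = TRUE)
    ev <- rbinom(n, 1, 0.6); ev[1] <- 1
    h <- round(rnorm(n), 1)  # provoke risk ties
    expect_equal(concordance_index(h, tm, ev), oracle_cindex(h, tm, ev))
  }
})

test_that("concordance agrees with the survival package", {
  skip_if_not_installed("survival")
  set.seed(19)
  for (rep in 1:10) {
    n <- 60
    tm <- sample(1:20, n, replace = TRUE)
    ev <- rbinom(n, 1, 0.6); ev[1] <- 1
    h <- rnorm(n)
    ours <- concordance_index(h, tm, ev)
    theirs <- survival::concordance(
      survival::Surv(tm, ev) ~ h, reverse = TRUE)$concordance
    expect_equal(ours, theirs, tolerance = 1e-12)
  }
})

test_that("negating risks complements the concordance when no ties exist", {
  set.seed(23)
  for (rep in 1:10) {
    n <- 30
    tm <- runif(n) + 0.1
    ev <- rbinom(n, 1, 0.7); ev[1] <- 1
    h <- rnorm(n)
    expect_equal(concordance_index(-h, tm, ev),
                 1 - concordance_index(h, tm, ev), tolerance = 1e-12)
  }
})

test_that("all-censored data raise an undefined-concordance error", {
  expect_error(concordance_index(c(1, 2), c(1, 2), c(0, 0)),
               class = "memsurv_undefined_cindex_error")
})

test_that("the analytic risk gradient matches finite differences", {
  set.seed(31)
  n <- 25
  tm <- sample(1:10, n, replace = TRUE)
  ev <- rbinom(n, 1, 0.6); ev[1] <- 1
  h <- rnorm(n)
  g <- memsurv:::cox_partial_gradient(h, tm, ev)
  ng <- sapply(1:n, function(i) {
    e <- rep(0, n); e[i] <- 1e-6
    (cox_partial_loss(h + e, tm, ev) - cox_partial_loss(h - e, tm, ev)) / 2e-6
  })
  expect_equal(g, ng, tolerance = 1e-6)
})
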