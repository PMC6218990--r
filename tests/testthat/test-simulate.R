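test_that("marker blocks carry the intended correlation structure", {
  set.seed(61)
  X <- sim_markers(5000, 100)
  expect_equal(cor(X[, 1], X[, 2]), 0.6, tolerance = 0.05)
  expect_equal(cor(X[, 3], X[, 5]), 0.6^2, tolerance = 0.05)
  expect_lt(abs(cor(X[, 50], X[, 51])), 0.05)  # across the block boundary
  expect_equal(unname(apply(X[, 1:5], 2, var)), rep(1, 5), tolerance = 0.07)
})

test_that("survival-time generators have the right null means", {
  set.seed(62)
  X0 <- matrix(0, 10000, 1)
  expect_equal(mean(sim_times(X0, 0, "exponential")), 1, tolerance = 0.03)
  expect_equal(mean(sim_times(X0, 0, "weibull")), gamma(1.5), tolerance = 0.03)
  expect_equal(mean(sim_times(X0, 0, "gamma")), 0.8, tolerance = 0.03)
})

test_that("larger marker effects lengthen survival", {
  set.seed(63)
  X <- matrix(rnorm(20000), 10000, 2)
  tt <- sim_times(X, c(1, 0), "exponential")
  expect_gt(cor(X[, 1], log(tt)), 0.5)
})

test_that("the calibrated censoring bound hits its target on fresh data", {
  set.seed(64)
  pilot <- rexp(50000)
  K <- calibrate_censoring(pilot, 0.40)
  fresh_t <- rexp(10000)
  fresh_c <- runif(10000, 0, K)
  expect_lt(abs(mean(fresh_c < fresh_t) - 0.40), 0.02)
})

test_that("the censored fraction is monotone decreasing in the bound", {
  set.seed(65)
  pilot <- rgamma(20000, shape = 0.8)
  fr <- vapply(seq(0.2, 4, length.out = 15),
               function(K) mean(pmin(pilot, K)) / K, numeric(1))
  expect_true(all(diff(fr) < 0))
})

test_that("extreme censoring targets are rejected", {
  expect_error(calibrate_censoring(rexp(100), 0), "target")
  expect_error(calibrate_censoring(rexp(100), 0.99), "target")
})

test_that("scenarios map to the published design settings", {
  s1 <- scenario_settings(1); s4 <- scenario_settings(4); s6 <- scenario_settings(6)
  expect_equal(s1[c("family", "p")], list(family = "exponential", p = 1000L))
  expect_equal(s4[c("family", "shape", "p")],
               list(family = "weibull", shape = 2, p = 5000L))
  expect_equal(s6[c("family", "shape", "p")],
               list(family = "gamma", shape = 0.8, p = 5000L))
  expect_equal(s1$n, 500L)
})

test_that("a generated replication satisfies its own design contracts", {
  sc <- sim_scenario(1, seed = 66)
  expect_equal(sc$train$n, 500L)
  expect_equal(sc$train$p, 1000L)
  expect_equal(sc$test$n, 100L)
  nz <- sc$beta_true[sc$beta_true != 0]
  expect_equal(sort(nz), sort(c(-0.2, 0.2, -0.3, 0.3, -0.4, 0.4)))
  expect_equal(length(sc$causal), 6)
  # ~40% censoring target: events around 60%
  expect_lt(abs(mean(sc$train$status) - 0.60), 0.06)
  # censoring consistency: events keep their latent time, censored are cut
  ev <- sc$train$status == 1
  expect_true(all(sc$train$time[ev] == sc$uncensored[ev]))
  expect_true(all(sc$train$time[!ev] < sc$uncensored[!ev]))
  # training markers standardized
  expect_equal(max(abs(colMeans(sc$train$X))), 0, tolerance = 1e-12)
  expect_equal(unname(apply(sc$train$X[, 1:3], 2, sd)), rep(1, 3))
})

test_that("replications are bit-reproducible under a fixed seed", {
  a <- sim_scenario(3, seed = 9, n = 80, p = 50)
  b <- sim_scenario(3, seed = 9, n = 80, p = 50)
  expect_identical(a$train$time, b$train$time)
  expect_identical(a$train$X, b$train$X)
  expect_identical(a$beta_true, b$beta_true)
  expect_identical(a$K, b$K)
})

test_that("selection metrics match direct enumeration", {
  expect_equal(selection_metrics(c(1, 2), c(1, 2), 10),
               c(tpr = 1, fpr = 0, fdr = 0))
  expect_equal(selection_metrics(integer(0), c(1, 2), 10),
               c(tpr = 0, fpr = 0, fdr = 0))
  expect_equal(selection_metrics(c(1, 3, 4), c(1, 2), 10),
               c(tpr = 0.5, fpr = 0.25, fdr = 2 / 3))
})

test_that("effect MSE matches the naive loop", {
  expect_identical(beta_mse(c(1, 2), c(1, 2)), 0)
  expect_equal(beta_mse(c(1, 0), c(0, 0)), 0.5)
  set.seed(67)
  a <- rnorm(40); b <- rnorm(40)
  acc <- 0
  for (j in 1:40) acc <- acc + (a[j] - b[j])^2
  expect_equal(beta_mse(a, b), acc / 40, tolerance = 1e-12)
})

test_that("concordance handles perfect ordering and total ties", {
  expect_equal(harrells_c(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1)
  expect_equal(harrells_c(rep(0, 5), 1:5, rep(1, 5)), 0.5)
  expect_error(harrells_c(1, 1, 0), "usable")
})

test_that("concordance equals brute-force pair enumeration on censored data", {
  set.seed(68)
  for (r in 1:5) {
    time <- rexp(30)
    status <- rbinom(30, 1, 0.6)
    risk <- rnorm(30)
    expect_identical(harrells_c(risk, time, status),
                     brute_force_c(risk, time, status))
  }
})

test_that("concordance agrees with the survival package on untied data", {
  skip_if_not_installed("survival")
  set.seed(69)
  time <- rexp(80)
  status <- rbinom(80, 1, 0.7)
  risk <- -0.8 * log(time) + rnorm(80, sd = 0.5)
  cf <- survival::concordance(survival::Surv(time, status) ~ risk,
                              reverse = TRUE)
  expect_equal(harrells_c(risk, time, status), unname(cf$concordance),
               tolerance = 1e-12)
})

test_that("a reduced replication study returns coherent aggregate metrics", {
  st <- run_study(1, n_rep = 2, tau = c(0, 1), seed = 3,
                  n = 120, p = 50, grid = data.frame(v0 = c(0.002, 0.02),
                                                     v1 = c(10, 10)))
  expect_equal(nrow(st$per_rep), 4)
  expect_true(all(st$per_rep$tpr >= 0 & st$per_rep$tpr <= 1))
  expect_true(all(st$per_rep$fdr >= 0 & st$per_rep$fdr <= 1))
  expect_true(all(st$per_rep$cindex > 0 & st$per_rep$cindex < 1))
  expect_equal(st$summary$n_rep, c(2, 2))
  expect_equal(st$n_failed, 0)
})
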