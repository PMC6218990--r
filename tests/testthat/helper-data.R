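# small censored Weibull datasets and independent oracles used across tests

make_test_data <- function(n = 50, p = 3, seed = 1, beta = NULL,
                           alpha_true = 1, cens_frac = 0.3, q = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  if (is.null(beta)) beta <- numeric(p)
  Z <- if (q > 0) matrix(rnorm(n * q), n, q) else NULL
  lambda <- exp(-drop(X %*% beta))
  t_raw <- rweibull(n, shape = alpha_true, scale = lambda^(-1 / alpha_true))
  if (cens_frac > 0) {
    cc <- quantile(t_raw, 1 - cens_frac) * runif(n, 0.5, 1.5)
    time <- pmin(t_raw, cc)
    status <- as.numeric(t_raw <= cc)
  } else {
    time <- t_raw
    status <- rep(1, n)
  }
  surv_data(time, status, X, Z, standardize = FALSE)
}

# independent log-likelihood: per-subject loop through stats::dweibull /
# pweibull with scale = lambda^(-1/alpha) (so S(t) = exp(-lambda t^alpha))
naive_loglik <- function(d, beta, u, alpha) {
  eta <- drop(d$Z %*% u) + drop(d$X %*% beta)
  total <- 0
  for (i in seq_len(d$n)) {
    b <- exp(-eta[i])^(-1 / alpha)
    total <- total +
      if (d$status[i] == 1) dweibull(d$time[i], alpha, b, log = TRUE)
      else pweibull(d$time[i], alpha, b, lower.tail = FALSE, log.p = TRUE)
  }
  total
}

# central finite differences of the log-likelihood along every coordinate
fd_gradients <- function(d, beta, u, alpha, h = 1e-6) {
  gb <- vapply(seq_along(beta), function(j) {
    bp <- beta; bp[j] <- beta[j] + h
    bm <- beta; bm[j] <- beta[j] - h
    (weibull_loglik(d, bp, u, alpha) - weibull_loglik(d, bm, u, alpha)) / (2 * h)
  }, numeric(1))
  gu <- vapply(seq_along(u), function(j) {
    up <- u; up[j] <- u[j] + h
    um <- u; um[j] <- u[j] - h
    (weibull_loglik(d, beta, up, alpha) - weibull_loglik(d, beta, um, alpha)) / (2 * h)
  }, numeric(1))
  ga <- (weibull_loglik(d, beta, u, alpha + h) -
           weibull_loglik(d, beta, u, alpha - h)) / (2 * h)
  list(beta = gb, u = gu, alpha = ga)
}

fd_curvatures <- function(d, beta, u, alpha, h = 1e-4) {
  f0 <- weibull_loglik(d, beta, u, alpha)
  cb <- vapply(seq_along(beta), function(j) {
    bp <- beta; bp[j] <- beta[j] + h
    bm <- beta; bm[j] <- beta[j] - h
    (weibull_loglik(d, bp, u, alpha) - 2 * f0 +
       weibull_loglik(d, bm, u, alpha)) / h^2
  }, numeric(1))
  cu <- vapply(seq_along(u), function(j) {
    up <- u; up[j] <- u[j] + h
    um <- u; um[j] <- u[j] - h
    (weibull_loglik(d, beta, up, alpha) - 2 * f0 +
       weibull_loglik(d, beta, um, alpha)) / h^2
  }, numeric(1))
  ca <- (weibull_loglik(d, beta, u, alpha + h) - 2 * f0 +
           weibull_loglik(d, beta, u, alpha - h)) / h^2
  list(beta = cb, u = cu, alpha = ca)
}

# exhaustive all-pairs concordance: the brute-force oracle
brute_force_c <- function(risk, time, status) {
  n <- length(time)
  conc <- 0
  usable <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && status[i] == 1) {
      usable <- usable + 1
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] == risk[j]) conc <- conc + 0.5
    }
  }
  if (usable == 0) stop("no usable pairs")
  conc / usable
}
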