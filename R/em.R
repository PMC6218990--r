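#' Spike-and-slab prior specification
#'
#' The marker effects receive a two-component normal mixture prior: given the
#' latent inclusion indicator, `beta_j ~ N(0, sigma2 * v0)` (spike, excluded)
#' or `N(0, sigma2 * v1)` (slab, included). The common variance `sigma2` has
#' an inverse-gamma `IG(nu/2, nu*eta/2)` hyperprior and the inclusion rate
#' `theta` a `Beta(a, b)` hyperprior. Defaults `nu = eta = a = b = 1` make
#' both hyperpriors weakly informative (uniform on `theta`).
#'
#' @param v0 Spike variance (small, positive).
#' @param v1 Slab variance (large, positive, `> v0`).
#' @param nu,eta Inverse-gamma hyperparameters for `sigma2`.
#' @param a,b Beta hyperparameters for `theta`.
#' @return An object of class `"prior_spec"`.
#' @export
#' @examples
#' prior_spec(v0 = 1 / 1000, v1 = 10)
prior_spec <- function(v0, v1, nu = 1, eta = 1, a = 1, b = 1) {
  stopifnot(is.numeric(v0), is.numeric(v1), v0 > 0, nu > 0, eta > 0,
            a > 0, b > 0)
  if (v0 >= v1)
    stop("spike variance 'v0' must be strictly smaller than slab variance 'v1'")
  structure(list(v0 = v0, v1 = v1, nu = nu, eta = eta, a = a, b = b),
            class = "prior_spec")
}

#' EM fitting settings
#'
#' @param tol Convergence tolerance on the relative change of the marker
#'   linear predictor (default `1e-4`).
#' @param max_iter Hard cap on EM iterations (default 500).
#' @param full_sweeps Number of initial coordinate-descent cycles that visit
#'   every marker before restricting to the active set (default 5).
#' @param refresh_every After restriction, run a full cycle every this many
#'   cycles so late-rising effects are not frozen out (default 10).
#' @param max_inner Cap on coordinate-descent cycles within one M-step
#'   (default 200).
#' @param active_thresh Magnitude above which a coefficient stays in the
#'   active set (default `1e-8`).
#' @param trust_init Initial per-coordinate trust radius bounding a single
#'   Newton step (default 1).
#' @return An object of class `"fit_settings"`.
#' @export
fit_settings <- function(tol = 1e-4, max_iter = 500L, full_sweeps = 5L,
                         refresh_every = 10L, max_inner = 200L,
                         active_thresh = 1e-8, trust_init = 1) {
  stopifnot(tol > 0, max_iter >= 1, full_sweeps >= 1, refresh_every >= 1,
            max_inner >= 1, active_thresh > 0, trust_init > 0)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 full_sweeps = as.integer(full_sweeps),
                 refresh_every = as.integer(refresh_every),
                 max_inner = as.integer(max_inner),
                 active_thresh = active_thresh, trust_init = trust_init),
            class = "fit_settings")
}

#' E-step: posterior inclusion probabilities and precision weights
#'
#' For each marker, the conditional probability that it belongs to the slab
#' component given the current effect estimate,
#' `p*_j = P(gamma_j = 1 | beta_j, theta, sigma2)`, is the two-component
#' normal posterior ratio with variances `sigma2 * v1` (slab, prior weight
#' `theta`) and `sigma2 * v0` (spike, prior weight `1 - theta`). It is
#' evaluated on the log scale so that simultaneous underflow of both mixture
#' components cannot produce 0/0. The expected inverse prior variance
#' `d*_j = (1 - p*_j)/v0 + p*_j/v1` acts as an adaptive ridge weight in the
#' M-step.
#'
#' @param beta Current marker effects.
#' @param sigma2 Current common variance (positive).
#' @param theta Current inclusion rate in (0, 1).
#' @param prior A [prior_spec()].
#' @return A list with `p_star` (in `[0, 1]`) and `d_star`
#'   (in `[1/v1, 1/v0]`), both length `p`.
#' @export
#' @examples
#' # at beta = 0 with v0 = 1, v1 = 100: p* = 1/11
#' e_step(0, 1, 0.5, prior_spec(1, 100))$p_star
e_step <- function(beta, sigma2, theta, prior) {
  stopifnot(sigma2 > 0, theta > 0, theta < 1)
  log_slab <- stats::dnorm(beta, 0, sqrt(sigma2 * prior$v1), log = TRUE) +
    log(theta)
  log_spike <- stats::dnorm(beta, 0, sqrt(sigma2 * prior$v0), log = TRUE) +
    log1p(-theta)
  p_star <- stats::plogis(log_slab - log_spike)
  list(p_star = p_star,
       d_star = (1 - p_star) / prior$v0 + p_star / prior$v1)
}

#' Closed-form M-step update of the common prior variance
#'
#' `sigma2 <- (sum_j beta_j^2 d*_j + nu * eta) / (p + nu + 2)`.
#'
#' @param beta Marker effects after the current M-step.
#' @param d_star Precision weights from the E-step.
#' @param prior A [prior_spec()].
#' @return Updated positive scalar `sigma2`.
#' @export
update_sigma2 <- function(beta, d_star, prior) {
  (sum(beta^2 * d_star) + prior$nu * prior$eta) /
    (length(beta) + prior$nu + 2)
}

#' Closed-form M-step update of the inclusion rate
#'
#' `theta <- (sum_j p*_j + a - 1) / (a + b + p - 2)`; with the default
#' uniform `Beta(1, 1)` hyperprior this is the mean inclusion probability.
#'
#' @param p_star Inclusion probabilities from the E-step.
#' @param prior A [prior_spec()].
#' @return Updated `theta`.
#' @export
update_theta <- function(p_star, prior) {
  (sum(p_star) + prior$a - 1) / (prior$a + prior$b + length(p_star) - 2)
}

#' EM convergence statistic
#'
#' Relative change of the marker linear predictor between consecutive EM
#' iterations: `sum_i |X_i (beta_new - beta_old)| / (1 + sum_i |X_i beta_new|)`.
#' Only the marker design enters; the clinical predictor is excluded.
#'
#' @param X Marker matrix.
#' @param beta_new,beta_old Marker effects at iterations `k` and `k - 1`.
#' @return Nonnegative scalar.
#' @export
convergence_stat <- function(X, beta_new, beta_old) {
  stopifnot(length(beta_new) == length(beta_old))
  sum(abs(X %*% (beta_new - beta_old))) / (1 + sum(abs(X %*% beta_new)))
}

#' One trust-region cyclic coordinate descent cycle over the marker effects
#'
#' Performs a single cycle of the M-step update for `beta`: for each visited
#' coordinate, one Newton step on the penalized objective
#' `-logL + d*_j beta_j^2 / (2 sigma2)`, clipped to the coordinate's trust
#' radius, halved until the objective does not increase, with the radius then
#' rescheduled to `max(2 |step|, radius / 2)`. With `active_only = TRUE` only
#' coordinates whose current magnitude exceeds the active-set threshold are
#' visited.
#'
#' This is the package's workhorse and runs in compiled code; the exported
#' wrapper exists so the update can be driven and tested on its own.
#'
#' @param data A [surv_data()] object.
#' @param beta,u,alpha Current parameter values.
#' @param d_star Precision weights from [e_step()].
#' @param sigma2 Current common variance.
#' @param trust Per-coordinate trust radii (recycled scalar allowed).
#' @param settings A [fit_settings()].
#' @param active_only Restrict the cycle to the active set?
#' @return A list with updated `beta`, `eta` (full linear predictor),
#'   `trust`, and `n_skipped`.
#' @export
update_beta_ccd <- function(data, beta, u, alpha, d_star, sigma2,
                            trust = NULL, settings = fit_settings(),
                            active_only = FALSE) {
  if (is.null(trust)) trust <- rep(settings$trust_init, data$p)
  trust <- rep_len(trust, data$p)
  lp <- .linpred(data, beta, u, alpha)
  active <- if (active_only) which(abs(beta) > settings$active_thresh)
            else seq_len(data$p)
  res <- ccd_sweep(data$X, data$status, alpha * lp$logt, lp$eta,
                   beta, d_star, sigma2, trust, active - 1L)
  if (res$n_skipped > 0)
    warning(res$n_skipped, " coordinate step(s) skipped (degenerate or no descent)")
  res
}

#' One cycle of safeguarded Newton updates for the covariate effects
#'
#' Each coordinate of `u` takes a single Newton step
#' `u_j - (dlogL/du_j) / (d2logL/du_j^2)` using the freshest values of the
#' other coordinates; a step that would decrease the log-likelihood is halved
#' (up to 20 times) before acceptance.
#'
#' @inheritParams update_beta_ccd
#' @return A list with updated `u` and `eta`.
#' @export
update_u <- function(data, beta, u, alpha) {
  lp <- .linpred(data, beta, u, alpha)
  eta <- lp$eta
  alogt <- alpha * lp$logt
  for (j in seq_along(u)) {
    zj <- data$Z[, j]
    w <- exp(alogt - eta)
    g <- sum(zj * (w - data$status))
    h <- -sum(zj^2 * w)
    if (!is.finite(g) || h >= 0)
      stop("degenerate covariate column ", j, " in Newton update of u")
    step <- -g / h
    # halve until the (eta-dependent part of) -logL does not increase
    for (half in 0:20) {
      dF <- sum(data$status * zj * step + w * (exp(-zj * step) - 1))
      if (is.finite(dF) && dF <= 0) break
      step <- step / 2
      if (half == 20L) step <- 0
    }
    u[j] <- u[j] + step
    eta <- eta + zj * step
  }
  list(u = u, eta = eta)
}

#' Safeguarded Newton update for the Weibull shape
#'
#' One Newton step `alpha - (dlogL/dalpha) / (d2logL/dalpha^2)`; the step is
#' halved (up to 20 times) while it would drive the shape nonpositive or
#' decrease the log-likelihood. If no acceptable step is found the shape is
#' left unchanged with a warning.
#'
#' @inheritParams update_beta_ccd
#' @return Updated positive `alpha`.
#' @export
update_alpha <- function(data, beta, u, alpha) {
  lp <- .linpred(data, beta, u, alpha)
  w <- exp(alpha * lp$logt - lp$eta)
  g <- sum(data$status * (1 / alpha + lp$logt) - w * lp$logt)
  h <- -sum(data$status / alpha^2 + w * lp$logt^2)
  step <- -g / h
  ll0 <- sum(data$status * (log(alpha) + (alpha - 1) * lp$logt) - w)
  for (half in 0:20) {
    a_new <- alpha + step
    if (a_new > 0) {
      w_new <- exp(a_new * lp$logt - lp$eta)
      ll_new <- sum(data$status * (log(a_new) + (a_new - 1) * lp$logt) - w_new)
      if (is.finite(ll_new) && ll_new >= ll0) return(a_new)
    }
    step <- step / 2
  }
  warning("no acceptable Newton step for the shape; alpha left unchanged")
  alpha
}

#' Fit the spike-and-slab Weibull survival model by EM
#'
#' Seeks the posterior mode of the Weibull regression parameters under the
#' spike-and-slab prior by alternating an E-step (inclusion probabilities
#' `p*` and adaptive ridge weights `d*`) with an M-step that updates, in
#' order: the marker effects `beta`, the covariate effects `u` and shape
#' `alpha` (safeguarded one-step Newton), and `sigma2` and `theta` (closed
#' form). The `beta` update solves the adaptive-ridge penalized likelihood
#' problem at the current `d*` by trust-region cyclic coordinate descent:
#' cycles of single clipped Newton steps per coordinate, repeated until the
#' relative change of the marker linear predictor falls below
#' `settings$tol` (capped at `settings$max_inner` cycles). After
#' `settings$full_sweeps` initial full cycles the coordinate cycle is
#' restricted to the active set (coefficients above
#' `settings$active_thresh`), with a full refresh every
#' `settings$refresh_every` cycles. EM iteration stops when the relative
#' change of the marker linear predictor across EM iterations falls below
#' `settings$tol` (see [convergence_stat()]) or at `settings$max_iter`.
#'
#' Markers with final inclusion probability `p*_j >= 0.5` form the selected
#' set (the local median probability model). The fit is deterministic given
#' the data: no randomness is involved.
#'
#' Initialization: `beta = 0`; `u = 0` except the intercept at
#' `log(sum(T) / sum(delta))` (the exponential MLE); `alpha = 1`;
#' `sigma2 = 1`; `theta = 0.5`.
#'
#' @param data A [surv_data()] object.
#' @param prior A [prior_spec()].
#' @param settings A [fit_settings()].
#' @param init Optional warm start: a list with any of `beta`, `u`, `alpha`
#'   overriding the neutral initialization (used by path-wise tuning).
#' @return An object of class `"survemvs"`: list with `beta`, `u`, `alpha`,
#'   `sigma2`, `theta`, `p_star`, `d_star`, `selected` (indices with
#'   `p* >= 0.5`), `loglik`, `converged`, `n_iter`, `trace` (per-iteration
#'   convergence statistic), `prior`, `settings`.
#' @export
#' @examples
#' sc <- sim_scenario(1, n = 60, p = 20, seed = 1)
#' fit <- survemvs(sc$train, prior_spec(v0 = 1 / 20, v1 = 10))
#' fit$selected
survemvs <- function(data, prior, settings = fit_settings(), init = NULL) {
  stopifnot(inherits(data, "surv_data"), inherits(prior, "prior_spec"))
  p <- data$p
  beta <- numeric(p)
  u <- numeric(data$q + 1L)
  u[1L] <- log(sum(data$time) / max(sum(data$status), 1))
  alpha <- 1
  if (!is.null(init)) {
    if (!is.null(init$beta)) beta <- rep_len(init$beta, p)
    if (!is.null(init$u)) u <- rep_len(init$u, data$q + 1L)
    if (!is.null(init$alpha)) alpha <- init$alpha
  }
  sigma2 <- 1
  theta <- 0.5
  trust <- rep(settings$trust_init, p)

  zu <- drop(data$Z %*% u)
  xb <- if (any(beta != 0)) drop(data$X %*% beta) else numeric(data$n)
  eta <- zu + xb
  logt <- log(data$time)
  trace <- numeric(0)
  converged <- FALSE
  n_cycles <- 0L
  all_idx <- seq_len(p)

  for (k in seq_len(settings$max_iter)) {
    es <- e_step(beta, sigma2, theta, prior)
    xb_old <- xb

    # M-step for beta: CCD cycles to convergence at fixed d*, sigma2
    for (m in seq_len(settings$max_inner)) {
      full <- n_cycles < settings$full_sweeps ||
        n_cycles %% settings$refresh_every == 0L
      idx <- if (full) all_idx else which(abs(beta) > settings$active_thresh)
      n_cycles <- n_cycles + 1L
      if (!length(idx)) break
      res <- ccd_sweep(data$X, data$status, alpha * logt, eta,
                       beta, es$d_star, sigma2, trust, idx - 1L)
      d_eta <- sum(abs(res$eta - eta))
      beta <- res$beta; eta <- res$eta; trust <- res$trust
      if (d_eta / (1 + sum(abs(eta - zu))) < settings$tol) break
    }
    xb <- eta - zu

    # cycle the one-step Newton updates for u and alpha to joint
    # stationarity: stopping the outer loop on the marker predictor alone
    # would otherwise freeze them short of the M-step optimum
    for (m in 1:50) {
      u_old <- u
      alpha_old <- alpha
      uu <- update_u(data, beta, u, alpha)
      u <- uu$u
      alpha <- update_alpha(data, beta, u, alpha)
      if (max(abs(u - u_old)) < 1e-8 && abs(alpha - alpha_old) < 1e-8) break
    }
    zu <- drop(data$Z %*% u)
    eta <- zu + xb
    sigma2 <- update_sigma2(beta, es$d_star, prior)
    # keep theta off the boundary: an all-spike E-step would otherwise give
    # exactly 0 and break the next mixture evaluation
    theta <- min(max(update_theta(es$p_star, prior), 1e-12), 1 - 1e-12)

    cs <- sum(abs(xb - xb_old)) / (1 + sum(abs(xb)))
    trace <- c(trace, cs)
    if (cs < settings$tol) { converged <- TRUE; break }
  }

  es <- e_step(beta, sigma2, theta, prior)  # refresh at the final estimates
  names(beta) <- colnames(data$X)
  names(u) <- colnames(data$Z)
  structure(
    list(beta = beta, u = u, alpha = alpha, sigma2 = sigma2, theta = theta,
         p_star = stats::setNames(es$p_star, colnames(data$X)),
         d_star = es$d_star,
         selected = which(es$p_star >= 0.5),
         loglik = weibull_loglik(data, beta, u, alpha),
         converged = converged, n_iter = length(trace), trace = trace,
         prior = prior, settings = settings),
    class = "survemvs"
  )
}

#' @export
print.survemvs <- function(x, ...) {
  cat("Spike-and-slab Weibull EM fit\n")
  cat(sprintf("  prior: v0 = %.4g, v1 = %.4g\n", x$prior$v0, x$prior$v1))
  cat(sprintf("  %s after %d EM iteration(s); logLik = %.3f\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iter, x$loglik))
  cat(sprintf("  shape alpha = %.3f, sigma2 = %.4g, theta = %.4g\n",
              x$alpha, x$sigma2, x$theta))
  cat("  selected markers (p* >= 0.5):", length(x$selected), "\n")
  if (length(x$selected))
    print(round(x$beta[x$selected], 4))
  invisible(x)
}

#' Linear risk scores from a fitted model
#'
#' Prognostic risk is the negated linear predictor: higher risk means shorter
#' expected survival. By default only the marker contribution `-(X beta)` is
#' used; `use_covariates = TRUE` adds `-(Z u)`.
#'
#' @param object A fitted [survemvs()] model.
#' @param newdata A [surv_data()] object (markers already on the fitting
#'   scale).
#' @param use_covariates Include the clinical predictor in the score?
#' @param ... Unused.
#' @return Numeric risk scores, length `nrow(newdata$X)`.
#' @export
predict.survemvs <- function(object, newdata, use_covariates = FALSE, ...) {
  risk <- -drop(newdata$X %*% object$beta)
  if (use_covariates) risk <- risk - drop(newdata$Z %*% object$u)
  risk
}
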