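#' Simulate block-correlated marker matrices
#'
#' Markers are drawn in mutually independent blocks of `block` columns from a
#' zero-mean multivariate normal with unit variances and within-block
#' correlation `rho^|i - j|` (AR-style decay). A single Cholesky factor of
#' the `block x block` covariance is reused for every block.
#'
#' @param n Number of subjects.
#' @param p Number of markers (multiple of `block`).
#' @param rho Base within-block correlation (default 0.6).
#' @param block Block size (default 50).
#' @return An `n x p` numeric matrix with columns `m1..mp`.
#' @export
#' @examples
#' X <- sim_markers(100, 100)
#' cor(X[, 1], X[, 2])  # ~ 0.6
sim_markers <- function(n, p, rho = 0.6, block = 50L) {
  stopifnot(n >= 1, p >= 1, p %% block == 0, abs(rho) < 1)
  S <- rho^abs(outer(seq_len(block), seq_len(block), "-"))
  R <- chol(S)  # upper triangular; S = R'R
  nb <- p %/% block
  X <- matrix(stats::rnorm(n * p), n, p) # standard normal, then correlate blockwise
  for (b in seq_len(nb)) {
    idx <- ((b - 1L) * block + 1L):(b * block)
    X[, idx] <- X[, idx] %*% R
  }
  colnames(X) <- paste0("m", seq_len(p))
  X
}

#' Simulate uncensored survival times
#'
#' Event times follow the per-subject rate `lambda_i = exp(-X_i beta)`:
#' exponential times with rate `lambda_i`; Weibull times with shape 2 and
#' survival `exp(-lambda_i t^2)` (the model's own parameterization); or
#' gamma times with shape 0.8 and rate `1 / lambda_i`, a deliberate
#' misspecification stress case.
#'
#' @param X Marker matrix.
#' @param beta True marker effects.
#' @param family One of `"exponential"`, `"weibull"`, `"gamma"`.
#' @param shape Family shape: 1, 2 and 0.8 respectively (informational for
#'   exponential).
#' @return Positive times, length `nrow(X)`.
#' @export
sim_times <- function(X, beta, family = c("exponential", "weibull", "gamma"),
                      shape = NULL) {
  family <- match.arg(family)
  lambda <- exp(-drop(X %*% beta))
  n <- length(lambda)
  switch(family,
    exponential = stats::rexp(n, rate = lambda),
    # S(t) = exp(-lambda t^2)  <=>  Weibull(shape 2, scale lambda^(-1/2))
    weibull = stats::rweibull(n, shape = if (is.null(shape)) 2 else shape,
                              scale = lambda^(-1 / if (is.null(shape)) 2 else shape)),
    gamma = stats::rgamma(n, shape = if (is.null(shape)) 0.8 else shape,
                          rate = 1 / lambda)
  )
}

#' Calibrate a uniform censoring bound to a target censoring fraction
#'
#' Censoring times are `U(0, K)`; given a pilot sample of uncensored times
#' `t`, the expected censored fraction is `E[min(t, K)] / K`, a continuous
#' decreasing function of `K`. The bound achieving the target fraction is
#' found by bisection after bracket expansion.
#'
#' @param times Pilot sample of uncensored event times (recommended large,
#'   e.g. 50000 draws).
#' @param target Target censoring fraction, restricted to (0.05, 0.95).
#' @param tol Bisection tolerance on the achieved fraction (default 0.001).
#' @return The calibrated bound `K`.
#' @export
#' @examples
#' set.seed(1)
#' K <- calibrate_censoring(rexp(50000), 0.40)
#' mean(runif(10000, 0, K) < rexp(10000))  # ~ 0.40
calibrate_censoring <- function(times, target = 0.40, tol = 1e-3) {
  stopifnot(all(times > 0))
  if (target <= 0.05 || target >= 0.95)
    stop("'target' censoring fraction must lie in (0.05, 0.95)")
  cens_frac <- function(K) mean(pmin(times, K)) / K
  lo <- stats::median(times) / 100
  hi <- stats::median(times)
  for (i in 1:60) {
    if (cens_frac(hi) < target) break
    hi <- hi * 2
    if (i == 60L) stop("censoring target unreachable: bracket expansion failed")
  }
  for (i in 1:60) {
    if (cens_frac(lo) > target) break
    lo <- lo / 2
    if (i == 60L) stop("censoring target unreachable: bracket expansion failed")
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    f <- cens_frac(mid)
    if (abs(f - target) < tol) return(mid)
    if (f > target) lo <- mid else hi <- mid
  }
  mid
}

#' Scenario lookup: survival family and problem size
#'
#' Six study conditions cross three survival-time generators (exponential;
#' Weibull with shape 2; gamma with shape 0.8) with marker counts 1000 and
#' 5000 at n = 500.
#'
#' @param scenario Integer 1..6.
#' @return List with `family`, `shape`, `n`, `p`.
#' @export
scenario_settings <- function(scenario) {
  stopifnot(scenario %in% 1:6)
  fam <- c("exponential", "exponential", "weibull", "weibull",
           "gamma", "gamma")[scenario]
  shp <- c(1, 1, 2, 2, 0.8, 0.8)[scenario]
  list(family = fam, shape = shp, n = 500L,
       p = if (scenario %% 2L == 1L) 1000L else 5000L)
}

#' Generate one replication of a simulation scenario
#'
#' Assembles a full training/test pair under one of the six study conditions:
#' block-correlated markers, six causal markers with effects
#' `(-0.2, 0.2, -0.3, 0.3, -0.4, 0.4)` at positions drawn uniformly without
#' replacement, survival times from the scenario's family with rate
#' `exp(-X beta)`, and uniform `U(0, K)` censoring with `K` calibrated per
#' replication (from a pilot resampling this replication's rates) to censor
#' 40% of subjects on average. Training marker columns are standardized after
#' generation; the test matrix is scaled with the training constants.
#'
#' @param scenario Integer 1..6 (see [scenario_settings()]), or ignored when
#'   `family` is given explicitly.
#' @param seed Optional integer seed; the entire replication is reproducible
#'   given it.
#' @param n,p,n_test Override sample sizes (defaults 500/scenario p/100).
#' @param family,shape Override the survival-time generator.
#' @param censoring Target censoring fraction (default 0.40).
#' @param effects Causal effect sizes (default the six `±0.2/±0.3/±0.4`).
#' @param fixed_positions Optional integer vector of causal positions; by
#'   default positions are re-drawn each replication.
#' @param pilot Pilot sample size for censoring calibration (default 50000).
#' @return A list of class `"sim_scenario"`: `train`, `test` ([surv_data()]
#'   objects), `beta_true` (length `p`), `causal` (positions), `K`,
#'   `uncensored` (training event times before censoring), `settings`.
#' @export
#' @examples
#' sc <- sim_scenario(1, n = 100, p = 50, seed = 1)
#' mean(sc$train$status)  # ~ 0.6 events
sim_scenario <- function(scenario = 1, seed = NULL, n = NULL, p = NULL,
                         n_test = 100L, family = NULL, shape = NULL,
                         censoring = 0.40,
                         effects = c(-0.2, 0.2, -0.3, 0.3, -0.4, 0.4),
                         fixed_positions = NULL, pilot = 50000L) {
  ss <- scenario_settings(scenario)
  if (is.null(n)) n <- ss$n
  if (is.null(p)) p <- ss$p
  if (is.null(family)) family <- ss$family
  if (is.null(shape)) shape <- ss$shape
  if (!is.null(seed)) set.seed(seed)

  # the 50-marker correlated blocks are defined for p a multiple of 50;
  # smaller problems use independent markers
  block <- if (p %% 50L == 0L) 50L else 1L
  X <- sim_markers(n, p, block = block)
  X_test <- sim_markers(n_test, p, block = block)

  beta_true <- numeric(p)
  causal <- if (is.null(fixed_positions)) sample.int(p, length(effects))
            else fixed_positions
  beta_true[causal] <- effects[sample.int(length(effects))]

  t_train <- sim_times(X, beta_true, family, shape)
  t_test <- sim_times(X_test, beta_true, family, shape)

  # calibrate K from this replication's rate structure: pilot resamples rows
  lambda <- exp(-drop(X %*% beta_true))
  lam_pilot <- sample(lambda, pilot, replace = TRUE)
  t_pilot <- switch(family,
    exponential = stats::rexp(pilot, rate = lam_pilot),
    weibull = stats::rweibull(pilot, shape = shape, scale = lam_pilot^(-1 / shape)),
    gamma = stats::rgamma(pilot, shape = shape, rate = 1 / lam_pilot))
  K <- calibrate_censoring(t_pilot, censoring)

  c_train <- stats::runif(n, 0, K)
  c_test <- stats::runif(n_test, 0, K)

  train <- surv_data(pmin(t_train, c_train), as.numeric(t_train <= c_train), X)
  ctr <- attr(train$X, "center"); scl <- attr(train$X, "scale")
  Xts <- sweep(sweep(X_test, 2L, ctr, "-"), 2L, scl, "/")
  test <- surv_data(pmin(t_test, c_test), as.numeric(t_test <= c_test),
                    Xts, standardize = FALSE)

  structure(list(train = train, test = test, beta_true = beta_true,
                 causal = sort(causal), K = K, uncensored = t_train,
                 settings = list(scenario = scenario, n = n, p = p,
                                 n_test = n_test, family = family,
                                 shape = shape, censoring = censoring)),
            class = "sim_scenario")
}

#' Variable-selection accuracy against a known causal set
#'
#' @param selected Indices of selected markers.
#' @param truth Indices of true causal markers.
#' @param p Total number of candidate markers.
#' @return Named vector `c(tpr, fpr, fdr)`; an empty selection has FDR 0.
#' @export
#' @examples
#' selection_metrics(c(1, 3, 4), c(1, 2), 10)  # 0.5, 0.25, 2/3
selection_metrics <- function(selected, truth, p) {
  stopifnot(all(selected %in% seq_len(p)), all(truth %in% seq_len(p)))
  tp <- length(intersect(selected, truth))
  fp <- length(setdiff(selected, truth))
  c(tpr = if (length(truth)) tp / length(truth) else 0,
    fpr = if (p > length(truth)) fp / (p - length(truth)) else 0,
    fdr = if (tp + fp > 0) fp / (tp + fp) else 0)
}

#' Mean squared error of estimated marker effects
#'
#' `sum_j (betahat_j - beta_j)^2 / p`.
#'
#' @param beta_hat,beta_true Effect vectors of equal length.
#' @return Nonnegative scalar.
#' @export
beta_mse <- function(beta_hat, beta_true) {
  stopifnot(length(beta_hat) == length(beta_true))
  mean((beta_hat - beta_true)^2)
}

#' Harrell's concordance index under right censoring
#'
#' The fraction of usable subject pairs in which the subject with the higher
#' risk score fails earlier. A pair is usable when its survival ordering is
#' determined despite censoring: the earlier time is distinct and corresponds
#' to an observed event. Tied risk scores credit 1/2.
#'
#' @param risk Predicted risk scores (higher = worse prognosis).
#' @param time Observed times.
#' @param status Event indicators (1 = event, 0 = censored).
#' @return Concordance in `[0, 1]`; errors if no pair is usable.
#' @export
#' @examples
#' harrells_c(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1))  # 1
harrells_c <- function(risk, time, status) {
  n <- length(time)
  stopifnot(length(risk) == n, length(status) == n)
  earlier <- outer(time, time, "<")              # [i, j]: i fails strictly first
  usable <- earlier & (status == 1)              # ... with i's event observed
  if (!any(usable)) stop("no usable pairs: concordance is undefined")
  conc <- sum(usable & outer(risk, risk, ">")) +
    0.5 * sum(usable & outer(risk, risk, "=="))
  conc / sum(usable)
}

#' Replication study: selection, estimation and prediction accuracy
#'
#' Runs the full pipeline for one study condition: per replication, generate
#' a training/test pair with [sim_scenario()], tune the spike-and-slab
#' variances over the EBIC grid with [survemvs_tune()], and score the winning
#' fit at each requested `tau` — TPR/FPR/FDR of the selected set, MSE of the
#' effect estimates, and Harrell's c of the marker risk score `-(X beta)` on
#' the test set. Replications that fail are logged and excluded.
#'
#' @param scenario Integer 1..6.
#' @param n_rep Number of replications (the study condition uses 50).
#' @param tau EBIC penalty weights to report (default all of 0, 0.5, 1).
#' @param seed Integer seed governing all replications.
#' @param grid Hyperparameter grid; default the full [hyper_grid()] for the
#'   scenario's `p`.
#' @param settings A [fit_settings()].
#' @param ... Passed to [sim_scenario()] (e.g. reduced `n`, `p`).
#' @return An object of class `"survemvs_study"`: list with `per_rep` (data
#'   frame: one row per replication x tau) and `summary` (means by tau), plus
#'   `n_failed`.
#' @export
run_study <- function(scenario, n_rep = 50L, tau = c(0, 0.5, 1), seed = 1L,
                      grid = NULL, settings = fit_settings(), ...) {
  stopifnot(n_rep >= 1)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max %/% 2L, n_rep)
  rows <- list()
  n_failed <- 0L
  for (r in seq_len(n_rep)) {
    res <- tryCatch({
      sc <- sim_scenario(scenario, seed = rep_seeds[r], ...)
      g <- if (is.null(grid)) hyper_grid(sc$train$p) else grid
      tn <- survemvs_tune(sc$train, grid = g, tau = tau[1L],
                          settings = settings)
      out <- lapply(tau, function(tv) {
        crit <- tn$table[[paste0("ebic_", format(tv, trim = TRUE))]]
        best <- order(crit, -tn$table$v0, tn$table$v1)[1L]
        fit <- tn$fits[[best]]
        sm <- selection_metrics(fit$selected, sc$causal, sc$train$p)
        risk <- predict(fit, sc$test)
        data.frame(rep = r, tau = tv,
                   v0 = tn$table$v0[best], v1 = tn$table$v1[best],
                   n_selected = length(fit$selected),
                   tpr = sm[["tpr"]], fpr = sm[["fpr"]], fdr = sm[["fdr"]],
                   mse = beta_mse(fit$beta, sc$beta_true),
                   cindex = harrells_c(risk, sc$test$time, sc$test$status),
                   n_iter = fit$n_iter, converged = fit$converged)
      })
      do.call(rbind, out)
    }, error = function(e) {
      message("replication ", r, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) n_failed <- n_failed + 1L else rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows)) stop("all replications failed")
  per_rep <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per_rep, per_rep$tau), function(d)
    data.frame(tau = d$tau[1L], n_rep = nrow(d),
               tpr = mean(d$tpr), fpr = mean(d$fpr), fdr = mean(d$fdr),
               mse = mean(d$mse), cindex = mean(d$cindex),
               n_selected = mean(d$n_selected))))
  rownames(summ) <- NULL
  structure(list(per_rep = per_rep, summary = summ, n_failed = n_failed,
                 scenario = scenario),
            class = "survemvs_study")
}

#' @export
print.survemvs_study <- function(x, ...) {
  cat(sprintf("Replication study, scenario %d (%d failed)\n",
              x$scenario, x$n_failed))
  print(x$summary, digits = 3)
  invisible(x)
}
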