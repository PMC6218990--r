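#' Extended Bayesian information criterion
#'
#' `EBIC_tau = -2 logL + p_m log(n) + 2 tau log C(p, p_m)`, where `p_m` is
#' the number of selected markers and `C(p, p_m)` the number of models of
#' that size among `p` candidates. `tau = 0` recovers the ordinary BIC; the
#' combinatorial term (evaluated through [lchoose()], never the raw binomial
#' coefficient) penalizes the size of the model space and curbs false
#' discoveries when `p >> n`.
#'
#' @param loglik Model log-likelihood at the fitted parameters.
#' @param n_selected Number of selected markers `p_m` (`0 <= p_m <= p`).
#' @param n Sample size.
#' @param p Number of candidate markers.
#' @param tau Model-space penalty weight in `[0, 1]`.
#' @return The criterion value (smaller is better).
#' @export
#' @examples
#' ebic(-100, 3, 500, 1000, tau = 0.5)
ebic <- function(loglik, n_selected, n, p, tau) {
  stopifnot(n_selected >= 0, n_selected <= p, tau >= 0, tau <= 1, n >= 1)
  -2 * loglik + n_selected * log(n) + 2 * tau * lchoose(p, n_selected)
}

#' Hyperparameter candidate grid for the spike and slab variances
#'
#' Spike candidates scale with the marker count:
#' `{1/(10p), 1/(5p), 1/(2p), 1/p, 2/p, 5/p, 10/p}`, plus the fixed value
#' `0.05` when `p > 500`. Slab candidates default to `{10, 100, 500}`. The
#' two sets are crossed; duplicates and pairs with `v0 >= v1` are dropped.
#' At `p = 1000` this yields the standard 24-point grid.
#'
#' @param p Number of candidate markers.
#' @param v1 Slab variance candidates.
#' @return A data frame with columns `v0`, `v1`, one row per grid point.
#' @export
#' @examples
#' nrow(hyper_grid(1000))  # 24
hyper_grid <- function(p, v1 = c(10, 100, 500)) {
  stopifnot(p >= 1, length(v1) >= 1, all(v1 > 0))
  v0 <- c(1 / (10 * p), 1 / (5 * p), 1 / (2 * p), 1 / p, 2 / p, 5 / p, 10 / p)
  if (p > 500) v0 <- c(v0, 0.05)
  v0 <- unique(v0)
  g <- expand.grid(v0 = v0, v1 = unique(v1), KEEP.OUT.ATTRS = FALSE)
  g <- g[g$v0 < g$v1, , drop = FALSE]
  if (nrow(g) == 0L) stop("empty hyperparameter grid")
  rownames(g) <- NULL
  g
}

#' Tune the spike-and-slab variances by EBIC over a grid
#'
#' Fits the model at every `(v0, v1)` grid point and scores each fit by the
#' EBIC at `tau` in `{0, 0.5, 1}`, with `p_m` counting selected markers only
#' (the clinical covariates and intercept are always in the model and are not
#' penalized). The winner minimizes the EBIC at the requested `tau`; ties are
#' broken toward the sparser prior (larger `v0`, then smaller `v1`).
#'
#' Grid points are independent: by default every fit starts from the same
#' neutral initialization, so results do not depend on grid order. Setting
#' `warm_start = TRUE` reuses each `v1`-path's previous solution as a speed
#' heuristic (order-dependent, off by default).
#'
#' @param data A [surv_data()] object.
#' @param grid Data frame of `v0`, `v1` candidates, as from [hyper_grid()].
#' @param tau EBIC penalty weight used to pick the winner (0, 0.5 or 1).
#' @param settings A [fit_settings()].
#' @param prior_args Extra hyperprior values passed to [prior_spec()].
#' @param warm_start Reuse solutions along the `v0` path?
#' @return An object of class `"survemvs_tune"`: list with `best_fit` (the
#'   winning [survemvs()] fit), `best` (its grid row), `table` (one row per
#'   grid point: `v0`, `v1`, `n_selected`, `loglik`, `ebic_0`, `ebic_0.5`,
#'   `ebic_1`, `converged`, `n_iter`), `fits` (all fits), `tau`.
#' @export
survemvs_tune <- function(data, grid = hyper_grid(data$p), tau = 0.5,
                          settings = fit_settings(), prior_args = list(),
                          warm_start = FALSE) {
  stopifnot(nrow(grid) >= 1, tau >= 0, tau <= 1)
  fits <- vector("list", nrow(grid))
  tab <- data.frame(v0 = grid$v0, v1 = grid$v1, n_selected = NA_integer_,
                    loglik = NA_real_, ebic_0 = NA_real_,
                    ebic_0.5 = NA_real_, ebic_1 = NA_real_,
                    converged = NA, n_iter = NA_integer_,
                    check.names = FALSE)
  ord_fit <- if (warm_start) order(grid$v1, grid$v0) else seq_len(nrow(grid))
  prev <- NULL
  prev_v1 <- NA_real_
  for (i in ord_fit) {
    prior <- do.call(prior_spec,
                     c(list(v0 = grid$v0[i], v1 = grid$v1[i]), prior_args))
    init <- NULL
    if (warm_start && !is.null(prev) && identical(prev_v1, grid$v1[i]))
      init <- list(beta = prev$beta, u = prev$u, alpha = prev$alpha)
    fits[[i]] <- survemvs(data, prior, settings, init = init)
    if (warm_start) { prev <- fits[[i]]; prev_v1 <- grid$v1[i] }
    f <- fits[[i]]
    pm <- length(f$selected)
    tab$n_selected[i] <- pm
    tab$loglik[i] <- f$loglik
    tab$ebic_0[i] <- ebic(f$loglik, pm, data$n, data$p, 0)
    tab$`ebic_0.5`[i] <- ebic(f$loglik, pm, data$n, data$p, 0.5)
    tab$ebic_1[i] <- ebic(f$loglik, pm, data$n, data$p, 1)
  }
  tab$converged <- vapply(fits, `[[`, logical(1), "converged")
  tab$n_iter <- vapply(fits, `[[`, integer(1), "n_iter")
  if (!any(tab$converged))
    warning("no grid fit converged; returning the best-effort minimizer")

  crit <- tab[[paste0("ebic_", format(tau, trim = TRUE))]]
  if (is.null(crit))
    crit <- -2 * tab$loglik + tab$n_selected * log(data$n) +
      2 * tau * lchoose(data$p, tab$n_selected)
  # ties toward the sparser prior: larger v0, then smaller v1
  ord <- order(crit, -tab$v0, tab$v1)
  best <- ord[1L]
  structure(list(best_fit = fits[[best]], best = tab[best, , drop = FALSE],
                 table = tab, fits = fits, tau = tau),
            class = "survemvs_tune")
}

#' @export
print.survemvs_tune <- function(x, ...) {
  cat(sprintf("EBIC tuning over %d grid point(s), tau = %s\n",
              nrow(x$table), format(x$tau)))
  cat(sprintf("  best: v0 = %.4g, v1 = %.4g, %d marker(s) selected\n",
              x$best$v0, x$best$v1, x$best$n_selected))
  invisible(x)
}

#' Write a tuning grid table to a delimited file
#'
#' @param x A `"survemvs_tune"` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_table <- function(x, path) {
  stopifnot(inherits(x, "survemvs_tune"))
  utils::write.csv(x$table, path, row.names = FALSE)
  invisible(path)
}
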