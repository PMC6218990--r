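#' Censored Weibull log-likelihood
#'
#' Log-likelihood of a Weibull regression model under right censoring. The
#' scale for subject `i` is `lambda_i = exp(-eta_i)` with linear predictor
#' `eta_i = Z_i u + X_i beta`; the shape `alpha` is shared. Events contribute
#' the log-density `log alpha + (alpha - 1) log T - eta - lambda T^alpha`,
#' censored subjects the log-survival `-lambda T^alpha`. All arithmetic stays
#' in log space: `lambda T^alpha` is evaluated as `exp(alpha log T - eta)`, so
#' large linear predictors do not overflow the density.
#'
#' @param data A [surv_data()] object.
#' @param beta Marker effects, length `p`.
#' @param u Covariate effects including intercept, length `q + 1`.
#' @param alpha Positive Weibull shape.
#' @return The scalar log-likelihood.
#' @export
#' @examples
#' d <- surv_data(1, 1, matrix(0, 1, 1), standardize = FALSE)
#' weibull_loglik(d, beta = 0, u = 0, alpha = 1)  # log f = -1
weibull_loglik <- function(data, beta, u, alpha) {
  lp <- .linpred(data, beta, u, alpha)
  ll <- sum(data$status * (log(alpha) + (alpha - 1) * lp$logt - lp$eta) - lp$w)
  if (!is.finite(ll))
    stop("non-finite log-likelihood: linear predictor or shape out of range")
  ll
}

# shared plumbing: eta, log T, and the cumulative hazard w_i = lambda_i T_i^alpha
.linpred <- function(data, beta, u, alpha) {
  if (length(beta) != data$p) stop("length(beta) must equal p")
  if (length(u) != data$q + 1L) stop("length(u) must equal q + 1")
  if (!is.finite(alpha) || alpha <= 0) stop("'alpha' must be positive")
  eta <- drop(data$Z %*% u)
  if (any(beta != 0)) eta <- eta + drop(data$X %*% beta)
  logt <- log(data$time)
  list(eta = eta, logt = logt, w = exp(alpha * logt - eta))
}

#' Gradient of the censored Weibull log-likelihood
#'
#' Analytic first partial derivatives with respect to each marker effect,
#' covariate effect, and the shape. Writing `w_i = lambda_i T_i^alpha`,
#' the score along any linear-predictor coefficient with design column `v` is
#' `sum_i v_i (w_i - delta_i)`, and along the shape it is
#' `sum_i delta_i (1/alpha + log T_i) - w_i log T_i`.
#'
#' @inheritParams weibull_loglik
#' @return A list with `beta` (length `p`), `u` (length `q + 1`) and
#'   `alpha` (scalar).
#' @export
weibull_score <- function(data, beta, u, alpha) {
  lp <- .linpred(data, beta, u, alpha)
  r <- lp$w - data$status
  list(beta = drop(crossprod(data$X, r)),
       u = drop(crossprod(data$Z, r)),
       alpha = sum(data$status * (1 / alpha + lp$logt) - lp$w * lp$logt))
}

#' Coordinatewise curvature of the censored Weibull log-likelihood
#'
#' Second partial derivatives of the log-likelihood along each coordinate,
#' other coordinates held fixed: `-sum_i v_i^2 w_i` for a linear-predictor
#' coefficient with design column `v`, and
#' `-sum_i delta_i / alpha^2 + w_i (log T_i)^2` for the shape. The
#' log-likelihood is concave in each linear-predictor coordinate, so the
#' `beta`/`u` entries are strictly negative unless a design column is
#' degenerate (identically zero), in which case that coordinate is flagged
#' with a warning.
#'
#' @inheritParams weibull_loglik
#' @return A list with `beta`, `u`, `alpha` second derivatives (all `<= 0`
#'   for valid inputs).
#' @export
weibull_curvature <- function(data, beta, u, alpha) {
  lp <- .linpred(data, beta, u, alpha)
  d2b <- -drop(crossprod(data$X^2, lp$w))
  d2u <- -drop(crossprod(data$Z^2, lp$w))
  if (any(d2b == 0))
    warning("degenerate (all-zero) marker column(s): ",
            paste(utils::head(which(d2b == 0), 5L), collapse = ", "))
  if (any(d2b > 0) || any(d2u > 0))
    stop("positive curvature along a linear-predictor coordinate: numerical breakdown")
  list(beta = d2b, u = d2u,
       alpha = -sum(data$status / alpha^2 + lp$w * lp$logt^2))
}
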