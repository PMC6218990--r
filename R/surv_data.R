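#' Construct a survival dataset for spike-and-slab Weibull regression
#'
#' Bundles observed times, event indicators, a high-dimensional marker matrix
#' `X` and a low-dimensional covariate matrix `Z` (with an intercept column)
#' into a validated object used by [survemvs()] and friends.
#'
#' Marker columns are standardized to mean zero and unit sample standard
#' deviation by default; the centering and scaling constants are stored as
#' attributes so that fitted effects can be back-transformed if needed.
#' Constant marker columns cannot be standardized and are rejected.
#'
#' @param time Positive observed times (event or censoring), length `n`.
#' @param status Event indicators: 1 = event observed, 0 = right-censored.
#' @param X Numeric `n x p` marker matrix (genotypes, expression, ...).
#' @param Z Optional numeric matrix of clinical covariates (`n x q`), without
#'   an intercept column; an all-ones intercept column is prepended. `NULL`
#'   gives an intercept-only `Z`.
#' @param standardize Standardize columns of `X`? Default `TRUE`. Set to
#'   `FALSE` only for matrices already on the fitting scale (e.g. a test set
#'   scaled with training constants).
#'
#' @return An object of class `"surv_data"`: a list with elements `time`,
#'   `status`, `X`, `Z`, `n`, `p`, `q`, and attributes `center`/`scale` on
#'   `X` when standardized.
#' @export
#' @examples
#' set.seed(1)
#' d <- surv_data(rexp(20), rbinom(20, 1, 0.6), matrix(rnorm(20 * 5), 20))
#' d$p
surv_data <- function(time, status, X, Z = NULL, standardize = TRUE) {
  time <- as.numeric(time)
  status <- as.numeric(status)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- length(time)
  if (length(status) != n)
    stop("'time' and 'status' must have the same length")
  if (anyNA(time) || anyNA(status) || anyNA(X))
    stop("missing values are not allowed in 'time', 'status' or 'X'")
  if (any(time <= 0))
    stop("all observed times must be strictly positive (zero/negative at rows: ",
         paste(utils::head(which(time <= 0), 5L), collapse = ", "), ")")
  if (!all(status %in% c(0, 1)))
    stop("'status' must be coded 0 (censored) / 1 (event)")
  if (nrow(X) != n)
    stop("nrow(X) must equal length(time)")
  if (is.null(colnames(X)))
    colnames(X) <- paste0("m", seq_len(ncol(X)))

  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, stats::sd)
    if (any(scl == 0))
      stop("constant marker column(s) cannot be standardized: ",
           paste(utils::head(colnames(X)[scl == 0], 5L), collapse = ", "))
    X <- sweep(sweep(X, 2L, ctr, "-"), 2L, scl, "/")
    attr(X, "center") <- ctr
    attr(X, "scale") <- scl
  }

  if (is.null(Z)) {
    Z <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    Z <- as.matrix(Z)
    storage.mode(Z) <- "double"
    if (nrow(Z) != n) stop("nrow(Z) must equal length(time)")
    if (anyNA(Z)) stop("missing values are not allowed in 'Z'")
    if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
    Z <- cbind("(Intercept)" = 1, Z)
  }

  structure(
    list(time = time, status = status, X = X, Z = Z,
         n = n, p = ncol(X), q = ncol(Z) - 1L),
    class = "surv_data"
  )
}

#' @export
print.surv_data <- function(x, ...) {
  cat("Survival dataset: n =", x$n, ", p =", x$p, "markers,",
      x$q, "clinical covariate(s)\n")
  cat(sprintf("  events: %d (%.1f%%), censored: %d\n",
              sum(x$status), 100 * mean(x$status), sum(1 - x$status)))
  invisible(x)
}
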