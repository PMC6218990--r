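#' Read a delimited survival table
#'
#' Reads a comma- (`.csv`) or tab-delimited table with a header row holding
#' observed times, event indicators and optional clinical covariates.
#' Validation is strict: rows with missing time or event are rejected with
#' their row indices, zero or negative survival times are rejected, events
#' must be coded 0/1, and covariates may not contain missing values
#' (imputation is out of scope).
#'
#' @param path Path to the file.
#' @param time_col,event_col Column names for time and event indicator.
#' @param covar_cols Optional character vector of covariate column names.
#' @param id_col Optional subject-ID column used to align with a marker file.
#' @return A list with `time`, `status`, `Z` (covariate matrix or `NULL`)
#'   and `id` (or `NULL`).
#' @export
read_survival_table <- function(path, time_col = "time",
                                event_col = "status", covar_cols = NULL,
                                id_col = NULL) {
  df <- .read_delim(path)
  for (col in c(time_col, event_col, covar_cols, id_col))
    if (!col %in% names(df))
      stop("column '", col, "' not found in ", path)
  time <- suppressWarnings(as.numeric(df[[time_col]]))
  bad <- which(is.na(time))
  if (length(bad))
    stop("non-numeric or missing time in column '", time_col, "' at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  bad <- which(time <= 0)
  if (length(bad))
    stop("zero or negative survival time at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  status <- suppressWarnings(as.numeric(df[[event_col]]))
  bad <- which(is.na(status) | !status %in% c(0, 1))
  if (length(bad))
    stop("event column '", event_col, "' must be coded 0/1; bad row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  Z <- NULL
  if (!is.null(covar_cols)) {
    Z <- as.matrix(df[covar_cols])
    storage.mode(Z) <- "double"
    if (anyNA(Z))
      stop("missing covariate values at row(s): ",
           paste(utils::head(which(rowSums(is.na(Z)) > 0), 5L), collapse = ", "),
           " (imputation is not performed)")
  }
  list(time = time, status = status, Z = Z,
       id = if (is.null(id_col)) NULL else as.character(df[[id_col]]))
}

#' Read a delimited marker matrix
#'
#' Reads a numeric marker matrix (subjects in rows, markers in columns) from
#' a comma- or tab-delimited file with a header. Constant columns are dropped
#' with a warning naming them. Missing values are either rejected or, with
#' `impute_mean = TRUE`, replaced by the column mean.
#'
#' @param path Path to the file.
#' @param id_col Optional subject-ID column name; when given together with
#'   `ids`, rows are realigned to that order.
#' @param ids Optional subject IDs (from [read_survival_table()]) defining
#'   the required row order.
#' @param impute_mean Impute missing marker values by their column mean?
#'   Default `FALSE` (missing values are an error).
#' @return A numeric matrix with marker names as column names.
#' @export
read_marker_matrix <- function(path, id_col = NULL, ids = NULL,
                               impute_mean = FALSE) {
  df <- .read_delim(path)
  if (!is.null(id_col)) {
    if (!id_col %in% names(df)) stop("column '", id_col, "' not found in ", path)
    rid <- as.character(df[[id_col]])
    df[[id_col]] <- NULL
    if (!is.null(ids)) {
      if (!setequal(rid, ids))
        stop("subject IDs in the marker file do not match the survival table")
      df <- df[match(ids, rid), , drop = FALSE]
    }
  }
  X <- as.matrix(df)
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    if (!impute_mean)
      stop("missing marker values; rerun with impute_mean = TRUE to use ",
           "per-column mean imputation")
    for (j in which(colSums(is.na(X)) > 0)) {
      mj <- mean(X[, j], na.rm = TRUE)
      X[is.na(X[, j]), j] <- mj
    }
  }
  const <- which(apply(X, 2L, stats::sd) == 0)
  if (length(const)) {
    warning("dropping constant marker column(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, -const, drop = FALSE]
  }
  X
}

.read_delim <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write fitted effects to delimited files
#'
#' Writes one CSV with per-marker results (name, effect, inclusion
#' probability, selected flag) and one with the global parameters
#' (covariate effects, shape, variance, inclusion rate, convergence).
#'
#' @param fit A fitted [survemvs()] model.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_fit <- function(fit, dir = ".", prefix = "survemvs") {
  stopifnot(inherits(fit, "survemvs"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  eff <- file.path(dir, paste0(prefix, "_effects.csv"))
  utils::write.csv(data.frame(marker = names(fit$beta), beta = fit$beta,
                              p_star = fit$p_star,
                              selected = seq_along(fit$beta) %in% fit$selected,
                              row.names = NULL),
                   eff, row.names = FALSE)
  par <- file.path(dir, paste0(prefix, "_parameters.csv"))
  utils::write.csv(data.frame(parameter = c(names(fit$u), "alpha", "sigma2",
                                            "theta", "loglik", "n_iter",
                                            "converged"),
                              value = c(fit$u, fit$alpha, fit$sigma2,
                                        fit$theta, fit$loglik, fit$n_iter,
                                        as.numeric(fit$converged))),
                   par, row.names = FALSE)
  invisible(c(eff, par))
}

#' Command-line interface
#'
#' Thin shell entry point over the package's functions, installed as
#' `inst/cli/survemvs`. Subcommands: `fit` (single `(v0, v1)` fit), `tune`
#' (EBIC grid search), `simulate` (write one scenario replication to CSV),
#' `study` (replication study), `evaluate` (metrics from a saved fit and a
#' dataset). Every run writes a plain-text log with the seed and settings.
#'
#' @param args Character vector of arguments (default: the process's).
#' @return Integer exit status, invisibly (0 on success).
#' @export
survemvs_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args))
      stop("usage: survemvs <fit|tune|simulate|study|evaluate> [options]")
    cmd <- args[[1L]]
    opts <- .cli_opts(args[-1L])
    out_dir <- opts$out %||% "."
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    seed <- as.integer(opts$seed %||% 1)
    log_path <- file.path(out_dir, "survemvs_log.txt")
    logf <- function(...) cat(..., "\n", file = log_path, append = TRUE)
    cat(sprintf("survemvs %s | %s | seed %d\n",
                utils::packageVersion("survemvs"), cmd, seed),
        file = log_path)
    logf("options:", paste(names(opts), unlist(opts), sep = "=", collapse = " "))

    load_data <- function() {
      st <- read_survival_table(opts$data, opts$time_col %||% "time",
                                opts$event_col %||% "status",
                                if (!is.null(opts$covars))
                                  strsplit(opts$covars, ",")[[1L]],
                                opts$id_col)
      X <- read_marker_matrix(opts$markers, opts$id_col, st$id,
                              impute_mean = isTRUE(opts$impute == "true"))
      surv_data(st$time, st$status, X, st$Z)
    }

    switch(cmd,
      fit = {
        d <- load_data()
        v0 <- as.numeric(opts$v0); v1 <- as.numeric(opts$v1)
        if (is.na(v0) || is.na(v1)) stop("'--v0' and '--v1' are required")
        fit <- survemvs(d, prior_spec(v0, v1))
        write_fit(fit, out_dir)
        logf("converged:", fit$converged, "iterations:", fit$n_iter)
        logf("trace:", paste(signif(fit$trace, 4), collapse = " "))
        cat(sprintf("fit done: %d marker(s) selected\n", length(fit$selected)))
      },
      tune = {
        d <- load_data()
        tn <- survemvs_tune(d, tau = as.numeric(opts$tau %||% 0.5))
        write_grid_table(tn, file.path(out_dir, "grid.csv"))
        write_fit(tn$best_fit, out_dir, "best")
        logf("best v0:", tn$best$v0, "v1:", tn$best$v1)
        cat(sprintf("tune done: best v0 = %.4g, v1 = %.4g, %d selected\n",
                    tn$best$v0, tn$best$v1, tn$best$n_selected))
      },
      simulate = {
        set.seed(seed)
        sc <- sim_scenario(as.integer(opts$scenario %||% 1), seed = seed)
        .write_scenario(sc, out_dir)
        logf("scenario written, K =", sc$K)
        cat(sprintf("simulate done: n = %d, p = %d, K = %.4f\n",
                    sc$train$n, sc$train$p, sc$K))
      },
      study = {
        st <- run_study(as.integer(opts$scenario %||% 1),
                        n_rep = as.integer(opts$reps %||% 50),
                        tau = as.numeric(strsplit(opts$tau %||% "0,0.5,1",
                                                  ",")[[1L]]),
                        seed = seed)
        utils::write.csv(st$per_rep, file.path(out_dir, "per_rep.csv"),
                         row.names = FALSE)
        utils::write.csv(st$summary, file.path(out_dir, "summary.csv"),
                         row.names = FALSE)
        logf("failed replications:", st$n_failed)
        print(st)
      },
      evaluate = {
        d <- load_data()
        eff <- utils::read.csv(opts$effects)
        if (!all(c("marker", "beta") %in% names(eff)))
          stop("'--effects' file must have columns marker, beta")
        beta <- eff$beta[match(colnames(d$X), eff$marker)]
        if (anyNA(beta)) stop("markers in data and effects file do not match")
        risk <- -drop(d$X %*% beta)
        ci <- harrells_c(risk, d$time, d$status)
        utils::write.csv(data.frame(metric = "cindex", value = ci),
                         file.path(out_dir, "metrics.csv"), row.names = FALSE)
        cat(sprintf("evaluate done: c-index = %.4f\n", ci))
      },
      stop("unknown subcommand '", cmd, "'")
    )
    0L
  }, error = function(e) {
    message("survemvs error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal --key value / --key=value parser; avoids a hard optparse dependency
.cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop("unexpected argument '", a, "'")
    a <- substring(a, 3L)
    if (grepl("=", a, fixed = TRUE)) {
      kv <- strsplit(a, "=", fixed = TRUE)[[1L]]
      opts[[kv[1L]]] <- paste(kv[-1L], collapse = "=")
    } else {
      if (i == length(args)) stop("option '--", a, "' needs a value")
      opts[[a]] <- args[[i + 1L]]
      i <- i + 1L
    }
    i <- i + 1L
  }
  opts
}

.write_scenario <- function(sc, dir) {
  for (part in c("train", "test")) {
    d <- sc[[part]]
    utils::write.csv(data.frame(id = seq_len(d$n), time = d$time,
                                status = d$status),
                     file.path(dir, paste0(part, "_survival.csv")),
                     row.names = FALSE)
    Xout <- cbind(data.frame(id = seq_len(d$n)), as.data.frame(d$X))
    utils::write.csv(Xout, file.path(dir, paste0(part, "_markers.csv")),
                     row.names = FALSE)
  }
  utils::write.csv(data.frame(marker = colnames(sc$train$X),
                              beta_true = sc$beta_true),
                   file.path(dir, "beta_true.csv"), row.names = FALSE)
  invisible(dir)
}
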