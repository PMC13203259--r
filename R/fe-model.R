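#' Individual fixed-effects regression with user-clustered standard errors
#'
#' Within (entity-demeaned) least squares: every variable is demeaned within
#' user, absorbing the individual fixed effect, and the slope coefficients are
#' estimated on the demeaned data. The covariance matrix is the one-way
#' cluster-robust estimator at the user level with the small-sample correction
#' `G/(G-1) * (N-1)/(N-K)`, where `G` is the number of users, `N` the number
#' of estimation rows and `K` the total number of absorbed plus estimated
#' parameters (users + slopes). Within R-squared is computed on the demeaned
#' data. Supports single-construct and joint multi-construct specifications
#' alike: list all focal constructs in `focal`.
#'
#' @param data Estimation rows (e.g. from [lead_outcome()]).
#' @param outcome Name of the outcome column.
#' @param focal Character vector of focal regressor names.
#' @param controls Character vector of control regressor names.
#' @param cluster Name of the cluster/entity id column (also defines the
#'   fixed effect).
#' @return An `fe_model` object; inspect with [generics::tidy()],
#'   [generics::glance()] or `print()`.
#' @export
fe_regression <- function(data, outcome, focal, controls = character(),
                          cluster = "user_id") {
  vars <- c(focal, controls)
  need <- c(outcome, vars, cluster)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  keep <- stats::complete.cases(data[need])
  data <- data[keep, , drop = FALSE]
  id <- as.character(data[[cluster]])
  # users contributing a single row carry no within information
  tab <- table(id)
  ok <- id %in% names(tab)[tab >= 2L]
  if (!all(ok)) {
    data <- data[ok, , drop = FALSE]
    id <- id[ok]
  }
  n <- nrow(data)
  if (n == 0L) stop("no estimation rows with >= 2 observations per user")
  y <- as.numeric(data[[outcome]])
  x <- as.matrix(data[vars])
  storage.mode(x) <- "double"

  fid <- factor(id)
  g <- nlevels(fid)
  demean <- function(m) m - rowsum(m, fid)[fid, , drop = FALSE] /
    as.vector(table(fid))[fid]
  yd <- as.numeric(demean(matrix(y, ncol = 1L)))
  xd <- demean(x)

  const_within <- apply(xd, 2L, function(col) all(abs(col) < 1e-12))
  if (any(const_within)) {
    stop("regressor(s) constant within every user: ",
         paste(vars[const_within], collapse = ", "))
  }
  xtx <- crossprod(xd)
  if (rcond_sym(xtx) < 1e-12) stop("singular demeaned design matrix")
  xtx_inv <- solve(xtx)
  beta <- as.numeric(xtx_inv %*% crossprod(xd, yd))
  names(beta) <- vars
  resid <- yd - as.numeric(xd %*% beta)

  # cluster-robust meat: sum_g (X_g' e_g)(X_g' e_g)'
  scores <- rowsum(xd * resid, fid)
  meat <- crossprod(scores)
  k_total <- length(vars) + g # slopes + absorbed user means
  adj <- (g / (g - 1)) * ((n - 1) / (n - k_total))
  vcov_cl <- adj * xtx_inv %*% meat %*% xtx_inv
  dimnames(vcov_cl) <- list(vars, vars)
  se <- sqrt(diag(vcov_cl))

  sst <- sum(yd^2)
  ssr <- sum(resid^2)
  structure(
    list(
      coefficients = beta, se = se, vcov = vcov_cl,
      focal = focal, controls = controls,
      n_obs = n, n_users = g,
      within_r2 = if (sst > 0) 1 - ssr / sst else NA_real_,
      df_resid = n - k_total,
      residuals = resid, outcome = outcome, cluster = cluster
    ),
    class = "fe_model"
  )
}

rcond_sym <- function(m) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(ev)) == 0) return(0)
  min(abs(ev)) / max(abs(ev))
}

#' @export
print.fe_model <- function(x, ...) {
  cat("Within fixed-effects model: ", x$outcome, " ~ ",
      paste(c(x$focal, x$controls), collapse = " + "),
      "\n  ", x$n_obs, " rows, ", x$n_users,
      " users, within R2 = ", format(x$within_r2, digits = 3), "\n\n",
      sep = "")
  print(generics::tidy(x))
  invisible(x)
}

#' @rdname fe_regression
#' @param x An `fe_model`.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.fe_model <- function(x, ...) {
  est <- x$coefficients
  se <- x$se
  stat <- est / se
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = 2 * stats::pt(-abs(unname(stat)), df = x$df_resid),
    role = ifelse(names(est) %in% x$focal, "focal", "control")
  )
}

#' @rdname fe_regression
#' @export
#' @exportS3Method generics::glance
glance.fe_model <- function(x, ...) {
  tibble::tibble(
    within.r.squared = x$within_r2,
    nobs = x$n_obs,
    n.users = x$n_users,
    df.residual = x$df_resid
  )
}

#' Confidence intervals for fixed-effects coefficients
#'
#' @param object An `fe_model`.
#' @param parm Coefficient names (default all).
#' @param level Confidence level.
#' @param ... Unused.
#' @return Matrix of lower/upper bounds, as [stats::confint()].
#' @export
confint.fe_model <- function(object, parm = NULL, level = 0.95, ...) {
  if (is.null(parm)) parm <- names(object$coefficients)
  a <- (1 - level) / 2
  crit <- stats::qt(1 - a, df = object$df_resid)
  est <- object$coefficients[parm]
  se <- object$se[parm]
  out <- cbind(est - crit * se, est + crit * se)
  colnames(out) <- paste(format(100 * c(a, 1 - a), trim = TRUE), "%")
  out
}
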