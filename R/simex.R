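#' SIMEX configuration
#'
#' Settings for simulation-extrapolation correction of measurement error in a
#' projection-score regressor: the multiplier grid `lambda` (must contain 0,
#' ascending), the number of noise replicates `B` per positive multiplier,
#' the assumed measurement-error variance `sigma2_u` of the (standardized)
#' focal score, and the seed. The error variance is an explicit input: supply
#' it directly or derive it from a reliability ratio with
#' [error_variance_from_reliability()].
#'
#' @param lambda Nonnegative multiplier grid; default `c(0, 0.5, 1, 1.5, 2)`.
#' @param B Replicates per positive lambda; default 30.
#' @param sigma2_u Measurement-error variance (> 0).
#' @param seed Integer seed (mandatory; the whole procedure is deterministic
#'   given the config).
#' @return A `simex_config` list.
#' @export
simex_config <- function(lambda = c(0, 0.5, 1, 1.5, 2), B = 30L,
                         sigma2_u, seed) {
  lambda <- sort(unique(as.numeric(lambda)))
  if (!0 %in% lambda) stop("lambda grid must contain 0")
  if (any(lambda < 0)) stop("lambda multipliers must be nonnegative")
  if (length(lambda) < 3L) {
    stop("need at least 3 lambda points for a quadratic extrapolation")
  }
  if (missing(sigma2_u) || !is.numeric(sigma2_u) || sigma2_u <= 0) {
    stop("sigma2_u must be a positive measurement-error variance")
  }
  if (missing(seed)) stop("seed is mandatory")
  structure(list(lambda = lambda, B = as.integer(B),
                 sigma2_u = as.numeric(sigma2_u),
                 seed = as.integer(seed)),
            class = "simex_config")
}

#' Measurement-error variance implied by a reliability ratio
#'
#' Under classical measurement error the observed score is signal plus
#' independent noise, and reliability `r` is the signal share of the observed
#' variance, so `sigma2_u = sigma2_x * (1 - r)` when `sigma2_x` is the
#' observed-score variance. (Equivalently `sigma2_true * (1 - r) / r` in
#' terms of the true-score variance.)
#'
#' @param sigma2_x Variance of the observed score.
#' @param r Reliability in (0, 1\].
#' @return Error variance.
#' @export
error_variance_from_reliability <- function(sigma2_x, r) {
  stopifnot(sigma2_x > 0, r > 0, r <= 1)
  sigma2_x * (1 - r)
}

#' SIMEX correction of a fixed-effects coefficient
#'
#' Simulation-extrapolation for attenuation from measurement error in the
#' focal construct score: for each multiplier `lambda > 0`, `B` replicates
#' add independent N(0, `lambda * sigma2_u`) noise to the focal regressor
#' only (controls are treated as error-free), the fixed-effects model is
#' refitted, and the focal coefficients are averaged per lambda. A quadratic
#' polynomial is then fitted by ordinary least squares to the mean
#' coefficient path (including the naive estimate at lambda = 0) and
#' evaluated at `lambda = -1` to obtain the corrected estimate.
#'
#' @param data Estimation rows (as for [fe_regression()]).
#' @param outcome Outcome column name.
#' @param focal Single focal regressor name (the error-prone score).
#' @param controls Control regressor names.
#' @param config A [simex_config()].
#' @param cluster Cluster/entity id column.
#' @return A `simex_result`: `naive_beta`, `path` (tibble `lambda`,
#'   `mean_beta`), `corrected_beta`, `bias_percent`, `quad_coefs`, `config`.
#' @export
simex_fe <- function(data, outcome, focal, controls = character(),
                     config, cluster = "user_id") {
  stopifnot(inherits(config, "simex_config"), length(focal) == 1L)
  base_fit <- fe_regression(data, outcome, focal, controls,
                            cluster = cluster)
  naive <- unname(base_fit$coefficients[focal])
  x0 <- data[[focal]]
  set.seed(config$seed)
  mean_beta <- vapply(config$lambda, function(lam) {
    if (lam == 0) return(naive)
    reps <- vapply(seq_len(config$B), function(b) {
      noisy <- data
      noisy[[focal]] <- x0 + stats::rnorm(length(x0),
                                          sd = sqrt(lam * config$sigma2_u))
      fit <- tryCatch(
        fe_regression(noisy, outcome, focal, controls, cluster = cluster),
        error = function(e) {
          stop("model failure at lambda = ", lam, ", replicate ", b, ": ",
               conditionMessage(e))
        }
      )
      unname(fit$coefficients[focal])
    }, numeric(1L))
    mean(reps)
  }, numeric(1L))
  path <- tibble::tibble(lambda = config$lambda, mean_beta = mean_beta)
  quad <- stats::lm(mean_beta ~ lambda + I(lambda^2), data = path)
  corrected <- unname(stats::predict(quad,
                                     newdata = data.frame(lambda = -1)))
  structure(
    list(
      naive_beta = naive,
      path = path,
      corrected_beta = corrected,
      bias_percent = bias_percent(naive, corrected),
      quad_coefs = stats::coef(quad),
      focal = focal,
      config = config
    ),
    class = "simex_result"
  )
}

#' Attenuation bias percentage
#'
#' `(|naive| - |corrected|) / |corrected| * 100`: negative values indicate
#' attenuation, i.e. the naive estimate understates the magnitude of the
#' corrected one.
#'
#' @param naive Naive coefficient.
#' @param corrected SIMEX-corrected coefficient (nonzero).
#' @return Percent bias.
#' @export
#' @examples
#' bias_percent(0.0689, 0.0792) # about -13.0
bias_percent <- function(naive, corrected) {
  if (any(corrected == 0)) stop("corrected estimate is zero")
  (abs(naive) - abs(corrected)) / abs(corrected) * 100
}

#' @export
print.simex_result <- function(x, ...) {
  cat("<simex_result> ", x$focal, ": naive = ",
      format(x$naive_beta, digits = 4), ", corrected = ",
      format(x$corrected_beta, digits = 4), " (bias ",
      format(x$bias_percent, digits = 3), "%)\n", sep = "")
  invisible(x)
}

#' @rdname simex_fe
#' @param x A `simex_result`.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.simex_result <- function(x, ...) {
  tibble::tibble(
    term = x$focal,
    naive = x$naive_beta,
    corrected = x$corrected_beta,
    bias_percent = x$bias_percent
  )
}

#' @rdname simex_fe
#' @export
#' @exportS3Method generics::glance
glance.simex_result <- function(x, ...) {
  tibble::tibble(
    n_lambda = length(x$config$lambda),
    B = x$config$B,
    sigma2_u = x$config$sigma2_u,
    seed = x$config$seed
  )
}
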