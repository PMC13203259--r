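#' Symmetric percentile winsorization
#'
#' Clamps values below the `pct`-th percentile to that percentile and values
#' above the `(100 - pct)`-th percentile to that one; record order is
#' untouched. `pct = 1` is the conventional "1% winsorization".
#'
#' @param values Numeric vector (NA passed through).
#' @param pct Tail percentile in \[0, 50).
#' @return Winsorized numeric vector.
#' @export
winsorize <- function(values, pct = 1) {
  if (length(values) == 0L) stop("winsorize of an empty sequence")
  stopifnot(pct >= 0, pct < 50)
  if (pct == 0) return(values)
  qs <- stats::quantile(values, probs = c(pct, 100 - pct) / 100,
                        na.rm = TRUE, names = FALSE, type = 7)
  pmin(pmax(values, qs[[1L]]), qs[[2L]])
}

z_standardize <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (is.na(s) || s == 0) stop("cannot standardize a zero-variance column")
  (x - mean(x, na.rm = TRUE)) / s
}

#' Prepare panel variables for estimation
#'
#' Applies the variable-construction conventions of the criterion-validity
#' panel: `ln(x + 1)` to the raw weekly minutes (`ExDur`) and to the social
#' count variables (`SocEngage`, `SocFeedback`); the behavioral-inertia first
#' difference `DurChg = ExDur_t - ExDur_{t-1}` within user over adjacent
#' weeks (missing when week `t - 1` is unobserved); then winsorization of the
#' continuous predictors at the `winsor_pct` tails followed by
#' z-standardization over the rows being prepared. The outcome `ExDur` is
#' never standardized, so slope coefficients on standardized predictors read
#' as approximate semi-elasticities.
#'
#' @param raw Tibble with one row per (user, week): `user_id`, `week_index`,
#'   `minutes` (raw weekly exercise minutes), any construct-score columns
#'   named in `predictors`, and optionally raw `soc_engage` / `soc_feedback`
#'   counts and other controls.
#' @param predictors Character vector of continuous predictor columns to
#'   winsorize and standardize (construct scores and controls). `DurChg` is
#'   added automatically when derivable.
#' @param winsor_pct Winsorization tail percentile (default 1).
#' @param standardize Standardize predictors after winsorization?
#' @return Tibble with `ExDur` (log scale), `DurChg`, log-transformed social
#'   counts, and transformed predictor columns; attribute `"raw_mean_minutes"`
#'   records the pre-log mean of weekly minutes used by
#'   [minutes_equivalent()].
#' @export
prepare_panel <- function(raw, predictors = character(), winsor_pct = 1,
                          standardize = TRUE) {
  stopifnot(all(c("user_id", "week_index", "minutes") %in% names(raw)))
  if (any(raw$minutes < 0, na.rm = TRUE)) {
    stop("negative raw minutes in panel")
  }
  for (v in c("soc_engage", "soc_feedback")) {
    if (v %in% names(raw) && any(raw[[v]] < 0, na.rm = TRUE)) {
      stop("negative raw counts in ", v)
    }
  }
  out <- raw |>
    dplyr::arrange(.data$user_id, .data$week_index) |>
    dplyr::mutate(ExDur = log1p(.data$minutes))
  if (anyDuplicated(out[c("user_id", "week_index")])) {
    stop("more than one record per (user, week)")
  }
  out <- out |>
    dplyr::group_by(.data$user_id) |>
    dplyr::mutate(
      DurChg = dplyr::if_else(
        .data$week_index - dplyr::lag(.data$week_index) == 1L,
        .data$ExDur - dplyr::lag(.data$ExDur),
        NA_real_
      )
    ) |>
    dplyr::ungroup()
  for (v in c("soc_engage", "soc_feedback")) {
    if (v %in% names(out)) out[[v]] <- log1p(out[[v]])
  }
  predictors <- union(predictors, intersect("DurChg", names(out)))
  for (v in predictors) {
    if (!v %in% names(out)) stop("predictor column not found: ", v)
    out[[v]] <- winsorize(out[[v]], pct = winsor_pct)
    if (standardize) out[[v]] <- z_standardize(out[[v]])
  }
  attr(out, "raw_mean_minutes") <- mean(raw$minutes, na.rm = TRUE)
  out
}

#' Pair regressors at week t with the outcome at week t + 1
#'
#' Builds the estimation rows of the lead-outcome specification: each row
#' carries the regressors observed at week `t` and the outcome observed at
#' week `t + 1` for the same user. The lead is strict — a row is emitted only
#' when the user has a record at exactly `week_index + 1`; gaps are not
#' bridged and each user's last observed week yields no row.
#'
#' @param panel Prepared panel tibble (needs `user_id`, `week_index`,
#'   `ExDur`).
#' @param outcome Column to lead (default `"ExDur"`).
#' @return The panel rows that have a next-week match, with the added column
#'   `ExDur_lead` (or `<outcome>_lead`).
#' @export
lead_outcome <- function(panel, outcome = "ExDur") {
  stopifnot(all(c("user_id", "week_index", outcome) %in% names(panel)))
  lead_col <- paste0(outcome, "_lead")
  out <- panel |>
    dplyr::arrange(.data$user_id, .data$week_index) |>
    dplyr::group_by(.data$user_id) |>
    dplyr::mutate(
      !!lead_col := dplyr::if_else(
        dplyr::lead(.data$week_index) - .data$week_index == 1L,
        dplyr::lead(.data[[outcome]]),
        NA_real_
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data[[lead_col]]))
  out
}

#' Semi-elasticity of a log outcome per standard-deviation change
#'
#' With a log-transformed outcome and a standardized predictor, a coefficient
#' `beta` translates to an approximate percent change of
#' `100 * (exp(beta) - 1)` in the raw outcome per one-SD increase.
#'
#' @param beta Coefficient(s).
#' @return Percent change(s).
#' @export
#' @examples
#' semi_elasticity(0.069) # about +7.1%
semi_elasticity <- function(beta) {
  100 * (expm1(beta))
}

#' Minutes-per-week equivalent of a coefficient
#'
#' Converts a semi-elasticity into raw outcome units using a reference mean
#' of the untransformed outcome: `ref_mean * (exp(beta) - 1)`.
#'
#' @param beta Coefficient(s) on a standardized predictor of the log outcome.
#' @param ref_mean Raw mean of weekly minutes before log transformation.
#' @return Minutes-per-week change(s).
#' @export
#' @examples
#' minutes_equivalent(0.069, ref_mean = 15.61) # about +1.12 min/week
minutes_equivalent <- function(beta, ref_mean) {
  stopifnot(ref_mean > 0)
  ref_mean * expm1(beta)
}

#' Collinearity diagnostics: VIFs and condition indices
#'
#' Variance inflation factor of each column, `1 / (1 - R2_j)` from regressing
#' column j on the remaining columns (infinite under exact collinearity), and
#' the condition indices of the standardized design: the ratio of the largest
#' singular value to each singular value.
#'
#' @param x Numeric matrix or data frame of regressor columns (>= 2 columns,
#'   more rows than columns).
#' @return List with `vif` (tibble `term`, `vif`) and `condition_indices`
#'   (numeric, ascending; the last entry is the condition number).
#' @export
collinearity_diagnostics <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least two columns")
  if (nrow(x) <= ncol(x)) stop("need more rows than columns")
  terms <- colnames(x)
  if (is.null(terms)) terms <- paste0("x", seq_len(ncol(x)))
  vif <- vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    ssr <- sum(fit$residuals^2)
    sst <- sum((x[, j] - mean(x[, j]))^2)
    r2 <- 1 - ssr / sst
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1L))
  xs <- scale(x)
  sv <- svd(xs, nu = 0, nv = 0)$d
  list(
    vif = tibble::tibble(term = terms, vif = vif),
    condition_indices = sort(max(sv) / sv)
  )
}

#' Two-sample z-test for a coefficient difference across subgroups
#'
#' For independently estimated subgroup coefficients,
#' `z = (b1 - b2) / sqrt(se1^2 + se2^2)` with a two-sided normal p-value.
#'
#' @param b1,se1 Estimate and SE in group 1.
#' @param b2,se2 Estimate and SE in group 2.
#' @return One-row tibble: `z`, `p.value`.
#' @export
coefficient_difference_test <- function(b1, se1, b2, se2) {
  if (se1 <= 0 || se2 <= 0) stop("standard errors must be positive")
  z <- (b1 - b2) / sqrt(se1^2 + se2^2)
  tibble::tibble(z = z, p.value = 2 * stats::pnorm(-abs(z)))
}

#' Aggregate relative-week trajectory of a construct score
#'
#' Standardizes the raw score with its full-sample mean and SD, averages it
#' by relative week (weeks since registration), and smooths the weekly means
#' with a centered three-week moving average whose window shrinks to the
#' available neighbours at the series edges.
#'
#' @param scores Score tibble (e.g. from [score_texts()]) with `week_index`
#'   and the score column.
#' @param construct Optional construct name to filter on when a `construct`
#'   column is present.
#' @param score_col Score column name (default `"wepa_score"`).
#' @param window Moving-average width (odd; default 3).
#' @return A `wepa_trajectory` tibble: `relative_week`, `mean_score`
#'   (standardized), `smoothed_score`, `n_users_observed`.
#' @export
relative_week_trajectory <- function(scores, construct = NULL,
                                     score_col = "wepa_score", window = 3L) {
  stopifnot(window %% 2L == 1L, window >= 1L)
  if (!is.null(construct) && "construct" %in% names(scores)) {
    scores <- dplyr::filter(scores, .data$construct == !!construct)
  }
  vals <- scores[[score_col]]
  keep <- !is.na(vals)
  scores <- scores[keep, , drop = FALSE]
  vals <- vals[keep]
  if (length(vals) == 0L) stop("no non-missing scores")
  s <- stats::sd(vals)
  if (s == 0) stop("zero-variance scores: trajectory undefined")
  scores$.z <- (vals - mean(vals)) / s
  agg <- scores |>
    dplyr::group_by(relative_week = .data$week_index) |>
    dplyr::summarise(
      mean_score = mean(.data$.z),
      n_users_observed = if ("user_id" %in% names(scores)) {
        dplyr::n_distinct(.data$user_id)
      } else {
        dplyr::n()
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$relative_week)
  half <- (window - 1L) %/% 2L
  m <- agg$mean_score
  agg$smoothed_score <- vapply(seq_along(m), function(i) {
    lo <- max(1L, i - half)
    hi <- min(length(m), i + half)
    mean(m[lo:hi])
  }, numeric(1L))
  class(agg) <- c("wepa_trajectory", class(agg))
  agg
}

#' Textual-sparsity subsets of a panel
#'
#' Splits panel rows by the effective cleaned-text length used in scoring
#' (`valid_str_len`): at least `min_tokens` valid tokens; the short stratum
#' `(0, split)`; and the long stratum `[split, Inf)`.
#'
#' @param panel Tibble with a `valid_str_len` column.
#' @param min_tokens Minimum-token filter threshold (default 5).
#' @param split Short/long boundary (default 20; the boundary value belongs
#'   to the long stratum).
#' @return Named list of tibbles `min_valid`, `short`, `long`, with a
#'   `"counts"` attribute.
#' @export
sparsity_subsets <- function(panel, min_tokens = 5L, split = 20L) {
  stopifnot("valid_str_len" %in% names(panel))
  v <- panel$valid_str_len
  out <- list(
    min_valid = panel[v >= min_tokens, , drop = FALSE],
    short = panel[v > 0L & v < split, , drop = FALSE],
    long = panel[v >= split, , drop = FALSE]
  )
  attr(out, "counts") <- tibble::tibble(
    subset = names(out),
    n_records = unname(vapply(out, nrow, integer(1L)))
  )
  out
}

#' Anchor-pair perturbation sweep
#'
#' Robustness check on anchor-set dependence: randomly removes 1..`max_pairs`
#' positive-negative anchor pairs from the focal construct's dictionary,
#' rebuilds the axis, rescores the texts, re-estimates the focal
#' fixed-effects model, and reports each perturbed coefficient together with
#' its percent deviation `100 * |b_r - b_0| / |b_0|` from the unperturbed
#' baseline.
#'
#' @param anchors Anchor tibble for the focal construct.
#' @param space The [embedding_space()].
#' @param userweeks Token tibble as for [score_texts()].
#' @param panel Prepared panel rows joinable to scores on
#'   (`user_id`, `week_index`), already containing the outcome and controls.
#' @param construct Focal construct name.
#' @param controls Control columns for the regression.
#' @param max_pairs Maximum number of pairs removed (default 3).
#' @param seed Integer seed controlling which pairs are removed.
#' @param outcome Lead outcome column (default `"ExDur_lead"`, created here
#'   via [lead_outcome()] if absent).
#' @return Tibble: `condition`, `n_pairs_removed`, `beta`, `deviation_pct`.
#' @export
anchor_perturbation_sweep <- function(anchors, space, userweeks, panel,
                                      construct, controls = character(),
                                      max_pairs = 3L, seed = 1L,
                                      outcome = "ExDur") {
  anchors <- validate_anchors(anchors)
  anchors <- dplyr::filter(anchors, .data$construct == !!construct)
  screened <- screen_anchors(anchors, space)
  pos <- screened$word[screened$pole == "pos"]
  neg <- screened$word[screened$pole == "neg"]

  fit_with <- function(anc) {
    axis <- build_axis(anc, space, construct = construct)
    sc <- score_texts(userweeks, axis, space)
    merged <- dplyr::inner_join(
      panel,
      dplyr::select(sc, "user_id", "week_index", "wepa_score"),
      by = c("user_id", "week_index")
    )
    merged$score_z <- z_standardize(merged$wepa_score)
    rows <- lead_outcome(merged, outcome = outcome)
    fit <- fe_regression(rows, paste0(outcome, "_lead"),
                         focal = "score_z", controls = controls)
    unname(fit$coefficients["score_z"])
  }

  b0 <- fit_with(screened)
  set.seed(seed)
  res <- purrr::map_dfr(seq_len(max_pairs), function(np) {
    if (length(pos) - np < 2L || length(neg) - np < 2L) {
      stop("removing ", np, " pairs would leave a pole with < 2 words")
    }
    drop_pos <- sample(pos, np)
    drop_neg <- sample(neg, np)
    anc <- dplyr::filter(
      screened,
      !(.data$pole == "pos" & .data$word %in% drop_pos),
      !(.data$pole == "neg" & .data$word %in% drop_neg)
    )
    tibble::tibble(
      condition = paste0("R", np),
      n_pairs_removed = np,
      beta = fit_with(anc)
    )
  })
  dplyr::bind_rows(
    tibble::tibble(condition = "R0", n_pairs_removed = 0L, beta = b0),
    res
  ) |>
    dplyr::mutate(deviation_pct = 100 * abs(.data$beta - b0) / abs(b0))
}

#' Maximum percent deviation among perturbed coefficients
#'
#' Helper for summarising a perturbation sweep (or any set of re-estimated
#' coefficients) against a baseline: `max 100 * |b_r - b_0| / |b_0|`.
#'
#' @param baseline Baseline coefficient.
#' @param perturbed Numeric vector of perturbed coefficients.
#' @return Maximum percent deviation.
#' @export
max_deviation_pct <- function(baseline, perturbed) {
  if (baseline == 0) stop("baseline coefficient is zero")
  max(100 * abs(perturbed - baseline) / abs(baseline))
}
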