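test_that("winsorization clamps both tails at the requested percentiles", {
  expect_equal(winsorize(c(5, 1, 9), pct = 0), c(5, 1, 9))
  expect_equal(winsorize(rep(3, 10)), rep(3, 10))

  x <- as.numeric(1:1000)
  w <- winsorize(x, pct = 1)
  qs <- quantile(x, c(0.01, 0.99), names = FALSE)
  expect_equal(min(w), qs[1])
  expect_equal(max(w), qs[2])
  expect_equal(w[x > qs[1] & x < qs[2]], x[x > qs[1] & x < qs[2]])
  expect_error(winsorize(numeric()), "empty")
})

test_that("panel preparation applies log, first-difference and scaling rules", {
  raw <- tibble::tibble(
    user_id = "u1",
    week_index = 1:3,
    minutes = c(0, 10, 20),
    score = c(1, 2, 3)
  )
  out <- prepare_panel(raw, predictors = "score", standardize = FALSE,
                       winsor_pct = 0)
  expect_equal(out$ExDur, log(c(1, 11, 21)))
  expect_equal(out$DurChg, c(NA, log(11) - log(1), log(21) - log(11)))

  # standardized predictors have mean 0 and sd 1
  set.seed(8)
  raw2 <- tibble::tibble(
    user_id = rep(c("a", "b"), each = 5),
    week_index = rep(1:5, 2),
    minutes = rexp(10, 0.05),
    score = rnorm(10),
    soc_engage = rpois(10, 3)
  )
  out2 <- prepare_panel(raw2, predictors = "score")
  expect_equal(mean(out2$score), 0, tolerance = 1e-10)
  expect_equal(sd(out2$score), 1, tolerance = 1e-10)
  expect_equal(out2$soc_engage, log1p(rpois_vals <- raw2$soc_engage))
  expect_equal(attr(out2, "raw_mean_minutes"), mean(raw2$minutes))

  expect_error(prepare_panel(dplyr::mutate(raw, minutes = -1)), "negative")

  # DurChg is missing across week gaps
  gap <- tibble::tibble(user_id = "u", week_index = c(1, 3),
                        minutes = c(5, 6))
  outg <- prepare_panel(gap, standardize = FALSE, winsor_pct = 0)
  expect_true(all(is.na(outg$DurChg)))
})

test_that("lead pairing is strict about adjacent weeks", {
  p <- tibble::tibble(user_id = "u", week_index = c(1, 2, 3),
                      ExDur = c(1, 2, 3))
  expect_equal(nrow(lead_outcome(p)), 2)
  expect_equal(lead_outcome(p)$ExDur_lead, c(2, 3))

  gap <- tibble::tibble(user_id = "u", week_index = c(1, 3),
                        ExDur = c(1, 2))
  expect_equal(nrow(lead_outcome(gap)), 0)

  # mixed toy panel: hand enumeration
  mixed <- tibble::tibble(
    user_id = c("a", "a", "a", "b", "b", "c"),
    week_index = c(1, 2, 4, 7, 8, 1),
    ExDur = 1:6
  )
  # a: (1,2); b: (7,8); c: none -> 2 rows
  expect_equal(nrow(lead_outcome(mixed)), 2)
})

test_that("effect translations satisfy their closed forms and consistency", {
  expect_equal(semi_elasticity(0), 0)
  expect_equal(minutes_equivalent(0, 15.61), 0)
  set.seed(9)
  for (b in rnorm(5, sd = 0.3)) {
    expect_equal(minutes_equivalent(b, 15.61),
                 15.61 * semi_elasticity(b) / 100, tolerance = 1e-12)
  }
  expect_error(minutes_equivalent(0.1, ref_mean = 0))
})

test_that("collinearity diagnostics match the auxiliary-regression oracle", {
  set.seed(10)
  # orthogonal polynomials: centered, orthonormal columns
  q <- unclass(poly(1:200, 3))
  d0 <- collinearity_diagnostics(q)
  expect_equal(d0$vif$vif, rep(1, 3), tolerance = 1e-8)
  expect_equal(max(d0$condition_indices), 1, tolerance = 1e-8)

  # duplicated column flags infinite VIF
  x <- matrix(rnorm(100 * 2), 100, 2)
  dup <- cbind(x, x[, 1])
  expect_true(any(is.infinite(collinearity_diagnostics(dup)$vif$vif)))

  # random 5-column design vs explicit R^2 regressions
  z <- matrix(rnorm(300 * 5), 300, 5)
  z[, 2] <- z[, 1] + rnorm(300, sd = 0.4) # induce correlation
  dz <- collinearity_diagnostics(z)
  for (j in 1:5) {
    r2 <- summary(lm(z[, j] ~ z[, -j]))$r.squared
    expect_equal(dz$vif$vif[j], 1 / (1 - r2), tolerance = 1e-8)
  }
})

test_that("subgroup coefficient z-test matches the normal closed form", {
  eq <- coefficient_difference_test(0.5, 0.1, 0.5, 0.2)
  expect_equal(eq$z, 0)
  expect_equal(eq$p.value, 1)

  big <- coefficient_difference_test(1.0, 0.1, 0.0, 0.1)
  expect_equal(big$z, 1 / sqrt(0.02), tolerance = 1e-10)
  expect_lt(big$p.value, 1e-10)

  a <- coefficient_difference_test(0.074, 0.003, 0.059, 0.003)
  b <- coefficient_difference_test(0.059, 0.003, 0.074, 0.003)
  expect_equal(a$z, -b$z)
  expect_equal(a$p.value, b$p.value)
  expect_error(coefficient_difference_test(1, 0, 1, 1), "positive")
})

test_that("relative-week trajectories standardize, group and smooth correctly", {
  # raw weekly means 0, 3, 6 -> smoothed middle value is 3 (on the z scale
  # the ordering and the centered-mean identity survive standardization)
  sc <- tibble::tibble(
    user_id = rep("u", 6),
    week_index = rep(0:2, each = 2),
    wepa_score = c(-1, 1, 2, 4, 5, 7) # weekly means 0, 3, 6
  )
  tr <- relative_week_trajectory(sc)
  expect_equal(tr$relative_week, 0:2)
  expect_equal(tr$smoothed_score[2], mean(tr$mean_score), tolerance = 1e-12)
  # shrink-to-window edges: first smoothed value is mean of weeks 0-1
  expect_equal(tr$smoothed_score[1], mean(tr$mean_score[1:2]),
               tolerance = 1e-12)

  single <- relative_week_trajectory(
    tibble::tibble(user_id = c("a", "b"), week_index = 0,
                   wepa_score = c(1, 2))
  )
  expect_equal(single$smoothed_score, single$mean_score)

  # toy 6-week panel vs brute-force per-week averaging
  set.seed(12)
  toy <- tibble::tibble(
    user_id = sample(letters[1:4], 40, replace = TRUE),
    week_index = sample(0:5, 40, replace = TRUE),
    wepa_score = rnorm(40)
  )
  tr2 <- relative_week_trajectory(toy)
  z <- (toy$wepa_score - mean(toy$wepa_score)) / sd(toy$wepa_score)
  for (w in 0:5) {
    expect_equal(tr2$mean_score[tr2$relative_week == w],
                 mean(z[toy$week_index == w]), tolerance = 1e-12)
  }

  expect_error(
    relative_week_trajectory(
      tibble::tibble(user_id = "u", week_index = 0:3, wepa_score = 1)
    ),
    "zero-variance"
  )
})

test_that("sparsity subsets respect the half-open short stratum", {
  panel <- tibble::tibble(id = 1:6,
                          valid_str_len = c(0, 4, 5, 19, 20, 50))
  subs <- sparsity_subsets(panel)
  expect_equal(subs$min_valid$id, c(3, 4, 5, 6))
  expect_equal(subs$short$id, c(2, 3, 4)) # 0 excluded, 20 excluded
  expect_equal(subs$long$id, c(5, 6))     # 20 belongs to the long stratum
  counts <- attr(subs, "counts")
  expect_equal(counts$n_records, c(4L, 3L, 2L))
})
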