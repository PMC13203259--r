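# Small deterministic fixtures shared across the test files.

# A 4-token, 3-dimensional space with hand-chosen vectors.
toy_space <- function() {
  m <- rbind(
    run  = c(1, 0, 0),
    gym  = c(0, 1, 0),
    rest = c(0, 0, 1),
    quit = c(-1, 0, 0)
  )
  embedding_space(m, source_tag = "toy")
}

# Random space with reproducible vectors; tokens w001..w<n>.
random_space <- function(n = 30, d = 5, seed = 1, tag = "random") {
  set.seed(seed)
  m <- matrix(rnorm(n * d), n, d)
  rownames(m) <- sprintf("w%03d", seq_len(n))
  embedding_space(m, source_tag = tag)
}

# Anchor tibble over a random space: first `npos` tokens pos, next `nneg` neg.
random_anchors <- function(space, npos = 4, nneg = 4,
                           construct = "Construct") {
  tibble::tibble(
    construct = construct,
    pole = rep(c("pos", "neg"), c(npos, nneg)),
    word = space$vocabulary[seq_len(npos + nneg)]
  )
}

# Random orthogonal matrix via QR, sign-fixed for determinism.
random_orthogonal <- function(d, seed = 1) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(d * d), d, d))
  q <- qr.Q(qr_d)
  q %*% diag(sign(diag(qr.R(qr_d))), d)
}

# Simple balanced panel with known fixed effects and coefficient, regressor
# observed without error; returns estimation-ready rows (outcome y, regressor
# x, cluster user_id).
known_beta_panel <- function(n_users = 50, n_weeks = 6, beta = 0.5,
                             seed = 1, noise_sd = 1) {
  set.seed(seed)
  alpha <- rnorm(n_users)
  grid <- expand.grid(user = seq_len(n_users), week = seq_len(n_weeks))
  grid <- grid[order(grid$user, grid$week), ]
  x <- rnorm(nrow(grid))
  y <- alpha[grid$user] + beta * x + rnorm(nrow(grid), sd = noise_sd)
  tibble::tibble(
    user_id = sprintf("u%03d", grid$user),
    week_index = grid$week,
    x = x,
    y = y
  )
}

# Independent LSDV oracle: user-dummy least squares via base lm().
lsdv_fit <- function(data, outcome, vars, cluster = "user_id") {
  f <- stats::as.formula(paste(
    outcome, "~", paste(vars, collapse = " + "), "+ factor(", cluster, ")"
  ))
  stats::lm(f, data = data)
}
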