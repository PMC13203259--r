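#' Specification of a synthetic validation scenario
#'
#' Describes a complete synthetic data-generating scenario: an embedding
#' space with planted bipolar construct directions, anchor dictionaries,
#' user-week token streams whose positive/negative anchor mixture encodes a
#' latent construct intensity, and a next-week behavioral outcome driven by
#' an individual fixed effect plus a linear construct effect plus noise.
#' Every generator draws from streams derived from the single `seed`
#' (one fixed offset per sub-generator), so outputs are reproducible and
#' adding a generator never perturbs the others.
#'
#' Defaults encode the reference validation scenario used throughout the
#' test-suite: a 50-dimensional space, pole separation `delta = 3`, 300
#' users observed for 8 weeks, and a true construct effect of 0.5 on the
#' log-scale outcome.
#'
#' @param dimension Embedding dimension d.
#' @param vocab_size Total vocabulary size (anchors + filler tokens).
#' @param constructs Tibble or data frame with columns `name`,
#'   `n_pos_anchors`, `n_neg_anchors`, `delta` (pole separation),
#'   `sigma_a` (within-pole anchor sd).
#' @param n_users,n_weeks Panel dimensions.
#' @param token_count_range Inclusive range of tokens per user-week.
#' @param signal_strength Mixing weight in (0, 1): the probability mass moved
#'   towards pole-aligned tokens as the latent intensity departs from 0.
#' @param filler_alignment Tilt of non-anchor token draws towards tokens
#'   whose own axis position matches the latent intensity (0 = uniform
#'   fillers; default 1). Emulates construct-related vocabulary outside the
#'   anchor lists.
#' @param true_beta Effect of the latent construct at week t on the log-scale
#'   outcome at week t + 1.
#' @param fixed_effect_sd SD of the individual fixed effects.
#' @param noise_sd SD of the idiosyncratic outcome noise.
#' @param seed Integer seed (mandatory).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(dimension = 50L,
                           vocab_size = 500L,
                           constructs = tibble::tibble(
                             name = "GoalCommit",
                             n_pos_anchors = 8L,
                             n_neg_anchors = 8L,
                             delta = 3,
                             sigma_a = 0.5
                           ),
                           n_users = 300L,
                           n_weeks = 8L,
                           token_count_range = c(20L, 60L),
                           signal_strength = 0.35,
                           filler_alignment = 1,
                           true_beta = 0.5,
                           fixed_effect_sd = 1,
                           noise_sd = 1,
                           seed) {
  if (missing(seed)) stop("seed is mandatory for synthetic generation")
  constructs <- tibble::as_tibble(constructs)
  need <- c("name", "n_pos_anchors", "n_neg_anchors", "delta", "sigma_a")
  stopifnot(all(need %in% names(constructs)),
            all(constructs$delta >= 0),
            dimension >= 2L, vocab_size > 0L, n_users > 0L, n_weeks > 1L,
            length(token_count_range) == 2L,
            token_count_range[[1L]] >= 1L,
            token_count_range[[2L]] >= token_count_range[[1L]],
            signal_strength >= 0, signal_strength < 1)
  n_anchors <- sum(constructs$n_pos_anchors + constructs$n_neg_anchors)
  if (vocab_size <= n_anchors) {
    stop("vocab_size (", vocab_size, ") must exceed total anchor count (",
         n_anchors, ")")
  }
  structure(
    list(dimension = as.integer(dimension),
         vocab_size = as.integer(vocab_size),
         constructs = constructs,
         n_users = as.integer(n_users),
         n_weeks = as.integer(n_weeks),
         token_count_range = as.integer(token_count_range),
         signal_strength = signal_strength,
         filler_alignment = filler_alignment,
         true_beta = true_beta,
         fixed_effect_sd = fixed_effect_sd,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Per-sub-generator seed streams: fixed offsets from the spec seed, kept
# below 2^31.
stream_seed <- function(spec, stream) {
  offsets <- c(space = 11L, panel = 23L, benchmark = 37L)
  (spec$seed + offsets[[stream]]) %% .Machine$integer.max
}

#' Generate an embedding space with planted bipolar axes
#'
#' For each construct a random unit direction `e_c` is drawn; positive
#' anchors are sampled isotropically (sd `sigma_a`) around `+delta/2 * e_c`
#' and negative anchors around `-delta/2 * e_c`, while filler tokens are
#' isotropic around the origin. With `delta` well above `sigma_a` the planted
#' construct passes the pole diagnostics; at `delta = 0` the axis direction
#' is pure noise.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `space` (an [embedding_space()]), `anchors` (anchor
#'   tibble) and `directions` (named list of the planted unit vectors).
#' @export
make_space <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(stream_seed(spec, "space"))
  d <- spec$dimension
  cons <- spec$constructs
  vocab <- character(0)
  rows <- list()
  anchors <- list()
  directions <- list()
  for (i in seq_len(nrow(cons))) {
    cn <- cons$name[[i]]
    e <- stats::rnorm(d)
    e <- e / sqrt(sum(e^2))
    directions[[cn]] <- e
    npos <- cons$n_pos_anchors[[i]]
    nneg <- cons$n_neg_anchors[[i]]
    half <- cons$delta[[i]] / 2
    sd_a <- cons$sigma_a[[i]]
    pos_mat <- matrix(stats::rnorm(npos * d, sd = sd_a), npos, d,
                      byrow = TRUE) + matrix(half * e, npos, d, byrow = TRUE)
    neg_mat <- matrix(stats::rnorm(nneg * d, sd = sd_a), nneg, d,
                      byrow = TRUE) - matrix(half * e, nneg, d, byrow = TRUE)
    pos_words <- sprintf("%s_pos_%02d", tolower(cn), seq_len(npos))
    neg_words <- sprintf("%s_neg_%02d", tolower(cn), seq_len(nneg))
    vocab <- c(vocab, pos_words, neg_words)
    rows <- c(rows, list(pos_mat, neg_mat))
    anchors[[cn]] <- tibble::tibble(
      construct = cn,
      pole = rep(c("pos", "neg"), c(npos, nneg)),
      word = c(pos_words, neg_words)
    )
  }
  n_fill <- spec$vocab_size - length(vocab)
  fill_words <- sprintf("filler_%04d", seq_len(n_fill))
  fill_mat <- matrix(stats::rnorm(n_fill * d), n_fill, d)
  vectors <- do.call(rbind, c(rows, list(fill_mat)))
  space <- embedding_space(vectors, c(vocab, fill_words),
                           source_tag = paste0("synthetic-seed", spec$seed))
  list(space = space, anchors = dplyr::bind_rows(anchors),
       directions = directions)
}

# Draw one user-week token vector given latent intensity z: pole-aligned
# token shares rise/fall with plogis(z), remainder are non-anchor tokens.
# When `fill_proj` (axis projection of each filler token) is supplied,
# fillers are drawn with probability tilted towards tokens whose own axis
# position matches z — construct-related vocabulary beyond the anchor lists,
# visible to projection scoring but invisible to exact dictionary matching.
draw_tokens <- function(n, z, pos_words, neg_words, fill_words, strength,
                        fill_proj = NULL, alignment = 1) {
  p_pos <- strength * stats::plogis(2 * z)
  p_neg <- strength * stats::plogis(-2 * z)
  kind <- sample.int(3L, n, replace = TRUE,
                     prob = c(p_pos, p_neg, 1 - p_pos - p_neg))
  out <- character(n)
  out[kind == 1L] <- sample(pos_words, sum(kind == 1L), replace = TRUE)
  out[kind == 2L] <- sample(neg_words, sum(kind == 2L), replace = TRUE)
  n_fill <- sum(kind == 3L)
  if (n_fill) {
    if (is.null(fill_proj)) {
      out[kind == 3L] <- sample(fill_words, n_fill, replace = TRUE)
    } else {
      w <- exp(pmin(alignment * z * fill_proj, 30))
      out[kind == 3L] <- sample(fill_words, n_fill, replace = TRUE,
                                prob = w)
    }
  }
  out
}

# Axis projections of the non-anchor vocabulary, used to tilt filler draws.
filler_projections <- function(spec, space, anchors) {
  cn <- spec$constructs$name[[1L]]
  axis <- build_axis(anchors[anchors$construct == cn, ], space)
  fill_words <- setdiff(space$vocabulary, anchors$word)
  list(words = fill_words,
       proj = as.numeric(space$vectors[fill_words, , drop = FALSE] %*%
                           axis$axis))
}

#' Generate a synthetic user-week corpus and behavioral panel
#'
#' Per user-week, a latent construct intensity `z ~ N(0, 1)` drives the
#' token mixture (tokens are drawn from the first construct's positive
#' anchors with probability increasing in `z`, from its negative anchors with
#' probability decreasing in `z`, and from fillers otherwise). The log-scale
#' outcome follows `ExDur[i, t+1] = alpha_i + true_beta * z[i, t] + noise`,
#' with `alpha_i` an individual fixed effect. Token streams are emitted as
#' raw posts so the corpus-preparation cleaning rules are exercised by the
#' full pipeline; the hidden truth (`z`, `alpha`) is returned for recovery
#' tests.
#'
#' @param spec A [synthetic_spec()].
#' @param space,anchors Output of [make_space()] (the space and anchor
#'   tibble).
#' @return List with `posts` (tibble `user_id`, `timestamp`, `text`),
#'   `registrations` (`user_id`, `registration_date`), `panel` (tibble
#'   `user_id`, `week_index`, `minutes` is not modelled — the outcome is
#'   generated directly on the log scale as `ExDur`), and `truth`
#'   (`user_id`, `week_index`, `z`, `alpha`).
#' @export
make_panel <- function(spec, space, anchors) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(stream_seed(spec, "panel"))
  cn <- spec$constructs$name[[1L]]
  pos_words <- anchors$word[anchors$construct == cn & anchors$pole == "pos"]
  neg_words <- anchors$word[anchors$construct == cn & anchors$pole == "neg"]
  fp <- filler_projections(spec, space, anchors)
  fill_words <- fp$words
  n_u <- spec$n_users
  n_w <- spec$n_weeks
  user_ids <- sprintf("u%04d", seq_len(n_u))
  alpha <- stats::rnorm(n_u, sd = spec$fixed_effect_sd)
  reg_date <- as.Date("2020-01-06")

  grid <- tidyr::expand_grid(ui = seq_len(n_u), week = seq_len(n_w) - 1L)
  grid$z <- stats::rnorm(nrow(grid))
  n_tok <- sample(seq(spec$token_count_range[[1L]],
                      spec$token_count_range[[2L]]),
                  nrow(grid), replace = TRUE)
  texts <- vapply(seq_len(nrow(grid)), function(i) {
    paste(draw_tokens(n_tok[[i]], grid$z[[i]], pos_words, neg_words,
                      fill_words, spec$signal_strength,
                      fill_proj = fp$proj,
                      alignment = spec$filler_alignment),
          collapse = " ")
  }, character(1L))

  posts <- tibble::tibble(
    user_id = user_ids[grid$ui],
    timestamp = as.POSIXct(reg_date, tz = "UTC") + grid$week * 7 * 86400 +
      3600,
    text = texts
  )
  registrations <- tibble::tibble(user_id = user_ids,
                                  registration_date = reg_date)

  # outcome at week t responds to z at week t-1
  eps <- stats::rnorm(nrow(grid), sd = spec$noise_sd)
  z_prev <- dplyr::lag(grid$z)
  first_week <- grid$week == 0L
  exdur <- alpha[grid$ui] + spec$true_beta * ifelse(first_week, 0, z_prev) +
    eps
  panel <- tibble::tibble(
    user_id = user_ids[grid$ui],
    week_index = grid$week,
    ExDur = exdur
  )
  truth <- tibble::tibble(
    user_id = user_ids[grid$ui],
    week_index = grid$week,
    z = grid$z,
    alpha = alpha[grid$ui]
  )
  list(posts = posts, registrations = registrations, panel = panel,
       truth = truth)
}

#' Generate a benchmark set of labelled synthetic texts
#'
#' Emulates an annotated benchmark: `n_texts` short texts whose ordinal
#' ground-truth label (1..5) drives the pole-token mixture, for comparing
#' projection and dictionary scoring against "human" labels via Spearman
#' correlation.
#'
#' @param spec A [synthetic_spec()].
#' @param space,anchors Output of [make_space()].
#' @param n_texts Number of benchmark texts.
#' @param n_levels Number of ordinal label levels.
#' @return Tibble: `text_id`, `label`, `tokens` (list column), `text`.
#' @export
make_benchmark <- function(spec, space, anchors, n_texts = 500L,
                           n_levels = 5L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(stream_seed(spec, "benchmark"))
  cn <- spec$constructs$name[[1L]]
  pos_words <- anchors$word[anchors$construct == cn & anchors$pole == "pos"]
  neg_words <- anchors$word[anchors$construct == cn & anchors$pole == "neg"]
  fp <- filler_projections(spec, space, anchors)
  fill_words <- fp$words
  label <- sample.int(n_levels, n_texts, replace = TRUE)
  z <- (label - (n_levels + 1) / 2) # centered ordinal intensity
  n_tok <- sample(seq(spec$token_count_range[[1L]],
                      spec$token_count_range[[2L]]),
                  n_texts, replace = TRUE)
  tokens <- lapply(seq_len(n_texts), function(i) {
    draw_tokens(n_tok[[i]], z[[i]], pos_words, neg_words, fill_words,
                spec$signal_strength, fill_proj = fp$proj,
                alignment = spec$filler_alignment)
  })
  tibble::tibble(
    text_id = seq_len(n_texts),
    label = label,
    tokens = tokens,
    text = vapply(tokens, paste, character(1L), collapse = " ")
  )
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Materialises one scenario in the same plain-text formats the real pipeline
#' consumes: the embedding file (word2vec text), the anchor dictionary (CSV),
#' the raw-post corpus (JSONL), the registration table (CSV) and the hidden
#' truth (CSV).
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture_bundle <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- make_space(spec)
  pn <- make_panel(spec, sp$space, sp$anchors)
  paths <- c(
    embedding = file.path(dir, "embedding.txt"),
    anchors = file.path(dir, "anchors.csv"),
    corpus = file.path(dir, "corpus.jsonl"),
    registrations = file.path(dir, "registrations.csv"),
    panel = file.path(dir, "panel.csv"),
    truth = file.path(dir, "truth.csv")
  )
  write_word2vec(sp$space, paths[["embedding"]])
  readr::write_csv(sp$anchors, paths[["anchors"]])
  con <- file(paths[["corpus"]], open = "wt", encoding = "UTF-8")
  jsonlite::stream_out(
    dplyr::mutate(pn$posts,
                  timestamp = format(.data$timestamp,
                                     "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")),
    con, verbose = FALSE
  )
  close(con)
  readr::write_csv(pn$registrations, paths[["registrations"]])
  readr::write_csv(pn$panel, paths[["panel"]])
  readr::write_csv(pn$truth, paths[["truth"]])
  invisible(paths)
}
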