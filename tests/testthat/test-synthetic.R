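small_spec <- function(seed, ...) {
  synthetic_spec(
    dimension = 20L, vocab_size = 120L,
    n_users = 60L, n_weeks = 5L,
    token_count_range = c(10L, 25L),
    seed = seed, ...
  )
}

test_that("generation is deterministic under a fixed seed", {
  s1 <- make_space(small_spec(99))
  s2 <- make_space(small_spec(99))
  expect_identical(s1$space$vectors, s2$space$vectors)
  expect_identical(s1$anchors, s2$anchors)

  p1 <- make_panel(small_spec(99), s1$space, s1$anchors)
  p2 <- make_panel(small_spec(99), s2$space, s2$anchors)
  expect_identical(p1$posts$text, p2$posts$text)
  expect_identical(p1$panel$ExDur, p2$panel$ExDur)

  b1 <- make_benchmark(small_spec(99), s1$space, s1$anchors, n_texts = 40)
  b2 <- make_benchmark(small_spec(99), s2$space, s2$anchors, n_texts = 40)
  expect_identical(b1$text, b2$text)
})

test_that("wide pole separation passes diagnostics; zero separation is near chance", {
  wide <- synthetic_spec(
    dimension = 20L, vocab_size = 120L, n_users = 10L, n_weeks = 2L,
    constructs = tibble::tibble(name = "C", n_pos_anchors = 8L,
                                n_neg_anchors = 8L, delta = 4,
                                sigma_a = 0.1),
    seed = 1
  )
  sw <- make_space(wide)
  expect_true(pole_diagnostics(sw$anchors, sw$space)$passes)

  pass_at_delta <- function(delta, seeds) {
    mean(vapply(seeds, function(s) {
      sp <- make_space(synthetic_spec(
        dimension = 20L, vocab_size = 60L, n_users = 5L, n_weeks = 2L,
        constructs = tibble::tibble(name = "C", n_pos_anchors = 6L,
                                    n_neg_anchors = 6L, delta = delta,
                                    sigma_a = 1),
        seed = s
      ))
      pole_diagnostics(sp$anchors, sp$space)$passes
    }, logical(1)))
  }
  expect_equal(pass_at_delta(4, 1:30), 1)
  expect_lt(pass_at_delta(0, 1:60), 0.75) # near-chance, far from certain
})

test_that("vocab too small for the anchors is rejected", {
  expect_error(
    synthetic_spec(vocab_size = 10L,
                   constructs = tibble::tibble(name = "C",
                                               n_pos_anchors = 8L,
                                               n_neg_anchors = 8L,
                                               delta = 3, sigma_a = 0.5),
                   seed = 1),
    "exceed"
  )
})

test_that("a zero construct effect yields a null fixed-effects estimate", {
  spec <- small_spec(7, true_beta = 0)
  sp <- make_space(spec)
  pn <- make_panel(spec, sp$space, sp$anchors)
  uw <- aggregate_weeks(pn$posts, pn$registrations)
  ax <- build_axis(sp$anchors, sp$space)
  sc <- score_texts(uw, ax, sp$space, baseline = FALSE)
  m <- dplyr::inner_join(
    pn$panel, dplyr::select(sc, user_id, week_index, wepa_score),
    by = c("user_id", "week_index")
  )
  m$score_z <- (m$wepa_score - mean(m$wepa_score)) / sd(m$wepa_score)
  rows <- lead_outcome(m)
  fit <- fe_regression(rows, "ExDur_lead", focal = "score_z")
  expect_lt(abs(fit$coefficients["score_z"]), 3 * fit$se["score_z"])
})

test_that("mean projection score increases across latent quartiles", {
  spec <- small_spec(13, signal_strength = 0.5)
  sp <- make_space(spec)
  pn <- make_panel(spec, sp$space, sp$anchors)
  uw <- aggregate_weeks(pn$posts, pn$registrations)
  ax <- build_axis(sp$anchors, sp$space)
  sc <- score_texts(uw, ax, sp$space, baseline = FALSE)
  m <- dplyr::inner_join(
    sc, pn$truth, by = c("user_id", "week_index")
  )
  qs <- cut(m$z, quantile(m$z, 0:4 / 4), include.lowest = TRUE,
            labels = FALSE)
  means <- tapply(m$wepa_score, qs, mean)
  expect_true(all(diff(means) > 0))
})

test_that("benchmark labels drive projection scores; shuffling kills the signal", {
  spec <- synthetic_spec(
    dimension = 20L, vocab_size = 120L, n_users = 5L, n_weeks = 2L,
    token_count_range = c(10L, 25L), signal_strength = 0.5, seed = 17
  )
  sp <- make_space(spec)
  bench <- make_benchmark(spec, sp$space, sp$anchors, n_texts = 500)
  ax <- build_axis(sp$anchors, sp$space)
  uw <- tibble::tibble(user_id = "t", week_index = bench$text_id,
                       tokens = bench$tokens)
  sc <- score_texts(uw, ax, sp$space)
  strong <- benchmark_agreement(sc$wepa_score, bench$label)
  expect_gt(strong$rho, 0.8)

  set.seed(18)
  shuffled <- benchmark_agreement(sc$wepa_score, sample(bench$label))
  expect_lt(abs(shuffled$rho), 0.1)

  # sparse-coverage regime: the projection scorer tracks the labels better
  # than the dictionary baseline when few texts hit an anchor word
  sparse_spec <- synthetic_spec(
    dimension = 20L, vocab_size = 400L, n_users = 5L, n_weeks = 2L,
    token_count_range = c(4L, 8L), signal_strength = 0.08, seed = 19
  )
  ssp <- make_space(sparse_spec)
  sbench <- make_benchmark(sparse_spec, ssp$space, ssp$anchors,
                           n_texts = 400)
  sax <- build_axis(ssp$anchors, ssp$space)
  suw <- tibble::tibble(user_id = "t", week_index = sbench$text_id,
                        tokens = sbench$tokens)
  ssc <- score_texts(suw, sax, ssp$space)
  wepa_rho <- benchmark_agreement(ssc$wepa_score, sbench$label)$rho
  dict_rho <- benchmark_agreement(ssc$dict_score, sbench$label,
                                  covered = ssc$covered)$rho
  expect_lt(coverage(ssc$covered), 60)
  expect_equal(coverage(!ssc$missing), 100)
  expect_gt(wepa_rho, dict_rho)
})

test_that("fixture bundles round-trip through the file formats", {
  dir <- withr::local_tempdir()
  spec <- small_spec(23)
  paths <- write_fixture_bundle(spec, dir)
  expect_true(all(file.exists(paths)))

  sp <- read_word2vec(paths[["embedding"]])
  gen <- make_space(spec)
  expect_identical(sp$vocabulary, gen$space$vocabulary)
  expect_equal(sp$vectors, gen$space$vectors, tolerance = 1e-6)

  anchors <- read_anchors(paths[["anchors"]])
  expect_identical(anchors$word, gen$anchors$word)

  posts <- read_corpus(paths[["corpus"]])
  pn <- make_panel(spec, gen$space, gen$anchors)
  expect_equal(nrow(posts), nrow(pn$posts))
  expect_identical(posts$text[1], pn$posts$text[1])
})
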