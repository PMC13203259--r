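test_that("anchor screening keeps in-vocabulary words and reports drops", {
  sp <- toy_space()
  anchors <- tibble::tibble(
    construct = "Commit",
    pole = c("pos", "pos", "neg", "neg"),
    word = c("run", "missing1", "quit", "missing2")
  )
  out <- screen_anchors(anchors, sp)
  expect_equal(out$word, c("run", "quit"))
  rep <- attr(out, "screening")
  expect_equal(sum(rep$n_candidates), 4)
  expect_equal(sum(rep$n_retained), 2)
  expect_setequal(unlist(rep$dropped), c("missing1", "missing2"))

  # all in vocabulary: screening is the identity on rows
  ok <- tibble::tibble(construct = "C", pole = c("pos", "neg"),
                       word = c("run", "quit"))
  expect_equal(screen_anchors(ok, sp)$word, ok$word)

  # a fully OOV pole is an error naming construct and pole
  bad <- tibble::tibble(construct = "C", pole = c("pos", "neg"),
                        word = c("zzz", "quit"))
  expect_error(screen_anchors(bad, sp), "C.*pos")
})

test_that("screening retains exactly the in-vocabulary candidate count", {
  # 260 candidates of which 9 are out of vocabulary -> 251 retained
  sp <- random_space(n = 300, d = 4, seed = 9)
  words <- c(sp$vocabulary[1:251], sprintf("oov%02d", 1:9))
  anchors <- tibble::tibble(
    construct = "C",
    pole = rep(c("pos", "neg"), c(130, 130)),
    word = words
  )
  out <- screen_anchors(anchors, sp)
  expect_equal(nrow(out), 251)
})

test_that("pole prototype is the anchor centroid", {
  sp <- toy_space()
  expect_equal(unname(pole_prototype("run", sp)), c(1, 0, 0))
  expect_equal(unname(pole_prototype(c("run", "gym"), sp)), c(0.5, 0.5, 0))

  # 7 random anchors vs an independent summation oracle
  rsp <- random_space(n = 20, d = 6, seed = 5)
  words <- rsp$vocabulary[3:9]
  oracle <- Reduce(`+`, lapply(words, function(w) rsp$vectors[w, ])) / 7
  expect_equal(pole_prototype(words, rsp), oracle, tolerance = 1e-12)

  expect_error(pole_prototype(character(), sp), "empty")
  expect_error(pole_prototype("nope", sp), "out-of-vocabulary")
})

test_that("axis construction normalises the prototype difference", {
  expect_equal(axis_from_prototypes(c(1, 0), c(-1, 0)), c(1, 0))
  expect_equal(axis_from_prototypes(c(2, 2), c(0, 0)),
               c(1, 1) / sqrt(2), tolerance = 1e-10)
  expect_error(axis_from_prototypes(c(1, 1), c(1, 1)), "identical")

  sp <- random_space(n = 16, d = 8, seed = 2)
  anchors <- random_anchors(sp)
  ax <- build_axis(anchors, sp)
  expect_equal(sqrt(sum(ax$axis^2)), 1, tolerance = 1e-10)
})

test_that("swapping poles negates the axis; translation leaves it unchanged", {
  sp <- random_space(n = 16, d = 8, seed = 12)
  anchors <- random_anchors(sp)
  ax <- build_axis(anchors, sp)

  swapped <- dplyr::mutate(
    anchors, pole = ifelse(pole == "pos", "neg", "pos")
  )
  ax_sw <- build_axis(swapped, sp)
  expect_equal(ax_sw$axis, -ax$axis, tolerance = 1e-12)

  shift <- rnorm(sp$dimension)
  shifted <- embedding_space(
    sweep(sp$vectors, 2, shift, `+`), sp$vocabulary
  )
  ax_sh <- build_axis(anchors, shifted)
  expect_equal(ax_sh$axis, ax$axis, tolerance = 1e-10)
})

test_that("pole diagnostics match trivial geometry and a brute-force oracle", {
  # two identical-vector poles, orthogonal across poles
  m <- rbind(p1 = c(1, 0), p2 = c(1, 0), n1 = c(0, 1), n2 = c(0, 1))
  sp <- embedding_space(m)
  anchors <- tibble::tibble(construct = "C",
                            pole = c("pos", "pos", "neg", "neg"),
                            word = c("p1", "p2", "n1", "n2"))
  d1 <- pole_diagnostics(anchors, sp)
  expect_equal(c(d1$within_pos, d1$within_neg, d1$between), c(1, 1, 0))
  expect_true(d1$passes)

  # all anchors identical: all three means are 1, diagnostics fail
  m2 <- matrix(rep(c(1, 1), 4), 4, 2, byrow = TRUE)
  rownames(m2) <- c("p1", "p2", "n1", "n2")
  d2 <- pole_diagnostics(anchors, embedding_space(m2))
  expect_equal(c(d2$within_pos, d2$within_neg, d2$between), c(1, 1, 1))
  expect_false(d2$passes)

  # random 4+4 anchors vs exhaustive pairwise averaging
  rsp <- random_space(n = 10, d = 5, seed = 21)
  ranch <- random_anchors(rsp, npos = 4, nneg = 4)
  d3 <- pole_diagnostics(ranch, rsp)
  pos <- ranch$word[ranch$pole == "pos"]
  neg <- ranch$word[ranch$pole == "neg"]
  pair_mean <- function(a, b) {
    mean(apply(expand.grid(a, b, stringsAsFactors = FALSE), 1, function(p) {
      cosine_similarity(rsp$vectors[p[1], ], rsp$vectors[p[2], ])
    }))
  }
  within_oracle <- function(ws) {
    prs <- t(combn(ws, 2))
    mean(apply(prs, 1, function(p) {
      cosine_similarity(rsp$vectors[p[1], ], rsp$vectors[p[2], ])
    }))
  }
  expect_equal(d3$within_pos, within_oracle(pos), tolerance = 1e-12)
  expect_equal(d3$within_neg, within_oracle(neg), tolerance = 1e-12)
  expect_equal(d3$between, pair_mean(pos, neg), tolerance = 1e-12)
})

test_that("single-word poles yield undefined within-pole similarity", {
  sp <- toy_space()
  anchors <- tibble::tibble(construct = "C", pole = c("pos", "neg", "neg"),
                            word = c("run", "quit", "rest"))
  d <- pole_diagnostics(anchors, sp)
  expect_true(is.na(d$within_pos))
  expect_false(is.na(d$between))
  expect_true(is.na(d$passes))
})

test_that("anchor dictionaries load from CSV and JSON", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("construct,pole,word", "C,pos,run", "C,neg,quit"), csv)
  a1 <- read_anchors(csv)
  expect_equal(a1$word, c("run", "quit"))

  js <- withr::local_tempfile(fileext = ".json")
  writeLines('{"C": {"pos": ["run"], "neg": ["quit"]}}', js)
  a2 <- read_anchors(js)
  expect_equal(dplyr::arrange(a2, word)$word, c("quit", "run"))

  demo <- read_anchors(system.file("extdata", "anchor_glosses_demo.csv",
                                   package = "wepa"))
  expect_true(all(c("GoalCommit", "PhyState") %in% demo$construct))
})
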