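#' Mean text vector with OOV tokens in the denominator
#'
#' The text vector is the mean of the embedding vectors of *all* cleaned
#' tokens: out-of-vocabulary tokens contribute zero vectors but stay in the
#' denominator, pulling low-coverage texts towards the neutral point. An empty
#' token list yields a missing text vector (`NULL`).
#'
#' @param tokens Character vector of cleaned tokens.
#' @param space An [embedding_space()].
#' @return A list with `vector` (length-d numeric, or `NULL` when missing),
#'   `n_tokens`, `n_invocab`, `missing`.
#' @export
text_vector <- function(tokens, space) {
  n <- length(tokens)
  if (n == 0L) {
    return(list(vector = NULL, n_tokens = 0L, n_invocab = 0L,
                missing = TRUE))
  }
  emb <- embed_tokens(space, tokens)
  list(
    vector = colSums(emb$vectors) / n,
    n_tokens = n,
    n_invocab = sum(emb$in_vocab),
    missing = FALSE
  )
}

#' Projection score of a text vector on a construct axis
#'
#' The scalar projection (dot product) of the mean text vector onto the unit
#' semantic-axis vector. Positive values indicate language closer to the
#' positive pole; larger magnitudes indicate greater deviation from the
#' neutral point.
#'
#' @param text_vec Length-d numeric vector (not missing).
#' @param axis A `construct_axis` from [build_axis()], or a unit-norm numeric
#'   vector.
#' @return Signed scalar score.
#' @export
projection_score <- function(text_vec, axis) {
  axis_vec <- if (inherits(axis, "construct_axis")) axis$axis else axis
  if (length(text_vec) != length(axis_vec)) {
    stop("dimension mismatch: text vector has length ", length(text_vec),
         ", axis has length ", length(axis_vec))
  }
  sum(text_vec * axis_vec)
}

#' Dictionary-ratio baseline score
#'
#' Closed-vocabulary baseline: counts the distinct word *types* shared between
#' the text and each anchor pole and forms the damped normalised difference
#' `(pos_hits - neg_hits) / (pos_hits + neg_hits + 1)`, which lies strictly in
#' (-1, 1). A text is "covered" when it hits at least one anchor. Set
#' `count = "tokens"` to count occurrences instead of types.
#'
#' @param tokens Character vector of cleaned tokens.
#' @param pos_words,neg_words Anchor words of the two poles (disjoint).
#' @param count `"types"` (set intersection, default) or `"tokens"`
#'   (occurrence counts).
#' @return A one-row tibble: `pos_hits`, `neg_hits`, `dict_score`, `covered`.
#' @export
#' @examples
#' dictionary_score(c("persist", "plan", "quit"),
#'                  pos_words = c("persist", "plan"), neg_words = "quit")
dictionary_score <- function(tokens, pos_words, neg_words,
                             count = c("types", "tokens")) {
  count <- match.arg(count)
  if (length(intersect(pos_words, neg_words))) {
    stop("anchor pole sets are not disjoint")
  }
  if (count == "types") {
    pos_hits <- length(intersect(unique(tokens), pos_words))
    neg_hits <- length(intersect(unique(tokens), neg_words))
  } else {
    pos_hits <- sum(tokens %in% pos_words)
    neg_hits <- sum(tokens %in% neg_words)
  }
  tibble::tibble(
    pos_hits = pos_hits,
    neg_hits = neg_hits,
    dict_score = (pos_hits - neg_hits) / (pos_hits + neg_hits + 1),
    covered = (pos_hits + neg_hits) > 0L
  )
}

#' Score user-week texts on construct axes
#'
#' The main scoring entry point: for every (user-week, construct) pair,
#' computes the projection score and the dictionary-ratio baseline from the
#' same anchor sets. Projection scores are missing only when the token list is
#' empty; a text of pure OOV tokens scores 0 (the zero text vector projected
#' on the axis), so projection coverage of non-empty texts is always 100%.
#'
#' @param userweeks Tibble with `user_id`, `week_index`, `tokens` (list
#'   column), e.g. from [aggregate_weeks()].
#' @param axes Named list of `construct_axis` objects from [build_axes()], or
#'   a single `construct_axis`.
#' @param space The [embedding_space()] the axes were built in.
#' @param dict_count Hit-counting mode for the baseline, see
#'   [dictionary_score()].
#' @param baseline Compute the dictionary baseline alongside the projection
#'   scores? (Default `TRUE`.)
#' @return Long tibble: `user_id`, `week_index`, `construct`, `wepa_score`,
#'   `n_tokens`, `n_invocab`, `missing`, and with `baseline = TRUE` also
#'   `pos_hits`, `neg_hits`, `dict_score`, `covered`.
#' @export
score_texts <- function(userweeks, axes, space, dict_count = "types",
                        baseline = TRUE) {
  stopifnot(all(c("user_id", "week_index", "tokens") %in% names(userweeks)))
  dict_count <- match.arg(dict_count, c("types", "tokens"))
  if (inherits(axes, "construct_axis")) {
    axes <- stats::setNames(list(axes), axes$construct)
  }
  # one flat lookup over all tokens, then per-text aggregation by rowsum
  n_per <- lengths(userweeks$tokens)
  flat <- unlist(userweeks$tokens, use.names = FALSE)
  grp <- rep.int(seq_len(nrow(userweeks)), n_per)
  d <- space$dimension
  sums <- matrix(0, nrow = nrow(userweeks), ncol = d)
  n_invocab <- integer(nrow(userweeks))
  if (length(flat)) {
    emb <- embed_tokens(space, flat)
    agg <- rowsum(emb$vectors, group = grp, reorder = FALSE)
    rows <- as.integer(rownames(agg))
    sums[rows, ] <- agg
    hits <- rowsum(as.numeric(emb$in_vocab), group = grp, reorder = FALSE)
    n_invocab[as.integer(rownames(hits))] <- as.integer(hits[, 1L])
  }
  text_mat <- sums / pmax(n_per, 1L)
  missing <- n_per == 0L

  # vectorized pole-hit counts over the flat token stream
  count_hits <- function(words) {
    out <- integer(nrow(userweeks))
    if (!length(flat)) return(out)
    in_set <- flat %in% words
    if (dict_count == "types") {
      key <- paste0(grp, "\r", flat)
      in_set <- in_set & !duplicated(key)
    }
    tab <- rowsum(as.integer(in_set), group = grp, reorder = FALSE)
    out[as.integer(rownames(tab))] <- as.integer(tab[, 1L])
    out
  }

  purrr::imap_dfr(axes, function(axis, construct) {
    wepa <- as.numeric(text_mat %*% axis$axis)
    wepa[missing] <- NA_real_
    out <- tibble::tibble(
      user_id = userweeks$user_id,
      week_index = userweeks$week_index,
      construct = construct,
      wepa_score = wepa,
      n_tokens = n_per,
      n_invocab = n_invocab,
      missing = missing
    )
    if (baseline) {
      pos_hits <- count_hits(axis$anchors_pos)
      neg_hits <- count_hits(axis$anchors_neg)
      out$pos_hits <- pos_hits
      out$neg_hits <- neg_hits
      out$dict_score <- (pos_hits - neg_hits) / (pos_hits + neg_hits + 1)
      out$covered <- (pos_hits + neg_hits) > 0L
    }
    out
  })
}

#' Overall self-efficacy composite
#'
#' Sums the four source-dimension projection scores (mastery experience,
#' vicarious experience, social persuasion, physiological states) into the
#' overall self-efficacy indicator. The composite is formed on raw projection
#' scores, before any winsorization or standardization. Any missing input
#' yields a missing composite.
#'
#' @param mast,vic,soc,phy Numeric vectors of the four dimension scores.
#' @return Numeric vector of composites.
#' @export
self_efficacy_composite <- function(mast, vic, soc, phy) {
  mast + vic + soc + phy
}

#' Coverage percentage of a scoring method
#'
#' Percentage of texts that receive a non-missing score: for the dictionary
#' baseline pass the `covered` flags, for projection scoring pass
#' `!missing`.
#'
#' @param covered Logical vector (NA counts as not covered).
#' @return Percent in \[0, 100\].
#' @export
coverage <- function(covered) {
  if (length(covered) == 0L) stop("coverage of an empty score set")
  100 * sum(covered, na.rm = TRUE) / length(covered)
}

#' Benchmark a scorer against ordinal labels
#'
#' Spearman rank correlation between scores and ordinal human-style labels,
#' the agreement statistic used to compare projection and dictionary scoring.
#' Uncovered dictionary scores can be treated as missing (dropped, the
#' default) or as zeros.
#'
#' @param scores Numeric scores.
#' @param labels Ordinal ground-truth labels.
#' @param covered Optional logical coverage flags.
#' @param uncovered `"drop"` or `"zero"`.
#' @return One-row tibble: `rho`, `n_used`, `coverage`.
#' @export
benchmark_agreement <- function(scores, labels, covered = NULL,
                                uncovered = c("drop", "zero")) {
  uncovered <- match.arg(uncovered)
  stopifnot(length(scores) == length(labels))
  if (is.null(covered)) covered <- !is.na(scores)
  cov_pct <- coverage(covered)
  if (uncovered == "drop") {
    keep <- covered & !is.na(scores)
    scores <- scores[keep]
    labels <- labels[keep]
  } else {
    scores[!covered | is.na(scores)] <- 0
  }
  rho <- stats::cor(scores, labels, method = "spearman")
  tibble::tibble(rho = rho, n_used = length(scores), coverage = cov_pct)
}
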