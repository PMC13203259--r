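#' Orthogonal Procrustes alignment of two embedding spaces
#'
#' Finds the orthogonal matrix (rotation, reflections permitted; no scaling or
#' translation) that minimises the Frobenius mismatch between the source
#' space's rows and the reference space's rows over a shared vocabulary,
#' solved via the singular value decomposition of the cross-covariance. All
#' source vectors are then carried into the reference coordinate system, so
#' period-specific spaces can be compared on a common basis.
#'
#' @param source,reference [embedding_space()] objects of equal dimension.
#' @param shared_vocab Tokens used to fit the transform; defaults to the
#'   vocabulary intersection restricted to the first `top_n` reference tokens
#'   (reference vocabulary order is taken as the frequency order).
#' @param top_n Cap on the default fitting vocabulary.
#' @return A `procrustes_alignment`: `rotation` (d x d orthogonal),
#'   `shared_vocab`, `residual` (Frobenius norm of the post-alignment
#'   mismatch), `aligned` (the rotated source space).
#' @export
procrustes_align <- function(source, reference, shared_vocab = NULL,
                             top_n = 5000) {
  stopifnot(inherits(source, "embedding_space"),
            inherits(reference, "embedding_space"))
  if (source$dimension != reference$dimension) {
    stop("spaces differ in dimension")
  }
  d <- source$dimension
  if (is.null(shared_vocab)) {
    ref_head <- utils::head(reference$vocabulary, top_n)
    shared_vocab <- ref_head[ref_head %in% source$vocabulary]
  } else {
    miss <- setdiff(shared_vocab, intersect(source$vocabulary,
                                            reference$vocabulary))
    if (length(miss)) {
      stop("shared_vocab token(s) absent from a space: ",
           paste(utils::head(miss, 5L), collapse = ", "))
    }
  }
  if (length(shared_vocab) == 0L) stop("empty shared vocabulary")
  if (length(shared_vocab) < d) {
    warning("only ", length(shared_vocab), " shared tokens for d = ", d,
            ": Procrustes fit may be ill-conditioned")
  }
  a <- source$vectors[shared_vocab, , drop = FALSE]
  b <- reference$vectors[shared_vocab, , drop = FALSE]
  sv <- svd(crossprod(a, b)) # d x d cross-covariance A'B
  rotation <- sv$u %*% t(sv$v)
  aligned_vectors <- source$vectors %*% rotation
  residual <- sqrt(sum((a %*% rotation - b)^2))
  aligned <- embedding_space(
    aligned_vectors, source$vocabulary,
    source_tag = paste0(source$source_tag, " (aligned)")
  )
  structure(
    list(rotation = rotation, shared_vocab = shared_vocab,
         residual = residual, aligned = aligned),
    class = "procrustes_alignment"
  )
}

#' @export
print.procrustes_alignment <- function(x, ...) {
  cat("<procrustes_alignment> fit on ", length(x$shared_vocab),
      " shared tokens, residual = ", format(x$residual, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Cross-period axis stability
#'
#' Cosine similarity between the construct axis built in an (aligned) period
#' space and the axis built in the reference space. Anchors are screened per
#' space, so period spaces missing some anchors still yield an axis as long
#' as both poles survive.
#'
#' @param period_space Aligned period [embedding_space()].
#' @param reference_space Reference [embedding_space()].
#' @param anchors Anchor tibble for one construct.
#' @param construct Construct name (optional when the table has one).
#' @return Cosine in \[-1, 1\].
#' @export
axis_stability <- function(period_space, reference_space, anchors,
                           construct = NULL) {
  ax_p <- build_axis(anchors, period_space, construct = construct)
  ax_r <- build_axis(anchors, reference_space, construct = construct)
  cosine_similarity(ax_p$axis, ax_r$axis)
}

#' Cross-period anchor rank-order consistency
#'
#' Spearman rank correlation between the anchor words' projections onto the
#' construct axis as computed in the (aligned) period space and in the
#' reference space. High values mean the internal ordering of anchor words
#' along the construct dimension is preserved even if the axis direction
#' drifts. Ties are handled by average ranks.
#'
#' @inheritParams axis_stability
#' @return One-row tibble: `rho`, `n_anchors_used`.
#' @export
anchor_rank_consistency <- function(period_space, reference_space, anchors,
                                    construct = NULL) {
  ax_p <- build_axis(anchors, period_space, construct = construct)
  ax_r <- build_axis(anchors, reference_space, construct = construct)
  words <- intersect(c(ax_p$anchors_pos, ax_p$anchors_neg),
                     c(ax_r$anchors_pos, ax_r$anchors_neg))
  if (length(words) < 3L) {
    stop("fewer than 3 anchors shared by both spaces")
  }
  proj_p <- as.numeric(embed_tokens(period_space, words)$vectors %*%
                         ax_p$axis)
  proj_r <- as.numeric(embed_tokens(reference_space, words)$vectors %*%
                         ax_r$axis)
  tibble::tibble(
    rho = stats::cor(proj_p, proj_r, method = "spearman"),
    n_anchors_used = length(words)
  )
}

#' Cross-temporal stability report
#'
#' Aligns each period space to the reference with [procrustes_align()] and
#' reports, per construct and period, the axis-stability cosine and the
#' anchor rank-order consistency.
#'
#' @param period_spaces Named list of period [embedding_space()] objects.
#' @param reference Reference [embedding_space()].
#' @param anchors Anchor tibble covering the constructs of interest.
#' @param shared_vocab,top_n Passed to [procrustes_align()].
#' @return Tibble: `construct`, `period`, `axis_cosine`, `anchor_rank_rho`,
#'   `n_anchors_used`, `alignment_residual`.
#' @export
stability_report <- function(period_spaces, reference, anchors,
                             shared_vocab = NULL, top_n = 5000) {
  anchors <- validate_anchors(anchors)
  purrr::imap_dfr(period_spaces, function(space, period) {
    al <- procrustes_align(space, reference, shared_vocab = shared_vocab,
                           top_n = top_n)
    purrr::map_dfr(unique(anchors$construct), function(cn) {
      cosv <- axis_stability(al$aligned, reference, anchors, construct = cn)
      rk <- anchor_rank_consistency(al$aligned, reference, anchors,
                                    construct = cn)
      tibble::tibble(
        construct = cn, period = period, axis_cosine = cosv,
        anchor_rank_rho = rk$rho, n_anchors_used = rk$n_anchors_used,
        alignment_residual = al$residual
      )
    })
  })
}
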