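#' Read an anchor-word dictionary
#'
#' Anchor dictionaries assign each theory-selected word to the positive or
#' negative pole of a named construct. Accepted formats: CSV with columns
#' `construct`, `pole` (`pos`/`neg`), `word`; or JSON mapping construct names
#' to `{"pos": [...], "neg": [...]}`.
#'
#' @param path File path (`.json` triggers the JSON reader).
#' @return Tibble with columns `construct`, `pole`, `word`.
#' @export
read_anchors <- function(path) {
  if (!file.exists(path)) stop("anchor file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    out <- purrr::imap_dfr(raw, function(poles, construct) {
      tibble::tibble(
        construct = construct,
        pole = rep(names(poles), lengths(poles)),
        word = unlist(poles, use.names = FALSE)
      )
    })
  } else {
    out <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  }
  validate_anchors(out)
}

validate_anchors <- function(anchors) {
  need <- c("construct", "pole", "word")
  if (!all(need %in% names(anchors))) {
    stop("anchor table must have columns: ", paste(need, collapse = ", "))
  }
  anchors <- tibble::as_tibble(anchors[need])
  if (!all(anchors$pole %in% c("pos", "neg"))) {
    stop("anchor pole must be \"pos\" or \"neg\"")
  }
  dup <- anchors |>
    dplyr::count(.data$construct, .data$pole, .data$word) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    stop("duplicate anchor word within a pole: ", dup$word[[1L]])
  }
  both <- anchors |>
    dplyr::distinct(.data$construct, .data$pole, .data$word) |>
    dplyr::count(.data$construct, .data$word) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(both)) {
    stop("anchor word assigned to both poles of one construct: ",
         both$word[[1L]])
  }
  anchors
}

#' Screen anchor candidates against an embedding vocabulary
#'
#' Keeps only in-vocabulary anchor words; out-of-vocabulary candidates are
#' dropped and tallied per construct and pole in the `"screening"` attribute.
#' Screening happens once, at axis-build time; axes built from the screened
#' set are immutable thereafter.
#'
#' @param anchors Anchor tibble (`construct`, `pole`, `word`).
#' @param space An [embedding_space()].
#' @return The retained anchor tibble with attribute `"screening"`: a tibble
#'   of `construct`, `pole`, `n_candidates`, `n_retained`, `dropped`
#'   (list column of dropped words).
#' @export
screen_anchors <- function(anchors, space) {
  anchors <- validate_anchors(anchors)
  anchors$in_vocab <- anchors$word %in% space$vocabulary
  report <- anchors |>
    dplyr::group_by(.data$construct, .data$pole) |>
    dplyr::summarise(
      n_candidates = dplyr::n(),
      n_retained = sum(.data$in_vocab),
      dropped = list(.data$word[!.data$in_vocab]),
      .groups = "drop"
    )
  empty <- dplyr::filter(report, .data$n_retained == 0L)
  if (nrow(empty)) {
    stop("every anchor of construct \"", empty$construct[[1L]],
         "\", pole \"", empty$pole[[1L]], "\" is out of vocabulary")
  }
  out <- anchors |>
    dplyr::filter(.data$in_vocab) |>
    dplyr::select(-"in_vocab")
  attr(out, "screening") <- report
  out
}

#' Pole prototype vector
#'
#' The prototype of a pole is the arithmetic mean (centroid) of its anchor
#' words' embedding vectors. All anchors must be in-vocabulary (screen first).
#'
#' @param words Character vector of anchor words for one pole.
#' @param space An [embedding_space()].
#' @return Length-d numeric vector.
#' @export
pole_prototype <- function(words, space) {
  if (length(words) == 0L) stop("empty anchor set")
  emb <- embed_tokens(space, words)
  if (!all(emb$in_vocab)) {
    stop("out-of-vocabulary anchor(s): ",
         paste(words[!emb$in_vocab], collapse = ", "),
         " (screen anchors before building prototypes)")
  }
  colMeans(emb$vectors)
}

#' Unit semantic-axis vector from two pole prototypes
#'
#' The axis points from the negative-pole centroid towards the positive-pole
#' centroid and is normalised to unit length, so projection scores are on a
#' common scale across constructs.
#'
#' @param proto_pos,proto_neg Length-d prototype vectors.
#' @return Unit-norm length-d vector.
#' @export
axis_from_prototypes <- function(proto_pos, proto_neg) {
  diffv <- proto_pos - proto_neg
  nrm <- sqrt(sum(diffv^2))
  if (nrm == 0) stop("identical pole prototypes: axis direction undefined")
  diffv / nrm
}

#' Build a bipolar construct axis
#'
#' Screens the construct's anchors against the space, forms the two pole
#' prototypes, and normalises their difference into the unit axis vector.
#'
#' @param anchors Anchor tibble restricted or restrictable to one construct.
#' @param space An [embedding_space()].
#' @param construct Construct name; defaults to the single construct present.
#' @return A `construct_axis` object: `construct`, `anchors_pos`,
#'   `anchors_neg`, `proto_pos`, `proto_neg`, `axis`, `dimension`.
#' @export
build_axis <- function(anchors, space, construct = NULL) {
  anchors <- validate_anchors(anchors)
  if (is.null(construct)) {
    cs <- unique(anchors$construct)
    if (length(cs) != 1L) {
      stop("anchor table has ", length(cs),
           " constructs; supply `construct`")
    }
    construct <- cs
  }
  anchors <- dplyr::filter(anchors, .data$construct == !!construct)
  if (nrow(anchors) == 0L) stop("no anchors for construct ", construct)
  screened <- screen_anchors(anchors, space)
  pos <- screened$word[screened$pole == "pos"]
  neg <- screened$word[screened$pole == "neg"]
  proto_pos <- pole_prototype(pos, space)
  proto_neg <- pole_prototype(neg, space)
  structure(
    list(
      construct = construct,
      anchors_pos = pos,
      anchors_neg = neg,
      proto_pos = proto_pos,
      proto_neg = proto_neg,
      axis = axis_from_prototypes(proto_pos, proto_neg),
      dimension = space$dimension
    ),
    class = "construct_axis"
  )
}

#' @export
print.construct_axis <- function(x, ...) {
  cat("<construct_axis> ", x$construct, ": ", length(x$anchors_pos),
      " pos / ", length(x$anchors_neg), " neg anchors, d = ", x$dimension,
      "\n", sep = "")
  invisible(x)
}

#' Build axes for every construct in an anchor table
#'
#' @param anchors Anchor tibble covering one or more constructs.
#' @param space An [embedding_space()].
#' @return Named list of `construct_axis` objects.
#' @export
build_axes <- function(anchors, space) {
  anchors <- validate_anchors(anchors)
  cs <- unique(anchors$construct)
  out <- lapply(cs, function(cn) build_axis(anchors, space, construct = cn))
  stats::setNames(out, cs)
}

mean_pairwise_cosine <- function(vectors) {
  n <- nrow(vectors)
  if (n < 2L) return(NA_real_)
  norms <- sqrt(rowSums(vectors^2))
  if (any(norms == 0)) stop("zero-norm anchor vector in pole diagnostics")
  unit <- vectors / norms
  sims <- tcrossprod(unit)
  mean(sims[upper.tri(sims)])
}

mean_cross_cosine <- function(a, b) {
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  if (any(na == 0) || any(nb == 0)) {
    stop("zero-norm anchor vector in pole diagnostics")
  }
  mean(tcrossprod(a / na, b / nb))
}

#' Semantic-space pole diagnostics for anchor sets
#'
#' For each construct, computes the average cosine similarity within the
#' positive pole, within the negative pole (unordered pairs, self-pairs
#' excluded), and between poles (all cross pairs). The anchor set shows the
#' expected bipolar separation when both within-pole averages exceed the
#' between-pole average. A single-word pole leaves its within value `NA` and
#' `passes` `NA`; the between-pole average is still reported.
#'
#' @param anchors Anchor tibble; screened against `space` internally.
#' @param space An [embedding_space()].
#' @return Tibble: `construct`, `within_pos`, `within_neg`, `between`,
#'   `passes`.
#' @export
pole_diagnostics <- function(anchors, space) {
  screened <- screen_anchors(validate_anchors(anchors), space)
  screened |>
    dplyr::group_by(.data$construct) |>
    dplyr::group_modify(function(df, key) {
      pos <- embed_tokens(space, df$word[df$pole == "pos"])$vectors
      neg <- embed_tokens(space, df$word[df$pole == "neg"])$vectors
      within_pos <- mean_pairwise_cosine(pos)
      within_neg <- mean_pairwise_cosine(neg)
      between <- mean_cross_cosine(pos, neg)
      tibble::tibble(
        within_pos = within_pos,
        within_neg = within_neg,
        between = between,
        passes = within_pos > between & within_neg > between
      )
    }) |>
    dplyr::ungroup()
}
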