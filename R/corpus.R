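#' Whitespace tokenizer
#'
#' Deterministic fallback segmenter: splits on runs of whitespace. Languages
#' without whitespace word boundaries (e.g. Chinese) should supply their own
#' segmentation function to [clean_and_tokenize()]; the cleaning rules are
#' applied after segmentation either way.
#'
#' @param text Character scalar.
#' @return Character vector of raw tokens (possibly empty).
#' @export
tokenize_whitespace <- function(text) {
  out <- strsplit(trimws(text), "\\s+")[[1L]]
  out[nzchar(out)]
}

# A token is "nonlinguistic" when it contains no letter in any script
# (Unicode letter class covers CJK).
is_nonlinguistic <- function(tokens) {
  !stringr::str_detect(tokens, "\\p{L}")
}

is_url <- function(tokens) {
  stringr::str_detect(tokens, stringr::fixed("://")) |
    stringr::str_starts(tokens, stringr::fixed("www."))
}

#' Clean and tokenize raw post text
#'
#' Segments `text` with the supplied tokenizer, then drops URLs (tokens
#' containing `://` or starting `www.`), @-mentions, nonlinguistic symbol
#' tokens (no letter in any script), one-character tokens, and any token in
#' the optional stop-word list. Relative token order is preserved; an empty
#' result is valid.
#'
#' @param text Character scalar (one document).
#' @param tokenizer Function mapping a string to a character vector of tokens.
#' @param stopwords Optional character vector of stop words removed after the
#'   structural rules (default none; supply a language-appropriate list).
#' @return Character vector of cleaned tokens.
#' @export
#' @examples
#' clean_and_tokenize("@coach see https://a.b great run ok",
#'                    stopwords = "see")
clean_and_tokenize <- function(text, tokenizer = tokenize_whitespace,
                               stopwords = character()) {
  toks <- tokenizer(text)
  if (length(toks) == 0L) return(character())
  keep <- !is_url(toks) &
    !stringr::str_starts(toks, stringr::fixed("@")) &
    !is_nonlinguistic(toks) &
    nchar(toks) > 1L &
    !toks %in% stopwords
  toks[keep]
}

#' Aggregate raw posts into user-week texts
#'
#' Buckets each user's posts into 7-day windows anchored at that user's
#' registration date (`week_index = floor(days since registration / 7)`, so
#' the registration week is week 0), concatenates post texts chronologically
#' with a single separating space, and tokenizes the weekly text. Weeks with
#' no posts produce no record.
#'
#' @param posts Data frame with columns `user_id`, `timestamp` (Date or
#'   POSIXct or ISO-8601 string), `text`.
#' @param registrations Data frame with columns `user_id`,
#'   `registration_date`; every poster must appear and no post may predate its
#'   user's registration.
#' @param tokenizer Segmentation function passed to [clean_and_tokenize()].
#' @return A tibble with one row per (user, week) holding `user_id`,
#'   `week_index`, `raw_text`, `tokens` (list column), `str_len` (characters
#'   of `raw_text`) and `valid_str_len` (number of cleaned tokens).
#' @export
aggregate_weeks <- function(posts, registrations,
                            tokenizer = tokenize_whitespace) {
  stopifnot(all(c("user_id", "timestamp", "text") %in% names(posts)),
            all(c("user_id", "registration_date") %in% names(registrations)))
  posts <- dplyr::mutate(
    posts,
    user_id = as.character(.data$user_id),
    .ts = as.POSIXct(.data$timestamp, tz = "UTC")
  )
  if (anyNA(posts$.ts)) stop("unparseable timestamp in posts")
  reg <- dplyr::transmute(
    registrations,
    user_id = as.character(.data$user_id),
    .reg = as.POSIXct(as.Date(.data$registration_date), tz = "UTC")
  )
  joined <- dplyr::inner_join(posts, reg, by = "user_id")
  if (nrow(joined) < nrow(posts)) {
    missing <- setdiff(posts$user_id, reg$user_id)
    stop("posts from users without registration info: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  days <- as.numeric(difftime(joined$.ts, joined$.reg, units = "days"))
  if (any(days < 0)) {
    bad <- joined$user_id[days < 0][1L]
    stop("post earlier than registration for user ", bad)
  }
  joined$week_index <- as.integer(floor(days / 7))
  out <- joined |>
    dplyr::arrange(.data$user_id, .data$.ts) |>
    dplyr::group_by(.data$user_id, .data$week_index) |>
    dplyr::summarise(raw_text = paste(.data$text, collapse = " "),
                     .groups = "drop")
  out |>
    dplyr::mutate(
      tokens = purrr::map(.data$raw_text, clean_and_tokenize,
                          tokenizer = tokenizer),
      str_len = nchar(.data$raw_text),
      valid_str_len = lengths(.data$tokens)
    )
}

#' Apply panel inclusion filters to user-week records
#'
#' Drops, in order: records whose cleaned token list is empty; all records of
#' users missing from the registration table (or with missing registration
#' date); and all records of users left with fewer than two valid weeks. The
#' per-reason removal counts are attached as the `"exclusions"` attribute and
#' printed by [exclusion_report()].
#'
#' @param records User-week tibble from [aggregate_weeks()] (needs `user_id`
#'   and `tokens` or `valid_str_len`).
#' @param user_info Data frame with `user_id` and `registration_date`; users
#'   whose `registration_date` is `NA` count as missing info.
#' @return The retained tibble, with an `"exclusions"` attribute
#'   (tibble of `reason`, `n_records`).
#' @export
filter_panel <- function(records, user_info) {
  stopifnot("user_id" %in% names(records))
  if (!"valid_str_len" %in% names(records)) {
    records$valid_str_len <- lengths(records$tokens)
  }
  records$user_id <- as.character(records$user_id)
  n0 <- nrow(records)

  keep <- records$valid_str_len > 0L
  n_empty <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  ok_users <- user_info$user_id[!is.na(user_info$registration_date)]
  keep <- records$user_id %in% as.character(ok_users)
  n_noreg <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  wk <- table(records$user_id)
  keep <- records$user_id %in% names(wk)[wk >= 2L]
  n_few <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  report <- tibble::tibble(
    reason = c("empty_text", "missing_registration", "fewer_than_two_weeks",
               "retained"),
    n_records = c(n_empty, n_noreg, n_few, nrow(records))
  )
  stopifnot(sum(report$n_records) == n0)
  attr(records, "exclusions") <- report
  records
}

#' Retrieve the exclusion report of a filtered panel
#'
#' @param records Output of [filter_panel()].
#' @return Tibble of `reason`, `n_records`.
#' @export
exclusion_report <- function(records) {
  rep <- attr(records, "exclusions")
  if (is.null(rep)) stop("no exclusion report: was filter_panel() applied?")
  rep
}

#' Read a raw-post corpus from TSV or JSONL
#'
#' @param path File path; `.jsonl`/`.ndjson` are read as one JSON object per
#'   line, anything else as tab-separated with a header. Required fields:
#'   `user_id`, `timestamp` (ISO-8601), `text`.
#' @return Tibble of raw posts.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) {
    out <- jsonlite::stream_in(file(path), verbose = FALSE)
    out <- tibble::as_tibble(out)
  } else {
    out <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  }
  need <- c("user_id", "timestamp", "text")
  if (!all(need %in% names(out))) {
    stop("corpus must have fields: ", paste(need, collapse = ", "))
  }
  out
}
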