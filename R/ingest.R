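#' Read a JSON-lines tweet stream
#'
#' One JSON object per line with fields `id`, `text`, `created_at`
#' (ISO-8601 UTC), `lang`, `retweeted`, `entities.urls` (list, possibly
#' empty), `user.id`, `user.description`, `user.location` and `place` — the
#' subset of classic platform metadata the pipeline uses. Malformed lines
#' are skipped with a warning and counted; more than 10% malformed lines is
#' treated as a probable schema mismatch and raises an error. Duplicate
#' tweet ids keep the first occurrence.
#'
#' @param path Path to the stream file.
#' @param study_window Optional length-2 `Date` vector; records outside the
#'   closed window are dropped with a count.
#' @return A tibble of tweet records: `tweet_id`, `text`, `created_at`
#'   (POSIXct, UTC), `lang`, `is_retweet`, `has_url`, `user_id`,
#'   `user_description`, `user_location`, `place`. The number of skipped
#'   malformed lines is in attribute `n_malformed`.
#' @export
read_tweet_stream <- function(path, study_window = NULL) {
  if (!file.exists(path)) stop("cannot read tweet stream: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- empty_tweet_tbl()
    attr(out, "n_malformed") <- 0L
    return(out)
  }
  parsed <- lapply(lines, function(l) {
    tryCatch(parse_tweet_json(l), error = function(e) NULL)
  })
  bad <- vapply(parsed, is.null, logical(1))
  if (any(bad)) {
    if (mean(bad) > 0.10)
      stop(sprintf("%d of %d lines malformed (>10%%): probable schema mismatch",
                   sum(bad), length(bad)))
    warning(sprintf("skipped %d malformed line(s)", sum(bad)))
  }
  out <- dplyr::bind_rows(parsed[!bad])
  dup <- duplicated(out$tweet_id)
  if (any(dup)) {
    warning(sprintf("dropped %d duplicate tweet id(s), keeping first occurrence",
                    sum(dup)))
    out <- out[!dup, ]
  }
  if (!is.null(study_window)) {
    d <- as.Date(out$created_at)
    keep <- d >= study_window[1] & d <= study_window[2]
    if (any(!keep)) message(sum(!keep), " record(s) outside the study window dropped")
    out <- out[keep, ]
  }
  attr(out, "n_malformed") <- sum(bad)
  out
}

parse_tweet_json <- function(line) {
  x <- jsonlite::fromJSON(line, simplifyVector = FALSE)
  ct <- as.POSIXct(x$created_at, tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ")
  if (is.na(ct)) stop("bad created_at")
  urls <- x$entities$urls
  tibble(
    tweet_id = as.character(x$id),
    text = as.character(x$text %||% ""),
    created_at = ct,
    lang = as.character(x$lang %||% "und"),
    is_retweet = isTRUE(x$retweeted),
    has_url = length(urls) > 0,
    user_id = as.character(x$user$id),
    user_description = as.character(x$user$description %||% ""),
    user_location = as.character(x$user$location %||% ""),
    place = as.character(x$place %||% "")
  )
}

empty_tweet_tbl <- function() {
  tibble(tweet_id = character(), text = character(),
         created_at = as.POSIXct(character(), tz = "UTC"), lang = character(),
         is_retweet = logical(), has_url = logical(), user_id = character(),
         user_description = character(), user_location = character(),
         place = character())
}

#' Apply the preprocessing filter cascade
#'
#' Records pass through a fixed stage order — language, retweet, URL,
#' lexicon match, spam user — and each removed record is attributed to
#' exactly one stage (the first that rejects it), so the report telescopes:
#' `input_count = output_count + sum(removals)`. Kept records are
#' English-language, original (not retweets), URL-free, contain at least
#' one mental-health lexicon term, and belong to users with at most
#' `spam_threshold` matching tweets in the stream (strictly more than the
#' threshold removes all of the user's matching tweets).
#'
#' @param records Tweet tibble from [read_tweet_stream()].
#' @param lexicon An [`mh_lexicon`][read_mh_lexicon].
#' @param spam_threshold Maximum mental-health-matching tweets per user
#'   before the user is treated as spam (default 1000).
#' @return A list:
#' \describe{
#'   \item{kept}{tibble of surviving records with a list-column
#'     `subgroups` of matched subgroup labels;}
#'   \item{report}{a `filter_report` (named integer vector as list) with
#'     fields `input_count`, `removed_non_english`, `removed_retweets`,
#'     `removed_url`, `removed_no_match`, `removed_spam_user`,
#'     `output_count`;}
#'   \item{eligible}{tibble of records surviving the language/retweet/URL
#'     stages — the denominator stream for proportion trends (carries
#'     `user_id`, `created_at`, geography fields).}
#' }
#' @export
apply_filters <- function(records, lexicon, spam_threshold = 1000) {
  stopifnot(spam_threshold >= 1)
  n0 <- nrow(records)
  en <- records$lang == "en"
  r1 <- records[en, ]
  rt <- r1$is_retweet
  r2 <- r1[!rt, ]
  url <- r2$has_url
  r3 <- r2[!url, ]
  subgroups <- match_subgroups_batch(r3$text, lexicon)
  hit <- lengths(subgroups) > 0
  r4 <- r3[hit, ]
  r4$subgroups <- subgroups[hit]
  per_user <- table(r4$user_id)
  spam_users <- names(per_user)[per_user > spam_threshold]
  spam <- r4$user_id %in% spam_users
  kept <- r4[!spam, ]
  report <- filter_report(
    input_count = n0,
    removed_non_english = sum(!en),
    removed_retweets = sum(rt),
    removed_url = sum(url),
    removed_no_match = sum(!hit),
    removed_spam_user = sum(spam),
    output_count = nrow(kept)
  )
  list(kept = kept, report = report, eligible = r3)
}

filter_report <- function(input_count, removed_non_english, removed_retweets,
                          removed_url, removed_no_match, removed_spam_user,
                          output_count) {
  rep <- list(input_count = as.integer(input_count),
              removed_non_english = as.integer(removed_non_english),
              removed_retweets = as.integer(removed_retweets),
              removed_url = as.integer(removed_url),
              removed_no_match = as.integer(removed_no_match),
              removed_spam_user = as.integer(removed_spam_user),
              output_count = as.integer(output_count))
  stopifnot(all(unlist(rep) >= 0))
  tele <- rep$input_count ==
    rep$output_count + rep$removed_non_english + rep$removed_retweets +
    rep$removed_url + rep$removed_no_match + rep$removed_spam_user
  if (!tele) stop("filter report does not telescope")
  structure(rep, class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Filter cascade report\n")
  cat(sprintf("  input:            %d\n", x$input_count))
  cat(sprintf("  - non-English:    %d\n", x$removed_non_english))
  cat(sprintf("  - retweets:       %d\n", x$removed_retweets))
  cat(sprintf("  - URL-bearing:    %d\n", x$removed_url))
  cat(sprintf("  - no lexicon hit: %d\n", x$removed_no_match))
  cat(sprintf("  - spam users:     %d\n", x$removed_spam_user))
  cat(sprintf("  kept:             %d\n", x$output_count))
  invisible(x)
}
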