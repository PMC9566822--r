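#' @useDynLib infovigil, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

MH_SUBGROUPS <- c("anxiety", "depression", "insomnia", "addiction")

#' Path to a packaged data file
#'
#' Convenience wrapper around [system.file()] for the lexicons, gazetteer and
#' stopword list shipped with the package.
#'
#' @param file File name under `extdata/`, e.g. `"mh_lexicon.tsv"`.
#' @return Absolute path to the file.
#' @export
infovigil_extdata <- function(file) {
  p <- system.file("extdata", file, package = "infovigil", mustWork = TRUE)
  p
}

norm_text <- function(x) {
  stringi::stri_trans_tolower(stringi::stri_trans_nfkc(x))
}

# word-boundary regex for a (possibly multi-word) term; internal whitespace
# matches any run of non-word characters so "panic  attack" still matches
term_regex <- function(term, case_insensitive = TRUE) {
  toks <- strsplit(trimws(term), "\\s+")[[1]]
  body <- paste(vapply(toks, function(t) stringi::stri_replace_all_regex(
    t, "([.\\\\+*?\\[\\]^$(){}=!<>|:#-])", "\\\\$1"), ""), collapse = "[^\\w]+")
  flag <- if (case_insensitive) "(?i)" else ""
  paste0(flag, "(?<![\\w])", body, "(?![\\w])")
}

#' Read a mental-health lexicon file
#'
#' The file is two-column tab-delimited text (`term<TAB>subgroup`), UTF-8,
#' with `#` comment lines. A term listed under several subgroups maps to the
#' union of those subgroups. Terms are normalized (NFKC, lower case,
#' whitespace collapsed) on load.
#'
#' @param path Path to the lexicon file; defaults to the representative
#'   lexicon shipped with the package.
#' @return An object of class `mh_lexicon`: a tibble with columns `term` and
#'   `subgroup`, one row per (term, subgroup) pair, plus compiled matching
#'   patterns in attributes.
#' @export
read_mh_lexicon <- function(path = infovigil_extdata("mh_lexicon.tsv")) {
  raw <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE, quote = "",
                           col.names = c("term", "subgroup"))
  raw$term <- gsub("\\s+", " ", trimws(norm_text(raw$term)))
  raw$subgroup <- trimws(raw$subgroup)
  if (any(raw$term == "")) stop("mh lexicon contains empty terms")
  bad <- setdiff(unique(raw$subgroup), MH_SUBGROUPS)
  if (length(bad)) stop("unknown subgroup(s) in lexicon: ", paste(bad, collapse = ", "))
  raw <- unique(raw)
  lex <- as_tibble(raw)
  terms <- unique(lex$term)
  # longest-first alternation so multi-word phrases win over their prefixes
  terms_ord <- terms[order(-nchar(terms))]
  pat <- paste0("(?i)(?<![\\w])(",
                paste(vapply(terms_ord, function(t) {
                  toks <- strsplit(t, " ", fixed = TRUE)[[1]]
                  paste(vapply(toks, function(x) stringi::stri_replace_all_regex(
                    x, "([.\\\\+*?\\[\\]^$(){}=!<>|:#-])", "\\\\$1"), ""),
                    collapse = "[^\\w]+")
                }, ""), collapse = "|"),
                ")(?![\\w])")
  sub_map <- split(lex$subgroup, lex$term)
  structure(lex, class = c("mh_lexicon", class(lex)),
            pattern = pat, sub_map = sub_map)
}

#' Match mental-health subgroups in a tweet text
#'
#' Case-insensitive word-boundary matching of the lexicon against one text:
#' a term matches only when flanked by non-word characters or string edges
#' (so a leading `#` hashtag counts as a boundary), and multi-word phrases
#' match as contiguous token sequences. A tweet may carry several subgroups.
#'
#' @param text A single character string.
#' @param lexicon An [`mh_lexicon`][read_mh_lexicon].
#' @return `NULL` if nothing matches; otherwise a list with elements
#'   `subgroups` (character vector, the union of matched terms' subgroups)
#'   and `matched_terms` (tibble `term`, `subgroup`, `start`, in text order).
#' @seealso [match_subgroups_batch()] for the vectorized form.
#' @export
match_subgroups <- function(text, lexicon) {
  stopifnot(length(text) == 1L, inherits(lexicon, "mh_lexicon"))
  hits <- match_hits(text, lexicon)[[1]]
  if (is.null(hits)) return(NULL)
  list(subgroups = unique(hits$subgroup), matched_terms = hits)
}

#' Match a vector of texts against the mental-health lexicon
#'
#' @param texts Character vector.
#' @param lexicon An [`mh_lexicon`][read_mh_lexicon].
#' @return A list of character vectors, one per text: the matched subgroups
#'   (`character(0)` for a non-matching text).
#' @export
match_subgroups_batch <- function(texts, lexicon) {
  lapply(match_hits(texts, lexicon), function(h) {
    if (is.null(h)) character(0) else unique(h$subgroup)
  })
}

# shared matcher: returns one tibble (term, subgroup, start) per text or NULL
match_hits <- function(texts, lexicon) {
  pat <- attr(lexicon, "pattern")
  sub_map <- attr(lexicon, "sub_map")
  ntexts <- norm_text(texts)
  locs <- stringi::stri_locate_all_regex(ntexts, pat, omit_no_match = TRUE)
  lapply(seq_along(texts), function(i) {
    lc <- locs[[i]]
    if (nrow(lc) == 0) return(NULL)
    matched <- stringi::stri_sub(ntexts[i], lc[, 1], lc[, 2])
    key <- gsub("[^a-z0-9']+", " ", matched)
    key <- trimws(key)
    rows <- lapply(seq_along(key), function(j) {
      sg <- sub_map[[key[j]]]
      if (is.null(sg)) return(NULL)
      tibble(term = key[j], subgroup = sg, start = lc[j, 1])
    })
    out <- dplyr::bind_rows(rows)
    if (nrow(out) == 0) NULL else out[order(out$start), ]
  })
}

#' Read a health-care-worker identification lexicon
#'
#' Tab-delimited `term<TAB>class<TAB>acronym` with classes
#' `occupation`/`degree`/`association`; `acronym = 1` marks short tokens
#' (e.g. `"MD"`) that must match exact-case as standalone tokens, guarding
#' against common-word and place-name collisions.
#'
#' @param path Path to the file; defaults to the packaged 47-term dictionary.
#' @return An object of class `hcw_lexicon` (tibble `term`, `class`,
#'   `acronym` plus compiled patterns).
#' @export
read_hcw_lexicon <- function(path = infovigil_extdata("hcw_lexicon.tsv")) {
  raw <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE, quote = "",
                           col.names = c("term", "class", "acronym"))
  raw$term <- gsub("\\s+", " ", trimws(raw$term))
  raw$acronym <- as.integer(raw$acronym) == 1L
  stopifnot(all(raw$class %in% c("occupation", "degree", "association")))
  by_class <- split(raw$term, raw$class)
  if (anyDuplicated(raw$term)) stop("duplicate terms in HCW lexicon")
  lex <- as_tibble(raw)
  long <- raw$term[!raw$acronym]
  long_pat <- paste0("(?i)(?<![\\w])(",
                     paste(vapply(long[order(-nchar(long))], term_body, ""),
                           collapse = "|"), ")(?![\\w])")
  acr <- raw$term[raw$acronym]
  acr_pat <- if (length(acr))
    paste0("(?<![\\w])(", paste(acr, collapse = "|"), ")(?![\\w])") else NA_character_
  structure(lex, class = c("hcw_lexicon", class(lex)),
            long_pattern = long_pat, acronym_pattern = acr_pat)
}

term_body <- function(t) {
  toks <- strsplit(t, " ", fixed = TRUE)[[1]]
  paste(vapply(toks, function(x) stringi::stri_replace_all_regex(
    x, "([.\\\\+*?\\[\\]^$(){}=!<>|:#-])", "\\\\$1"), ""), collapse = "[^\\w]+")
}

#' Identify health-care workers from profile descriptions
#'
#' A description is flagged when at least one lexicon keyword matches under
#' its class rule: ordinary terms case-insensitively at word boundaries,
#' short acronyms (e.g. `"MD"`, `"RN"`) as exact-case standalone tokens.
#' When `state_guard` is a gazetteer, an acronym hit that is also a US-state
#' abbreviation is discounted if a different state alias also appears in the
#' description (so "Road trip through MD and VA" is not a match).
#'
#' @param description Character vector of user profile descriptions
#'   (empty strings allowed).
#' @param lexicon An [`hcw_lexicon`][read_hcw_lexicon].
#' @param state_guard A [`state_gazetteer`][read_state_gazetteer] to enable
#'   the state-abbreviation co-occurrence guard, or `NULL` (default) to
#'   disable it.
#' @return Logical vector, `TRUE` where the user looks like a health-care
#'   worker.
#' @export
identify_hcw <- function(description, lexicon, state_guard = NULL) {
  stopifnot(inherits(lexicon, "hcw_lexicon"))
  description[is.na(description)] <- ""
  ndesc <- stringi::stri_trans_nfkc(description)
  long_hit <- stringi::stri_detect_regex(ndesc, attr(lexicon, "long_pattern"))
  acr_pat <- attr(lexicon, "acronym_pattern")
  if (is.na(acr_pat)) return(long_hit)
  acr_hits <- stringi::stri_extract_all_regex(ndesc, acr_pat, omit_no_match = TRUE)
  acr_ok <- vapply(seq_along(ndesc), function(i) {
    hits <- unique(acr_hits[[i]])
    if (length(hits) == 0) return(FALSE)
    if (is.null(state_guard)) return(TRUE)
    abbrs <- attr(state_guard, "abbr_alias")
    ambiguous <- hits %in% abbrs
    if (any(!ambiguous)) return(TRUE)
    # all acronym hits collide with state abbreviations: discount them when
    # a *different* state alias is present in the text
    others <- setdiff(find_state_aliases(ndesc[i], state_guard),
                      unname(attr(state_guard, "alias_map")[hits]))
    length(others) == 0
  }, logical(1))
  long_hit | acr_ok
}

#' Read a US state gazetteer
#'
#' Tab-delimited `alias<TAB>canonical` covering the 50 states; aliases are
#' full names (matched case-insensitively) and two-letter USPS abbreviations
#' (matched exact-case as standalone tokens).
#'
#' @param path Path to the file; defaults to the packaged gazetteer.
#' @return An object of class `state_gazetteer` (tibble `alias`,
#'   `canonical` plus compiled patterns).
#' @export
read_state_gazetteer <- function(path = infovigil_extdata("state_gazetteer.tsv")) {
  raw <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE, quote = "",
                           col.names = c("alias", "canonical"))
  if (anyDuplicated(raw$alias)) stop("duplicate aliases in gazetteer")
  is_abbr <- nchar(raw$alias) == 2L
  full <- raw$alias[!is_abbr]
  full_pat <- paste0("(?i)(?<![\\w])(",
                     paste(vapply(full[order(-nchar(full))], term_body, ""),
                           collapse = "|"), ")(?![\\w])")
  abbr <- raw$alias[is_abbr]
  abbr_pat <- paste0("(?<![\\w])(", paste(abbr, collapse = "|"), ")(?![\\w])")
  amap <- stats::setNames(raw$canonical, raw$alias)
  structure(as_tibble(raw), class = c("state_gazetteer", class(raw)),
            full_pattern = full_pat, abbr_pattern = abbr_pat,
            alias_map = amap, abbr_alias = abbr,
            canonical = unique(raw$canonical))
}

# canonical states whose alias occurs in one string (full names first)
find_state_aliases <- function(text, gaz) {
  full <- stringi::stri_extract_all_regex(text, attr(gaz, "full_pattern"),
                                          omit_no_match = TRUE)[[1]]
  abbr <- stringi::stri_extract_all_regex(text, attr(gaz, "abbr_pattern"),
                                          omit_no_match = TRUE)[[1]]
  amap <- attr(gaz, "alias_map")
  fl <- unname(amap[stringi::stri_trans_totitle(tolower(full))])
  fl <- fl[!is.na(fl)]
  unique(c(fl, unname(amap[abbr])))
}

#' Resolve the US state of a tweet
#'
#' The GPS-derived `place` field is the primary evidence: if it resolves to
#' a state the self-reported `location` is ignored; otherwise `location` is
#' tried; otherwise the result is `NA`. Resolution scans for gazetteer
#' aliases at word boundaries; full state names are preferred over
#' abbreviations, and on a full-name conflict the longest alias wins (so
#' "Kansas City, Missouri" resolves to Missouri).
#'
#' @param place,location Character vectors (recycled to common length);
#'   empty strings and `NA` are treated as absent.
#' @param gazetteer A [`state_gazetteer`][read_state_gazetteer].
#' @return Character vector of canonical state names, `NA` where
#'   unresolvable.
#' @export
resolve_state <- function(place, location, gazetteer) {
  n <- max(length(place), length(location))
  place <- rep_len(ifelse(is.na(place), "", place), n)
  location <- rep_len(ifelse(is.na(location), "", location), n)
  p <- resolve_one_field(place, gazetteer)
  need <- is.na(p)
  if (any(need)) p[need] <- resolve_one_field(location[need], gazetteer)
  p
}

resolve_one_field <- function(x, gaz) {
  out <- rep(NA_character_, length(x))
  nz <- which(nzchar(x))
  if (!length(nz)) return(out)
  tx <- stringi::stri_trans_nfkc(x[nz])
  amap <- attr(gaz, "alias_map")
  full <- stringi::stri_extract_all_regex(tx, attr(gaz, "full_pattern"),
                                          omit_no_match = TRUE)
  res <- vapply(full, function(f) {
    if (length(f) == 0) return(NA_character_)
    f <- f[order(-nchar(f))][1]           # longest full name wins
    unname(amap[stringi::stri_trans_totitle(tolower(f))])
  }, character(1))
  miss <- is.na(res)
  if (any(miss)) {
    ab <- stringi::stri_extract_all_regex(tx[miss], attr(gaz, "abbr_pattern"),
                                          omit_no_match = TRUE)
    res[miss] <- vapply(ab, function(a) {
      if (length(a) == 0) NA_character_ else unname(amap[a[1]])
    }, character(1))
  }
  out[nz] <- res
  out
}

#' Assign each user a single state or exclude multi-state users
#'
#' Users whose tweets resolve to one distinct state get that state; users
#' associated with more than one state are excluded from geographic
#' analyses (status `"excluded"`); users with no resolved tweet keep status
#' `"none"` and remain available to non-geographic analyses.
#'
#' @param resolved A tibble/data.frame with columns `user_id` and `state`
#'   (canonical state or `NA`), one row per tweet.
#' @return Tibble with columns `user_id`, `state` (`NA` unless status is
#'   `"assigned"`) and `status` (`"assigned"`, `"none"`, `"excluded"`).
#' @export
assign_user_state <- function(resolved) {
  stopifnot(all(c("user_id", "state") %in% names(resolved)))
  sp <- split(resolved$state, resolved$user_id)
  states <- lapply(sp, function(s) unique(s[!is.na(s)]))
  n <- lengths(states)
  tibble(
    user_id = names(sp),
    state = unname(ifelse(n == 1L,
                          vapply(states, function(s) s[1] %||% NA_character_,
                                 character(1)),
                          NA_character_)),
    status = dplyr::case_when(n == 0L ~ "none", n == 1L ~ "assigned",
                              TRUE ~ "excluded")
  )
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
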