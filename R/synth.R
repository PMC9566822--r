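#' Configuration for the synthetic tweet-corpus generator
#'
#' Bundles every knob of the generative model with validated defaults. The
#' defaults describe a desk-scale study: a ~10,000-tweet stream over
#' February-July 2020, twelve US states, four mental-health subgroups with
#' baseline per-tweet emission rates whose relative sizes follow the
#' depression > anxiety >> insomnia > addiction ordering seen in large
#' COVID-era corpora, a health-care-worker subpopulation with elevated
#' rates, planted post-lockdown step/slope changes in four states, spam
#' users, and URL/retweet/non-English nuisance records.
#'
#' @param n_users Number of regular users.
#' @param tweets_per_user Mean tweets per regular user (Poisson).
#' @param hcw_fraction Probability a user is a health-care worker.
#' @param geo_fraction Probability a user carries resolvable geography.
#' @param states Named numeric vector of state sampling probabilities
#'   (must sum to 1).
#' @param date_range Length-2 `Date` (or coercible) study window; must span
#'   at least 31 days so a +/-15-day policy window fits.
#' @param policy_dates Named vector state -> lockdown date.
#' @param baseline_rates 2 x 4 matrix of per-tweet subgroup emission
#'   probabilities, rows `general`/`hcw`, columns the four subgroups.
#' @param its_effects Named list state -> `c(delta=, gamma=)`: post-policy
#'   step and slope change of the daily mental-health proportion, in
#'   policy-relative coordinates (post-policy proportion =
#'   baseline + delta + gamma * days-since-policy, 1-based).
#' @param noise_sd Daily-proportion noise s.d. used by
#'   [generate_its_series()] defaults.
#' @param topic_params List: `k_true`, `vocab_size`, `doc_len_mean`,
#'   `alpha`, `beta` of the planted topic model.
#' @param hcw_topic_bias `c(topic=, factor=)`: one topic is emitted by
#'   health-care workers `factor` times as often as by the general
#'   population.
#' @param nuisance_fractions Named vector `url`, `retweet`, `non_english`
#'   (mutually exclusive per-tweet noise-type probabilities, summing with
#'   the implicit clean fraction to 1) and `multi_state_user` (fraction of
#'   geo users given two states).
#' @param spam_users Number of spam users, each emitting exactly
#'   `spam_threshold + 100` matching tweets.
#' @param spam_threshold Spam threshold the corpus is generated against.
#' @param seed Integer seed; a fixed seed makes regeneration byte-identical.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_users = 400,
                         tweets_per_user = 25,
                         hcw_fraction = 0.05,
                         geo_fraction = 0.9,
                         states = default_states(),
                         date_range = as.Date(c("2020-02-01", "2020-07-31")),
                         policy_dates = default_policy_dates(),
                         baseline_rates = default_baseline_rates(),
                         its_effects = default_its_effects(),
                         noise_sd = 0.003,
                         topic_params = list(k_true = 8, vocab_size = 300,
                                             doc_len_mean = 12, alpha = 0.5,
                                             beta = 0.1),
                         hcw_topic_bias = c(topic = 1, factor = 2),
                         nuisance_fractions = c(url = 0.15, retweet = 0.20,
                                                non_english = 0.10,
                                                multi_state_user = 0.02),
                         spam_users = 2,
                         spam_threshold = 50,
                         seed = 1L) {
  date_range <- as.Date(date_range)
  policy_dates <- stats::setNames(as.Date(policy_dates), names(policy_dates))
  cfg <- list(n_users = as.integer(n_users), tweets_per_user = tweets_per_user,
              hcw_fraction = hcw_fraction, geo_fraction = geo_fraction,
              states = states, date_range = date_range,
              policy_dates = policy_dates, baseline_rates = baseline_rates,
              its_effects = its_effects, noise_sd = noise_sd,
              topic_params = topic_params, hcw_topic_bias = hcw_topic_bias,
              nuisance_fractions = nuisance_fractions,
              spam_users = as.integer(spam_users),
              spam_threshold = as.integer(spam_threshold),
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

default_states <- function() {
  c(Michigan = 0.12, Pennsylvania = 0.12, Ohio = 0.10, `North Carolina` = 0.10,
    California = 0.08, Texas = 0.08, `New York` = 0.08, Florida = 0.08,
    Illinois = 0.06, Georgia = 0.06, Washington = 0.06, Arizona = 0.06)
}

default_policy_dates <- function() {
  c(Michigan = "2020-03-24", `North Carolina` = "2020-03-30",
    Ohio = "2020-03-23", Pennsylvania = "2020-04-01")
}

default_baseline_rates <- function() {
  m <- rbind(general = c(anxiety = 0.023, depression = 0.026,
                         insomnia = 0.0027, addiction = 0.0018),
             hcw = c(anxiety = 0.0248, depression = 0.0315,
                     insomnia = 0.0052, addiction = 0.0029))
  m
}

default_its_effects <- function() {
  list(Michigan = c(delta = -0.0214, gamma = 0.0020),
       `North Carolina` = c(delta = -0.0228, gamma = 0.0017),
       Ohio = c(delta = -0.0117, gamma = 0.0012),
       Pennsylvania = c(delta = 0.0288, gamma = -0.0012))
}

validate_synth_config <- function(cfg) {
  probs <- c(cfg$hcw_fraction, cfg$geo_fraction, cfg$states,
             cfg$nuisance_fractions, cfg$baseline_rates)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (abs(sum(cfg$states) - 1) > 1e-8) stop("state probabilities must sum to 1")
  nf <- cfg$nuisance_fractions
  if (sum(nf[c("url", "retweet", "non_english")]) >= 1)
    stop("noise fractions must sum to < 1 per tweet")
  span <- as.integer(diff(cfg$date_range))
  if (span < 30) stop("date_range must span at least 31 days")
  for (s in names(cfg$policy_dates)) {
    pd <- cfg$policy_dates[[s]]
    if (pd - 15 < cfg$date_range[1] || pd + 14 > cfg$date_range[2])
      stop("date span too short for the +/-15-day policy window of ", s)
  }
  if (!all(names(cfg$policy_dates) %in% names(cfg$states)))
    stop("policy_dates refer to states absent from the state list")
  tp <- cfg$topic_params
  if (tp$k_true < 2 || tp$vocab_size <= tp$k_true)
    stop("topic_params: need k_true >= 2 and vocab_size > k_true")
  if (tp$alpha <= 0 || tp$beta <= 0) stop("topic concentrations must be positive")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  invisible(cfg)
}

# independent per-component substreams from one global seed: adding a
# component never perturbs another component's draws
component_seed <- function(seed, id) {
  as.integer((as.numeric(seed) %% 65011) * 33013 + id * 271) %% 2147483647L
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Generate a synthetic tweet stream with ground truth
#'
#' Draws users (cohort, state, geography, spam), a planted topic model,
#' per-tweet mental-health subgroup emissions whose daily probability
#' follows the configured post-policy step/slope changes, and nuisance
#' records (URL-bearing, retweets, non-English, multi-state users). The
#' stream is written as time-sorted JSON lines; the returned ground truth
#' records every planted label so downstream stages can be verified
#' exactly.
#'
#' @param config A [synth_config()].
#' @param stream_path Output path for the JSON-lines stream.
#' @param lexicon Mental-health lexicon used to plant matching terms
#'   (defaults to the packaged one).
#' @param truth_path Optional path; when non-`NULL` the ground truth is
#'   also serialized there as JSON.
#' @return Invisibly, a list of class `synth_truth`: `tweets` (tibble with
#'   per-tweet planted labels: user, date, state, cohort, noise type,
#'   subgroups, topic, removal stage), `users`, `phi` (true topic-word
#'   matrix, rows summing to 1), `topic_weights` per cohort, `its_effects`,
#'   `spam_user_ids`, `multi_state_user_ids`, and `stage_counts` (the
#'   expected filter report).
#' @export
generate_corpus <- function(config, stream_path,
                            lexicon = read_mh_lexicon(),
                            truth_path = NULL) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)

  users <- synth_users(config)
  topics <- synth_topics(config)
  tw <- synth_tweets(config, users, topics, lexicon)

  # removal stage per tweet (first failing stage in the fixed cascade order)
  tw$removal_stage <- with(tw, ifelse(
    noise == "non_english", "non_english",
    ifelse(noise == "retweet", "retweet",
    ifelse(noise == "url", "url",
    ifelse(!signal & !spam, "no_match",
    ifelse(spam, "spam_user", "kept"))))))
  stage_counts <- list(
    input_count = nrow(tw),
    removed_non_english = sum(tw$removal_stage == "non_english"),
    removed_retweets = sum(tw$removal_stage == "retweet"),
    removed_url = sum(tw$removal_stage == "url"),
    removed_no_match = sum(tw$removal_stage == "no_match"),
    removed_spam_user = sum(tw$removal_stage == "spam_user"),
    output_count = sum(tw$removal_stage == "kept"))

  ord <- order(tw$created_at, tw$tweet_id)
  tw <- tw[ord, ]
  write_jsonl_stream(tw, stream_path)

  truth <- structure(list(
    tweets = tw[, c("tweet_id", "user_id", "date", "state", "cohort", "noise",
                    "spam", "signal", "subgroups", "topic", "removal_stage")],
    users = users, phi = topics$phi, topic_weights = topics$weights,
    its_effects = config$its_effects, policy_dates = config$policy_dates,
    spam_user_ids = users$user_id[users$spam],
    multi_state_user_ids = users$user_id[users$multi_state],
    stage_counts = stage_counts, config = config), class = "synth_truth")
  if (!is.null(truth_path)) write_truth_json(truth, truth_path)
  invisible(truth)
}

synth_users <- function(cfg) {
  set.seed(component_seed(cfg$seed, 1L))
  n <- cfg$n_users
  hcw <- stats::runif(n) < cfg$hcw_fraction
  state <- sample(names(cfg$states), n, replace = TRUE, prob = cfg$states)
  geo <- stats::runif(n) < cfg$geo_fraction
  multi <- geo & stats::runif(n) < cfg$nuisance_fractions[["multi_state_user"]]
  alt <- vapply(seq_len(n), function(i) {
    if (!multi[i]) return(NA_character_)
    sample(setdiff(names(cfg$states), state[i]), 1)
  }, character(1))
  hcw_lex <- read_hcw_lexicon()
  occ <- hcw_lex$term[hcw_lex$class == "occupation"]
  desc <- ifelse(hcw, paste0(sample(occ, n, replace = TRUE), " fighting covid"),
                 "just a regular account")
  desc[!hcw & stats::runif(n) < 0.3] <- ""
  spam_n <- cfg$spam_users
  tibble(
    user_id = c(sprintf("u%05d", seq_len(n)), sprintf("spam%03d", seq_len(spam_n))),
    cohort = c(ifelse(hcw, "hcw", "general"), rep("general", spam_n)),
    state = c(state, rep(NA_character_, spam_n)),
    alt_state = c(alt, rep(NA_character_, spam_n)),
    has_geo = c(geo, rep(FALSE, spam_n)),
    multi_state = c(multi, rep(FALSE, spam_n)),
    spam = c(rep(FALSE, n), rep(TRUE, spam_n)),
    description = c(desc, rep("", spam_n)))
}

synth_topics <- function(cfg) {
  set.seed(component_seed(cfg$seed, 2L))
  tp <- cfg$topic_params
  phi <- rdirichlet(tp$k_true, rep(tp$beta, tp$vocab_size))
  vocab <- sprintf("covw%03d", seq_len(tp$vocab_size))
  w_gen <- rep(1, tp$k_true)
  w_hcw <- w_gen
  bias_topic <- as.integer(cfg$hcw_topic_bias[["topic"]])
  w_hcw[bias_topic] <- w_hcw[bias_topic] * cfg$hcw_topic_bias[["factor"]]
  list(phi = phi, vocab = vocab,
       weights = list(general = w_gen / sum(w_gen), hcw = w_hcw / sum(w_hcw)))
}

# expected daily mental-health proportion for a (cohort, state, day);
# post-policy days get the planted step/slope change, proportionally
# scaling every subgroup's emission rate
its_multiplier <- function(cfg, state, date) {
  base <- 1 - prod(1 - cfg$baseline_rates["general", ])
  m <- rep(1, length(date))
  if (is.na(state) || !state %in% names(cfg$policy_dates)) return(m)
  eff <- cfg$its_effects[[state]]
  if (is.null(eff)) return(m)
  rel <- as.integer(date - cfg$policy_dates[[state]]) + 1L  # 1-based post index
  post <- rel >= 1L
  target <- base + ifelse(post, eff[["delta"]] + eff[["gamma"]] * rel, 0)
  target <- pmin(pmax(target, 1e-4), 0.95)
  ifelse(post, target / base, 1)
}

synth_tweets <- function(cfg, users, topics, lexicon) {
  set.seed(component_seed(cfg$seed, 3L))
  days <- seq(cfg$date_range[1], cfg$date_range[2], by = "day")
  reg <- users[!users$spam, ]
  n_tw <- stats::rpois(nrow(reg), cfg$tweets_per_user)
  rows <- rep(seq_len(nrow(reg)), n_tw)
  n <- length(rows)
  tw <- tibble(user_id = reg$user_id[rows], cohort = reg$cohort[rows],
               state = reg$state[rows], alt_state = reg$alt_state[rows],
               multi_state = reg$multi_state[rows], has_geo = reg$has_geo[rows],
               spam = FALSE)
  tw$date <- sample(days, n, replace = TRUE)

  # spam users: exactly spam_threshold + 100 matching tweets each
  if (cfg$spam_users > 0) {
    sp <- users[users$spam, ]
    m <- cfg$spam_threshold + 100L
    sp_rows <- rep(seq_len(nrow(sp)), each = m)
    tw_sp <- tibble(user_id = sp$user_id[sp_rows], cohort = "general",
                    state = NA_character_, alt_state = NA_character_,
                    multi_state = FALSE, has_geo = FALSE, spam = TRUE,
                    date = sample(days, length(sp_rows), replace = TRUE))
    tw <- dplyr::bind_rows(tw, tw_sp)
  }
  n <- nrow(tw)

  # mutually exclusive noise types; spam tweets stay clean so the spam
  # filter's effect is deterministic
  nf <- cfg$nuisance_fractions
  u <- stats::runif(n)
  noise <- rep("none", n)
  b1 <- nf[["non_english"]]; b2 <- b1 + nf[["retweet"]]; b3 <- b2 + nf[["url"]]
  noise[u < b1] <- "non_english"
  noise[u >= b1 & u < b2] <- "retweet"
  noise[u >= b2 & u < b3] <- "url"
  noise[tw$spam] <- "none"
  tw$noise <- noise

  # subgroup emissions: independent Bernoulli per subgroup, rates scaled by
  # the state's post-policy multiplier on post-policy days
  rates <- cfg$baseline_rates
  subs <- colnames(rates)
  mult <- vapply(seq_len(n), function(i)
    its_multiplier(cfg, tw$state[i], tw$date[i]), numeric(1))
  hit <- matrix(FALSE, n, length(subs), dimnames = list(NULL, subs))
  for (s in subs) {
    r <- rates[cbind(tw$cohort, s)]
    hit[, s] <- stats::runif(n) < pmin(r * mult, 1)
  }
  # spam tweets always match: give them one subgroup draw by global share
  share <- colSums(rates)[subs] / sum(rates)
  sp_idx <- which(tw$spam)
  if (length(sp_idx)) {
    pick <- sample(seq_along(subs), length(sp_idx), replace = TRUE, prob = share)
    hit[cbind(sp_idx, pick)] <- TRUE
  }
  tw$signal <- rowSums(hit) > 0

  # planted topic per tweet (single-membership draw from cohort weights)
  wts <- topics$weights
  k <- cfg$topic_params$k_true
  topic <- integer(n)
  for (co in names(wts)) {
    idx <- which(tw$cohort == co)
    topic[idx] <- sample.int(k, length(idx), replace = TRUE, prob = wts[[co]])
  }
  tw$topic <- topic

  # ground-truth subgroup sets from the terms actually planted in the text
  sub_map <- attr(lexicon, "sub_map")
  terms_by_sub <- lapply(subs, function(s) unique(lexicon$term[lexicon$subgroup == s]))
  names(terms_by_sub) <- subs

  len <- pmax(stats::rpois(n, cfg$topic_params$doc_len_mean), 3L)
  vocab <- topics$vocab
  phi <- topics$phi
  stop_pool <- c("the", "and", "of", "to", "in")
  texts <- character(n)
  sub_sets <- vector("list", n)
  for (i in seq_len(n)) {
    toks <- vocab[sample.int(length(vocab), len[i], replace = TRUE,
                             prob = phi[topic[i], ])]
    toks <- append(toks, sample(stop_pool, 2), after = 1)
    planted <- character(0)
    for (s in subs[hit[i, ]]) planted <- c(planted, sample(terms_by_sub[[s]], 1))
    sub_sets[[i]] <- if (length(planted))
      sort(unique(unlist(sub_map[planted]))) else character(0)
    body <- paste(c(toks, planted), collapse = " ")
    if (tw$noise[i] == "retweet") body <- paste("RT", body)
    if (tw$noise[i] == "url") body <- paste(body, "https://t.co/abc123")
    texts[i] <- body
  }
  tw$text <- texts
  tw$subgroups <- sub_sets
  # noise overrides ground-truth signal only through the removal stage;
  # 'signal' tracks whether a lexicon term is present in the text
  tw$signal <- lengths(sub_sets) > 0

  tw$lang <- ifelse(tw$noise == "non_english",
                    sample(c("es", "fr", "de"), n, replace = TRUE), "en")
  tw$is_retweet <- tw$noise == "retweet"
  tw$has_url <- tw$noise == "url"
  tw$created_at <- as.POSIXct(tw$date, tz = "UTC") + round(stats::runif(n, 0, 86399))

  # geography strings: place for geo users (multi-state users alternate a
  # second state on ~1/3 of their tweets), location mildly informative
  place <- rep("", n)
  geo_idx <- which(tw$has_geo & !is.na(tw$state))
  use_alt <- tw$multi_state & stats::runif(n) < 1 / 3 & !is.na(tw$alt_state)
  st <- ifelse(use_alt, tw$alt_state, tw$state)
  place[geo_idx] <- paste0("Somewhere, ", st[geo_idx])
  tw$place <- place
  tw$location <- ifelse(!is.na(tw$state) & stats::runif(n) < 0.5,
                        tw$state, "planet earth")

  desc_map <- stats::setNames(users$description, users$user_id)
  tw$description <- unname(desc_map[tw$user_id])
  tw$tweet_id <- sprintf("t%07d", seq_len(n))
  tw
}

write_jsonl_stream <- function(tw, path) {
  lines <- vapply(seq_len(nrow(tw)), function(i) {
    jsonlite::toJSON(list(
      id = tw$tweet_id[i], text = tw$text[i],
      created_at = format(tw$created_at[i], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      lang = tw$lang[i], retweeted = tw$is_retweet[i],
      entities = list(urls = if (tw$has_url[i]) list("https://t.co/abc123") else list()),
      user = list(id = tw$user_id[i], description = tw$description[i],
                  location = tw$location[i]),
      place = tw$place[i]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
}

write_truth_json <- function(truth, path) {
  tw <- truth$tweets
  tw$date <- as.character(tw$date)
  obj <- list(tweets = tw, users = truth$users, phi = truth$phi,
              topic_weights = truth$topic_weights,
              its_effects = truth$its_effects,
              policy_dates = as.character(truth$policy_dates),
              stage_counts = truth$stage_counts)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
}

#' Generate a daily-proportion series from the segmented-regression model
#'
#' The series follows `y_t = beta0 + beta1 t + delta P_t + gamma t P_t +
#' e_t` with time index `t = 1, ..., n_pre + n_post`, policy indicator
#' `P_t = 0` for the first `n_pre` days and 1 afterwards, and i.i.d.
#' Gaussian noise. With `sigma = 0` an ordinary least-squares fit of the
#' same design recovers the four coefficients exactly.
#'
#' @param beta0,beta1 Pre-policy level and slope.
#' @param delta,gamma Policy step change and slope change.
#' @param n_pre,n_post Days before/after the policy (each >= 2).
#' @param sigma Noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @param start_date First date of the series.
#' @return Tibble `date`, `t`, `policy`, `proportion`; the policy date
#'   (first `P = 1` day) is in attribute `policy_date`.
#' @export
generate_its_series <- function(beta0, beta1, delta, gamma, n_pre, n_post,
                                sigma, seed = 1L,
                                start_date = as.Date("2020-03-01")) {
  if (n_pre < 2 || n_post < 2) stop("n_pre and n_post must each be >= 2")
  if (sigma < 0) stop("sigma must be non-negative")
  set.seed(as.integer(seed))
  n <- n_pre + n_post
  t <- seq_len(n)
  p <- c(rep(0L, n_pre), rep(1L, n_post))
  mu <- beta0 + beta1 * t + delta * p + gamma * t * p
  y <- mu + stats::rnorm(n, 0, sigma)
  out <- tibble(date = start_date + t - 1L, t = t, policy = p, proportion = y)
  attr(out, "policy_date") <- start_date + n_pre
  out
}

#' Generate a corpus from the LDA generative process
#'
#' Topic-word rows are drawn from a symmetric Dirichlet(`beta`), each
#' document's topic mixture from Dirichlet(`alpha`), document lengths from
#' a Poisson, and every token by sampling a topic then a word — the full
#' mixed-membership generative model.
#'
#' @param k_true Number of topics (>= 2).
#' @param vocab_size Vocabulary size (> `k_true`).
#' @param n_docs Number of documents.
#' @param alpha,beta Positive Dirichlet concentrations.
#' @param seed Integer seed.
#' @param doc_len_mean Mean document length (Poisson, floored at 1).
#' @param phi Optional K x V matrix of topic-word rows to use instead of
#'   Dirichlet draws (rows must sum to 1) — handy for planting disjoint
#'   topics.
#' @return List: `docs` (list of integer token vectors, 1-based vocabulary
#'   indices), `vocab` (token strings), `phi` (true K x V topic-word
#'   matrix), `theta` (true doc-topic mixtures).
#' @export
generate_lda_corpus <- function(k_true, vocab_size, n_docs, alpha, beta,
                                seed = 1L, doc_len_mean = 60, phi = NULL) {
  if (k_true < 2) stop("k_true must be >= 2")
  if (vocab_size <= k_true) stop("vocab_size must exceed k_true")
  if (alpha <= 0 || beta <= 0) stop("concentrations must be positive")
  set.seed(as.integer(seed))
  if (is.null(phi)) phi <- rdirichlet(k_true, rep(beta, vocab_size))
  stopifnot(nrow(phi) == k_true, ncol(phi) == vocab_size,
            max(abs(rowSums(phi) - 1)) < 1e-9)
  theta <- rdirichlet(n_docs, rep(alpha, k_true))
  lens <- pmax(stats::rpois(n_docs, doc_len_mean), 1L)
  docs <- lapply(seq_len(n_docs), function(d) {
    z <- sample.int(k_true, lens[d], replace = TRUE, prob = theta[d, ])
    vapply(z, function(k) sample.int(vocab_size, 1, prob = phi[k, ]), integer(1))
  })
  list(docs = docs, vocab = sprintf("w%04d", seq_len(vocab_size)),
       phi = phi, theta = theta)
}
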