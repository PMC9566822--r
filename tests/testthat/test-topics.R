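test_that("preprocessing removes stopwords, numbers and symbols; builds bigrams", {
  out <- suppressMessages(preprocess_for_topics(
    c("The 19 !!!", "panic buying panic buying", "panic buying here",
      "covid numbers 123 rising"),
    bigram_min_count = 2))
  expect_identical(out$n_dropped, 1L)                 # "The 19 !!!" is emptied
  expect_true("panic_buying" %in% out$vocab$token)
  expect_false(any(grepl("^[0-9]+$", out$vocab$token)))
  expect_false("the" %in% out$vocab$token)
  # indices are dense 1..V and doc frequencies are right
  expect_identical(out$vocab$index, seq_len(nrow(out$vocab)))
  expect_identical(out$vocab$doc_freq[out$vocab$token == "panic_buying"], 2L)
  expect_error(suppressMessages(preprocess_for_topics(c("the a of", "123 !!"))),
               "empty")
})

test_that("synthetic tweet text preprocesses to the planted vocabulary", {
  cfg <- small_synth_config(seed = 19)
  f <- withr::local_tempfile(fileext = ".jsonl")
  generate_corpus(cfg, f, lexicon = mh_lex)
  rec <- read_tweet_stream(f)
  clean <- rec[rec$lang == "en" & !rec$is_retweet & !rec$has_url, ]
  out <- suppressMessages(preprocess_for_topics(clean$text, bigram_min_count = 1e9))
  # every non-lexicon token is a planted topic word (stopwords are removed,
  # and URLs never reach this stage)
  planted <- sprintf("covw%03d", seq_len(cfg$topic_params$vocab_size))
  lex_words <- unique(unlist(strsplit(mh_lex$term, " ")))
  expect_true(all(out$vocab$token %in% c(planted, lex_words)))
})

test_that("degenerate one-word corpora and fixed seeds behave deterministically", {
  docs <- rep(list(rep(1L, 3)), 4)
  st <- fit_lda(docs, K = 2, n_iter = 50, seed = 5, vocab_size = 1)
  phi <- lda_phi(st)
  expect_true(all(phi[, 1] > 1 - 1e-6))
  st2 <- fit_lda(docs, K = 2, n_iter = 50, seed = 5, vocab_size = 1)
  expect_identical(st$z, st2$z)
  expect_error(fit_lda(list(1L), K = 5, n_iter = 1), "token count")
  expect_error(fit_lda(list(integer(0), 1L), K = 2), "empty")
})

test_that("count invariants hold after sampling sweeps", {
  set.seed(3)
  corp <- generate_lda_corpus(3, 30, 40, alpha = 0.5, beta = 0.2, seed = 3,
                              doc_len_mean = 15)
  for (iters in c(1, 7)) {
    st <- fit_lda(corp$docs, K = 3, n_iter = iters, seed = 9, vocab_size = 30)
    expect_true(check_lda_state(st, corp$docs))
    expect_identical(sum(st$n_k), st$n_tokens)
  }
})

test_that("perplexity matches closed forms and brute-force summation", {
  # single-word vocabulary: perplexity exactly 1
  docs <- rep(list(rep(1L, 4)), 3)
  st <- fit_lda(docs, K = 2, n_iter = 20, seed = 1, vocab_size = 1)
  expect_equal(as.numeric(lda_perplexity(st, docs)), 1, tolerance = 1e-12)
  # uniform model over V words on uniform heldout: perplexity V
  V <- 7
  st_unif <- fit_lda(list(1:V), K = 2, n_iter = 1, seed = 1, vocab_size = V)
  st_unif$n_kw <- matrix(0L, 2, V)   # beta-only: phi exactly uniform
  st_unif$n_k <- c(0L, 0L)
  expect_equal(as.numeric(lda_perplexity(st_unif, list(1:V, rep(3L, 5)))),
               V, tolerance = 1e-9)
  # brute force: perplexity = exp(-sum(log p)/N) with p = theta %*% phi
  corp <- generate_lda_corpus(2, 12, 6, alpha = 1, beta = 1, seed = 8,
                              doc_len_mean = 8)
  st3 <- fit_lda(corp$docs[1:4], K = 2, n_iter = 30, seed = 2, vocab_size = 12)
  hold <- corp$docs[5:6]
  got <- lda_perplexity(st3, hold, fold_in_iter = 40, seed = 77)
  phi <- lda_phi(st3)
  set.seed(77)
  m_dk <- infovigil:::gibbs_fold_in_cpp(unlist(hold) - 1L,
                                        rep(0:1, lengths(hold)), 2L, phi,
                                        st3$alpha, 40L)
  theta <- (m_dk + st3$alpha) / (rowSums(m_dk) + 2 * st3$alpha)
  ll <- 0
  for (d in 1:2) for (w in hold[[d]]) ll <- ll + log(sum(theta[d, ] * phi[, w]))
  expect_equal(as.numeric(got), exp(-ll / sum(lengths(hold))),
               tolerance = 1e-8)
  expect_error(lda_perplexity(st3, list()), "heldout")
})

test_that("UMass coherence matches an independent pairwise-count oracle", {
  set.seed(5)
  corp <- generate_lda_corpus(3, 15, 30, alpha = 0.7, beta = 0.3, seed = 5,
                              doc_len_mean = 10)
  st <- fit_lda(corp$docs, K = 3, n_iter = 30, seed = 6, vocab_size = 15)
  top_n <- 4
  got <- umass_coherence(st, corp$docs, top_n = top_n)
  phi <- lda_phi(st)
  per_topic <- numeric(3)
  for (k in 1:3) {
    top <- order(phi[k, ], decreasing = TRUE)[1:top_n]
    vals <- c()
    for (i in 1:(top_n - 1)) for (j in (i + 1):top_n) {
      Dj <- sum(vapply(corp$docs, function(d) top[j] %in% d, logical(1)))
      Dij <- sum(vapply(corp$docs, function(d)
        top[i] %in% d && top[j] %in% d, logical(1)))
      vals <- c(vals, log((Dij + 1) / max(Dj, 1)))
    }
    per_topic[k] <- mean(vals)
  }
  expect_equal(as.numeric(got), mean(per_topic), tolerance = 1e-10)
})

test_that("coherence boundary cases follow the closed forms", {
  # terms 1 and 2 always co-occur in all D docs: each pair gives log((D+1)/D)
  docs <- rep(list(c(1L, 2L)), 10)
  st <- fit_lda(docs, K = 2, n_iter = 10, seed = 1, vocab_size = 2)
  got <- umass_coherence(st, docs, top_n = 2)
  expect_equal(as.numeric(got), log(11 / 10), tolerance = 1e-12)
  # never co-occurring top terms: each pair contributes log(1 / D(w_j))
  docs2 <- c(rep(list(rep(1L, 2)), 6), rep(list(rep(2L, 2)), 4))
  st2 <- fit_lda(docs2, K = 2, n_iter = 60, seed = 10, vocab_size = 2)
  phi2 <- lda_phi(st2)
  got2 <- attr(umass_coherence(st2, docs2, top_n = 2), "per_topic")
  for (k in 1:2) {
    top <- order(phi2[k, ], decreasing = TRUE)[1:2]
    Dj <- if (top[2] == 1) 6 else 4
    expect_equal(got2[k], log(1 / Dj), tolerance = 1e-12)
  }
})

test_that("collapsed sampler agrees with a naive uncollapsed sampler", {
  # 3-doc, 5-word toy corpus: compare long-run topic-word marginals after
  # greedy matching (topic labels are not identified)
  docs <- list(c(1L, 1L, 2L, 2L, 1L), c(4L, 5L, 5L, 4L, 4L), c(1L, 2L, 3L))
  K <- 2; V <- 5; alpha <- 0.5; beta <- 0.5
  st <- fit_lda(docs, K, alpha, beta, n_iter = 4000, seed = 31, vocab_size = V)
  phi_c <- lda_phi(st)
  phi_n <- oracle_naive_lda(docs, K, V, alpha, beta, n_iter = 1500, seed = 32)
  phi_n <- phi_n + beta
  phi_n <- phi_n / rowSums(phi_n)
  sim <- greedy_cosine_match(phi_c, phi_n)
  expect_gt(sim, 0.9)
})

test_that("training log-likelihood improves with more sweeps", {
  corp <- generate_lda_corpus(4, 60, 80, alpha = 0.3, beta = 0.05, seed = 14,
                              doc_len_mean = 25)
  loglik <- function(st, docs) {
    phi <- lda_phi(st); theta <- lda_theta(st)
    ll <- 0
    for (d in seq_along(docs))
      ll <- ll + sum(log(theta[d, , drop = FALSE] %*% phi[, docs[[d]]]))
    ll
  }
  wins <- vapply(1:5, function(s) {
    short <- fit_lda(corp$docs, K = 4, n_iter = 10, seed = s, vocab_size = 60)
    long <- fit_lda(corp$docs, K = 4, n_iter = 400, seed = s, vocab_size = 60)
    loglik(long, corp$docs) > loglik(short, corp$docs)
  }, logical(1))
  expect_true(all(wins))
})

test_that("a planted five-topic corpus is recovered by the sampler", {
  corp <- generate_lda_corpus(5, 150, 400, alpha = 0.3, beta = 0.05,
                              seed = 51, doc_len_mean = 40)
  st <- fit_lda(corp$docs, K = 5, n_iter = 500, seed = 52, vocab_size = 150)
  sim <- greedy_cosine_match(lda_phi(st), corp$phi)
  expect_gt(sim, 0.8)
})

test_that("topic selection returns the only candidate on a singleton grid", {
  corp <- generate_lda_corpus(3, 40, 60, alpha = 0.5, beta = 0.2, seed = 61,
                              doc_len_mean = 15)
  sel <- select_num_topics(corp$docs, k_grid = 5, seeds = 1, n_iter = 30,
                           fold_in_iter = 10)
  expect_identical(sel$k, 5L)
  expect_identical(nrow(sel$diagnostics), 1L)
})

test_that("topic shares are normalized per period and track assignments", {
  docs <- rep(list(c(1L, 1L), c(2L, 2L)), 5)
  st <- fit_lda(docs, K = 2, n_iter = 100, seed = 3, vocab_size = 2)
  dates <- rep(as.Date("2020-04-01") + c(0, 40), 5)
  out <- topic_share_series(st, dates, granularity = "month")
  sums <- tapply(out$share, out$period_start, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # all docs assigned to one topic: share 1 every period
  st1 <- structure(list(K = 2, alpha = 0.1,
                        n_dk = matrix(c(3L, 0L), 6, 2, byrow = TRUE)),
                   class = "lda_state")
  out1 <- topic_share_series(st1, as.Date("2020-05-01") + c(0, 0, 0, 40, 40, 40),
                             "month")
  expect_identical(out1$topic, c(1L, 1L))
  expect_identical(out1$share, c(1, 1))
})
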