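#' Read the packaged English stopword list
#'
#' A pinned snapshot of a standard English stopword list, shipped with the
#' package so preprocessing never drifts with upstream list changes.
#'
#' @param path Path to a one-token-per-line file with `#` comments.
#' @return Character vector of stopwords.
#' @export
read_stopwords <- function(path = infovigil_extdata("stopwords_en.txt")) {
  x <- readLines(path, encoding = "UTF-8")
  x <- trimws(x[!startsWith(x, "#")])
  x[nzchar(x)]
}

#' Tokenize texts for topic modelling
#'
#' Lower-cases (NFKC-normalized), splits on non-alphanumeric characters,
#' and removes stopwords and pure-number tokens (symbols disappear in the
#' split). Adjacent surviving token pairs occurring at least
#' `bigram_min_count` times corpus-wide are merged into single
#' `a_b` tokens (greedy left-to-right, non-overlapping). Documents left
#' empty are dropped with a count.
#'
#' @param texts Character vector of document texts.
#' @param doc_ids Optional document ids (default positions as character).
#' @param stopwords Stopword list (default the packaged snapshot).
#' @param bigram_min_count Minimum corpus frequency for an adjacent pair to
#'   become a bigram token.
#' @return List: `docs` (list of integer token-index vectors, all
#'   nonempty), `vocab` (tibble `token`, `index`, `doc_freq`, indices dense
#'   `1..V`), `doc_ids` (ids of surviving docs), `n_dropped` (empty docs
#'   removed). All documents empty is an error.
#' @export
preprocess_for_topics <- function(texts, doc_ids = as.character(seq_along(texts)),
                                  stopwords = read_stopwords(),
                                  bigram_min_count = 20) {
  stopifnot(length(texts) == length(doc_ids))
  low <- stringi::stri_trans_tolower(stringi::stri_trans_nfkc(texts))
  tok <- stringi::stri_split_regex(low, "[^a-z0-9']+", omit_empty = TRUE)
  tok <- lapply(tok, function(t) {
    t <- t[!stringi::stri_detect_regex(t, "^[0-9]+$")]
    t <- t[!stringi::stri_detect_regex(t, "^'+$")]
    t[!(t %in% stopwords)]
  })
  # corpus-wide bigram counts over adjacent surviving tokens
  big <- unlist(lapply(tok, function(t) {
    if (length(t) < 2) return(character(0))
    paste(t[-length(t)], t[-1], sep = "_")
  }))
  if (length(big)) {
    bt <- table(big)
    keep_bi <- names(bt)[bt >= bigram_min_count]
  } else keep_bi <- character(0)
  if (length(keep_bi)) {
    tok <- lapply(tok, merge_bigrams, keep_bi = keep_bi)
  }
  nonempty <- lengths(tok) > 0
  n_dropped <- sum(!nonempty)
  if (!any(nonempty)) stop("all documents empty after cleaning")
  if (n_dropped) message(n_dropped, " empty document(s) dropped after cleaning")
  tok <- tok[nonempty]
  types <- sort(unique(unlist(tok)))
  idx <- stats::setNames(seq_along(types), types)
  docs <- lapply(tok, function(t) unname(idx[t]))
  doc_freq <- table(factor(unlist(lapply(tok, unique)), levels = types))
  list(docs = docs,
       vocab = tibble(token = types, index = seq_along(types),
                      doc_freq = as.integer(doc_freq)),
       doc_ids = doc_ids[nonempty], n_dropped = n_dropped)
}

merge_bigrams <- function(t, keep_bi) {
  if (length(t) < 2) return(t)
  out <- character(0)
  i <- 1L
  while (i <= length(t)) {
    if (i < length(t) && paste(t[i], t[i + 1], sep = "_") %in% keep_bi) {
      out <- c(out, paste(t[i], t[i + 1], sep = "_"))
      i <- i + 2L
    } else {
      out <- c(out, t[i])
      i <- i + 1L
    }
  }
  out
}

#' Fit LDA by collapsed Gibbs sampling
#'
#' The document and topic distributions are integrated out and each
#' token's topic assignment is resampled from its full conditional for
#' `n_iter` full sweeps. A fixed seed yields an identical chain.
#'
#' @param docs List of integer token vectors (1-based vocabulary indices),
#'   e.g. from [preprocess_for_topics()].
#' @param K Number of topics (>= 2).
#' @param alpha,beta Symmetric Dirichlet hyperparameters; defaults
#'   `50 / K` and `0.01`.
#' @param n_iter Number of Gibbs sweeps (>= 1).
#' @param seed Integer seed.
#' @param vocab_size Vocabulary size `V`; defaults to the largest index
#'   seen.
#' @return An object of class `lda_state`: `K`, `V`, `alpha`, `beta`,
#'   `z` (list of 1-based topic assignments per token), count matrices
#'   `n_kw` (K x V), `n_dk` (D x K), `n_k`, `n_tokens`, `seed`.
#' @export
fit_lda <- function(docs, K, alpha = 50 / K, beta = 0.01, n_iter = 1000,
                    seed = 1L, vocab_size = NULL) {
  stopifnot(K >= 2, n_iter >= 1, alpha > 0, beta > 0)
  lens <- lengths(docs)
  if (any(lens == 0)) stop("empty documents are not allowed in the fit")
  n_tok <- sum(lens)
  if (K > n_tok) stop("K exceeds the total token count")
  tokens <- unlist(docs, use.names = FALSE)
  if (is.null(vocab_size)) vocab_size <- max(tokens)
  stopifnot(all(tokens >= 1), all(tokens <= vocab_size))
  doc <- rep(seq_along(docs), lens)
  set.seed(as.integer(seed))
  z0 <- sample.int(K, n_tok, replace = TRUE)
  res <- gibbs_lda_cpp(tokens - 1L, doc - 1L, length(docs), K, vocab_size,
                       alpha, beta, n_iter, z0 - 1L)
  z <- split(res$z + 1L, doc)
  names(z) <- NULL
  structure(list(K = K, V = vocab_size, alpha = alpha, beta = beta,
                 z = z, n_kw = res$n_kw, n_dk = res$n_dk, n_k = res$n_k,
                 n_tokens = n_tok, seed = as.integer(seed)),
            class = "lda_state")
}

#' Continue a collapsed Gibbs chain
#'
#' Runs further sweeps from an existing state using the current R RNG
#' stream (no reseeding), so running `fit_lda(n_iter = a)` followed by
#' `resume_lda(n_iter = b)` reproduces `fit_lda(n_iter = a + b)` exactly.
#' Useful for checkpointing and for verifying count invariants along the
#' chain.
#'
#' @param state An [`lda_state`][fit_lda].
#' @param docs The token corpus the state was fitted on.
#' @param n_iter Additional sweeps.
#' @return The updated `lda_state`.
#' @export
resume_lda <- function(state, docs, n_iter) {
  stopifnot(inherits(state, "lda_state"), n_iter >= 1)
  lens <- lengths(docs)
  tokens <- unlist(docs, use.names = FALSE)
  doc <- rep(seq_along(docs), lens)
  z0 <- unlist(state$z, use.names = FALSE)
  stopifnot(length(z0) == length(tokens))
  res <- gibbs_lda_cpp(tokens - 1L, doc - 1L, length(docs), state$K, state$V,
                       state$alpha, state$beta, n_iter, z0 - 1L)
  z <- split(res$z + 1L, doc)
  names(z) <- NULL
  state$z <- z
  state$n_kw <- res$n_kw
  state$n_dk <- res$n_dk
  state$n_k <- res$n_k
  state
}

#' Check the count-consistency invariants of an LDA state
#'
#' Verifies that the sufficient statistics agree with the token-level
#' assignments: topic-word rows sum to the per-topic totals, doc-topic
#' rows sum to document lengths, all counts are non-negative, and the
#' count matrices can be rebuilt from `z` exactly.
#'
#' @param state An [`lda_state`][fit_lda].
#' @param docs The token corpus the state was fitted on.
#' @return `TRUE` invisibly; inconsistencies raise an error.
#' @export
check_lda_state <- function(state, docs) {
  stopifnot(inherits(state, "lda_state"))
  if (any(state$n_kw < 0) || any(state$n_dk < 0) || any(state$n_k < 0))
    stop("negative counts")
  if (!all(rowSums(state$n_kw) == state$n_k)) stop("n_kw rows != n_k")
  if (!all(rowSums(state$n_dk) == lengths(docs))) stop("n_dk rows != doc lengths")
  n_kw <- matrix(0L, state$K, state$V)
  n_dk <- matrix(0L, length(docs), state$K)
  for (d in seq_along(docs)) {
    for (j in seq_along(docs[[d]])) {
      k <- state$z[[d]][j]; w <- docs[[d]][j]
      n_kw[k, w] <- n_kw[k, w] + 1L
      n_dk[d, k] <- n_dk[d, k] + 1L
    }
  }
  if (!all(n_kw == state$n_kw)) stop("n_kw inconsistent with z")
  if (!all(n_dk == state$n_dk)) stop("n_dk inconsistent with z")
  invisible(TRUE)
}

#' Posterior-mean topic-word matrix
#' @param state An [`lda_state`][fit_lda].
#' @return K x V matrix with rows summing to 1.
#' @export
lda_phi <- function(state) {
  (state$n_kw + state$beta) / (state$n_k + state$V * state$beta)
}

#' Posterior-mean doc-topic matrix
#' @param state An [`lda_state`][fit_lda].
#' @return D x K matrix with rows summing to 1.
#' @export
lda_theta <- function(state) {
  len <- rowSums(state$n_dk)
  (state$n_dk + state$alpha) / (len + state$K * state$alpha)
}

#' Held-out perplexity of a fitted topic model
#'
#' Out-of-vocabulary tokens are dropped (and counted); each held-out
#' document's topic mixture is estimated by a fixed number of fold-in
#' Gibbs sweeps with the topic-word distributions frozen at their
#' posterior means, and perplexity is `exp(-mean per-token log-likelihood)`
#' under the resulting mixture.
#'
#' @param state An [`lda_state`][fit_lda].
#' @param heldout List of integer token vectors.
#' @param fold_in_iter Fold-in sweeps (default 50).
#' @param seed Integer seed for the fold-in chain.
#' @return Perplexity (a single number >= 1); the count of dropped
#'   out-of-vocabulary tokens is in attribute `n_oov`.
#' @export
lda_perplexity <- function(state, heldout, fold_in_iter = 50, seed = 1L) {
  stopifnot(inherits(state, "lda_state"))
  n_before <- sum(lengths(heldout))
  heldout <- lapply(heldout, function(d) d[d >= 1 & d <= state$V])
  n_oov <- n_before - sum(lengths(heldout))
  keep <- lengths(heldout) > 0
  heldout <- heldout[keep]
  if (!length(heldout)) stop("empty heldout set")
  phi <- lda_phi(state)
  tokens <- unlist(heldout, use.names = FALSE)
  doc <- rep(seq_along(heldout), lengths(heldout))
  set.seed(as.integer(seed))
  m_dk <- gibbs_fold_in_cpp(tokens - 1L, doc - 1L, length(heldout), phi,
                            state$alpha, fold_in_iter)
  theta <- (m_dk + state$alpha) / (rowSums(m_dk) + state$K * state$alpha)
  probs <- rowSums(theta[doc, , drop = FALSE] * t(phi)[tokens, , drop = FALSE])
  out <- exp(-mean(log(probs)))
  attr(out, "n_oov") <- n_oov
  out
}

#' UMass topic coherence
#'
#' For each topic's `top_n` most probable terms, averages
#' `log((D(w_i, w_j) + 1) / D(w_j))` over ordered term pairs `i < j`, where
#' `D` counts documents of the training corpus containing the term(s);
#' topic coherences are then averaged. A top term absent from the corpus is
#' handled by the +1 smoothing (its document count is floored at 1 in the
#' denominator), never an error.
#'
#' @param state An [`lda_state`][fit_lda].
#' @param docs Training corpus (list of integer token vectors).
#' @param top_n Number of top terms per topic (>= 2).
#' @return Mean coherence over topics; per-topic values in attribute
#'   `per_topic`.
#' @export
umass_coherence <- function(state, docs, top_n = 10) {
  stopifnot(top_n >= 2)
  phi <- lda_phi(state)
  doc_sets <- lapply(docs, unique)
  all_terms <- unique(unlist(lapply(seq_len(state$K), function(k)
    order(phi[k, ], decreasing = TRUE)[seq_len(top_n)])))
  # incidence matrix docs x terms restricted to the needed terms
  inc <- vapply(all_terms, function(w)
    vapply(doc_sets, function(s) w %in% s, logical(1)),
    logical(length(docs)))
  colnames(inc) <- as.character(all_terms)
  dcount <- colSums(inc)
  per_topic <- vapply(seq_len(state$K), function(k) {
    top <- order(phi[k, ], decreasing = TRUE)[seq_len(top_n)]
    vals <- c()
    for (i in seq_len(top_n - 1)) {
      for (j in seq((i + 1), top_n)) {
        wi <- as.character(top[i]); wj <- as.character(top[j])
        co <- sum(inc[, wi] & inc[, wj])
        vals <- c(vals, log((co + 1) / max(dcount[wj], 1)))
      }
    }
    mean(vals)
  }, numeric(1))
  out <- mean(per_topic)
  attr(out, "per_topic") <- per_topic
  out
}

#' Select the number of topics by perplexity and coherence
#'
#' For each candidate `K` (and each seed) the corpus is split into a
#' training and held-out part, a model is fitted, and held-out perplexity
#' plus UMass coherence are recorded. Averaging over seeds, the selected
#' `K` maximizes coherence among candidates whose perplexity lies within a
#' tolerance band of the grid minimum — a rule that prefers interpretable
#' models among the predictively adequate ones. The full diagnostic table
#' is returned so any other rule can be applied.
#'
#' @param docs List of integer token vectors.
#' @param k_grid Candidate topic counts (nonempty).
#' @param seeds Integer seeds to average over.
#' @param n_iter Gibbs sweeps per fit.
#' @param heldout_frac Fraction of documents held out for perplexity.
#' @param perplexity_tol Relative tolerance band above the minimum mean
#'   perplexity within which candidates stay eligible.
#' @param alpha,beta Priors (`alpha = NULL` means `50 / K` per candidate).
#' @param top_n Top terms per topic for coherence.
#' @param fold_in_iter Fold-in sweeps for held-out perplexity.
#' @return List: `k` (selected), `diagnostics` (tibble `K`, `perplexity`,
#'   `coherence`, `eligible`).
#' @export
select_num_topics <- function(docs, k_grid, seeds = 1:3, n_iter = 300,
                              heldout_frac = 0.1, perplexity_tol = 0.05,
                              alpha = NULL, beta = 0.01, top_n = 10,
                              fold_in_iter = 30) {
  stopifnot(length(k_grid) >= 1)
  k_grid <- sort(unique(as.integer(k_grid)))
  V <- max(unlist(docs))
  res <- expand.grid(K = k_grid, seed = seeds)
  res$perplexity <- NA_real_
  res$coherence <- NA_real_
  for (i in seq_len(nrow(res))) {
    sd <- res$seed[i]; K <- res$K[i]
    set.seed(as.integer(sd))
    n_hold <- max(1L, floor(length(docs) * heldout_frac))
    hold_idx <- sample(seq_along(docs), n_hold)
    train <- docs[-hold_idx]; hold <- docs[hold_idx]
    a <- if (is.null(alpha)) 50 / K else alpha
    st <- fit_lda(train, K, alpha = a, beta = beta, n_iter = n_iter,
                  seed = sd, vocab_size = V)
    res$perplexity[i] <- as.numeric(lda_perplexity(st, hold, fold_in_iter,
                                                   seed = sd))
    res$coherence[i] <- as.numeric(umass_coherence(st, train, top_n))
  }
  diag <- dplyr::summarise(dplyr::group_by(as_tibble(res), .data$K),
                           perplexity = mean(.data$perplexity),
                           coherence = mean(.data$coherence), .groups = "drop")
  diag$eligible <- diag$perplexity <= min(diag$perplexity) * (1 + perplexity_tol)
  elig <- diag[diag$eligible, ]
  k_sel <- elig$K[which.max(elig$coherence)]
  list(k = as.integer(k_sel), diagnostics = diag)
}

#' Topic-share time series
#'
#' Each document is assigned its modal topic (argmax of smoothed doc-topic
#' counts, lowest index on ties) and per-period topic shares are computed
#' over documents; shares sum to 1 within each period. Periods with no
#' documents are omitted.
#'
#' @param state An [`lda_state`][fit_lda].
#' @param doc_dates `Date` vector, one per fitted document.
#' @param granularity `"day"`, `"week"` or `"month"`.
#' @return Tibble `period_start`, `topic`, `n_docs`, `share`.
#' @export
topic_share_series <- function(state, doc_dates,
                               granularity = c("month", "week", "day")) {
  granularity <- match.arg(granularity)
  doc_dates <- as.Date(doc_dates)
  stopifnot(length(doc_dates) == nrow(state$n_dk), !any(is.na(doc_dates)))
  modal <- max.col(state$n_dk + state$alpha, ties.method = "first")
  df <- tibble(period_start = period_start(doc_dates, granularity),
               topic = modal)
  counts <- dplyr::count(df, .data$period_start, .data$topic, name = "n_docs")
  totals <- dplyr::count(df, .data$period_start, name = "n_total")
  out <- dplyr::left_join(counts, totals, by = "period_start")
  out$share <- out$n_docs / out$n_total
  out$n_total <- NULL
  out[order(out$period_start, out$topic), ]
}

#' Ranked top terms of each topic
#'
#' @param state An [`lda_state`][fit_lda].
#' @param vocab Vocabulary tibble from [preprocess_for_topics()] (or a
#'   character vector indexed by token id).
#' @param top_n Terms per topic.
#' @return Tibble `topic`, `rank`, `term`, `probability`.
#' @export
top_terms <- function(state, vocab, top_n = 20) {
  phi <- lda_phi(state)
  tokens <- if (is.character(vocab)) vocab else vocab$token
  dplyr::bind_rows(lapply(seq_len(state$K), function(k) {
    ord <- order(phi[k, ], decreasing = TRUE)[seq_len(min(top_n, state$V))]
    tibble(topic = k, rank = seq_along(ord), term = tokens[ord],
           probability = phi[k, ord])
  }))
}
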