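# Shared fixtures and independent oracles used across test files.

mh_lex <- read_mh_lexicon()
hcw_lex <- read_hcw_lexicon()
gaz <- read_state_gazetteer()

# small, fast synthetic configuration reused by several tests
small_synth_config <- function(seed = 11, ...) {
  synth_config(n_users = 120, tweets_per_user = 15, spam_users = 1,
               spam_threshold = 20, seed = seed, ...)
}

# --- independent oracles -----------------------------------------------------

# brute-force lexicon matcher: per-term regex scan with boundary check,
# no shared code with the packaged alternation matcher
oracle_match_subgroups <- function(text, lexicon) {
  txt <- tolower(stringi::stri_trans_nfkc(text))
  hits <- character(0)
  for (i in seq_len(nrow(lexicon))) {
    term <- lexicon$term[i]
    pat <- paste0("(?<![[:alnum:]_])",
                  gsub("([^a-zA-Z0-9' ])", "\\\\\\1", term),
                  "(?![[:alnum:]_])")
    pat <- gsub(" ", "[^[:alnum:]_]+", pat, fixed = TRUE)
    if (grepl(pat, txt, perl = TRUE)) hits <- c(hits, lexicon$subgroup[i])
  }
  sort(unique(hits))
}

# independently coded Wilson interval: invert the score test numerically
oracle_wilson <- function(k, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  score <- function(p0) (k / n - p0) / sqrt(p0 * (1 - p0) / n)
  low <- if (k == 0) 0 else
    uniroot(function(p) score(p) - z, c(1e-12, min(k / n, 1 - 1e-12)),
            tol = 1e-14)$root
  high <- if (k == n) 1 else
    uniroot(function(p) score(p) + z, c(max(k / n, 1e-12), 1 - 1e-12),
            tol = 1e-14)$root
  c(low = low, high = high)
}

# textbook OLS via normal equations with explicit inference formulas
oracle_ols <- function(X, y) {
  XtX <- crossprod(X)
  est <- solve(XtX, crossprod(X, y))
  res <- y - X %*% est
  n <- nrow(X); p <- ncol(X)
  s2 <- sum(res^2) / (n - p)
  se <- sqrt(diag(s2 * solve(XtX)))
  tstat <- est / se
  pval <- 2 * pt(abs(tstat), n - p, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  rss <- sum(res^2)
  f <- ((tss - rss) / (p - 1)) / (rss / (n - p))
  fp <- pf(f, p - 1, n - p, lower.tail = FALSE)
  list(est = drop(est), se = se, t = drop(tstat), p = drop(pval),
       f = f, f_p = fp)
}

# full enumeration of all 2^n sign assignments of the signed-rank test;
# works on doubled midranks so all comparisons are exact integer comparisons
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r2 <- as.integer(round(2 * rank(abs(d))))
  W2 <- sum(r2[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0L, 1L)), n)))
  sums <- as.vector(signs %*% r2)
  p_le <- sum(sums <= W2) / 2^n
  p_ge <- sum(sums >= W2) / 2^n
  list(W = W2 / 2, p = min(1, 2 * min(p_le, p_ge)))
}

# uncollapsed (naive) Gibbs sampler for LDA: samples phi and theta
# explicitly each sweep; used only as a distributional cross-check on toy
# corpora
oracle_naive_lda <- function(docs, K, V, alpha, beta, n_iter, seed) {
  set.seed(seed)
  rdir <- function(a) { x <- rgamma(length(a), a); x / sum(x) }
  tokens <- unlist(docs)
  doc <- rep(seq_along(docs), lengths(docs))
  z <- sample.int(K, length(tokens), replace = TRUE)
  nkw_sum <- matrix(0, K, V)
  n_samples <- 0
  for (it in seq_len(n_iter)) {
    n_kw <- matrix(0, K, V); n_dk <- matrix(0, length(docs), K)
    for (i in seq_along(tokens)) {
      n_kw[z[i], tokens[i]] <- n_kw[z[i], tokens[i]] + 1
      n_dk[doc[i], z[i]] <- n_dk[doc[i], z[i]] + 1
    }
    phi <- t(apply(n_kw, 1, function(r) rdir(r + beta)))
    theta <- t(apply(n_dk, 1, function(r) rdir(r + alpha)))
    for (i in seq_along(tokens)) {
      p <- phi[, tokens[i]] * theta[doc[i], ]
      z[i] <- sample.int(K, 1, prob = p)
    }
    if (it > n_iter / 2) {   # burn-in: first half
      n_kw <- matrix(0, K, V)
      for (i in seq_along(tokens))
        n_kw[z[i], tokens[i]] <- n_kw[z[i], tokens[i]] + 1
      nkw_sum <- nkw_sum + n_kw
      n_samples <- n_samples + 1
    }
  }
  nkw_sum / n_samples
}

# greedy one-to-one matching of estimated to true topic rows by cosine
# similarity; returns the mean matched cosine
greedy_cosine_match <- function(phi_est, phi_true) {
  cs <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  K <- nrow(phi_true)
  sim <- outer(seq_len(nrow(phi_est)), seq_len(K),
               Vectorize(function(i, j) cs(phi_est[i, ], phi_true[j, ])))
  total <- 0
  for (step in seq_len(min(nrow(phi_est), K))) {
    best <- which(sim == max(sim, na.rm = TRUE), arr.ind = TRUE)[1, ]
    total <- total + sim[best[1], best[2]]
    sim[best[1], ] <- NA
    sim[, best[2]] <- NA
  }
  total / min(nrow(phi_est), K)
}
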