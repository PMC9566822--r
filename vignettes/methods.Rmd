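---
title: "Methods: mental-health infoveillance from tweet streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mental-health infoveillance from tweet streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`infovigil` implements a complete infoveillance pipeline for tracking
public mental-health signals in a social-media stream: a raw tweet stream
is filtered, tweets mentioning mental-health terms are identified in four
symptom subgroups (anxiety, depression, insomnia, addiction), health-care
workers (HCW) are recognized from profile descriptions, geography is
resolved to US states, and the labelled stream feeds four analyses —
proportion trends, topic modelling, cohort comparison, and interrupted
time series (ITS) around lockdown dates. Because real platform data cannot
be redistributed, the package ships a seeded synthetic corpus generator
with planted, recoverable effects; every statistical claim the test suite
makes is a claim about recovering those planted quantities.

# The filter cascade

Records pass five stages in a fixed order: language (keep `lang == "en"`),
retweet, URL-bearing (from the metadata entity list, with a regex fallback
unnecessary for the shipped generator), mental-health lexicon match, and
spam users. A record is attributed to the *first* stage that rejects it,
so the report telescopes: the input count equals the output count plus the
per-stage removals. Spam users are users with strictly more than
`spam_threshold` (default 1000) lexicon-matching tweets in the analysis
window; exactly the threshold is kept. Duplicate tweet ids keep the first
occurrence. Because the language, retweet and URL predicates are
record-local, permuting those stages changes only the attribution, never
the total kept count — a property the suite tests.

# Lexicon matching

Matching is case-insensitive at word boundaries after NFKC normalization:
a term matches only when flanked by non-word characters or string edges,
so "mad" never fires inside "nomad" and a leading `#` hashtag counts as a
boundary. Multi-word phrases match as contiguous token sequences across
any non-word separator. A tweet may carry several subgroups, and
subgroup-level numerators therefore sum above the all-subgroup numerator
by design. The packaged mental-health lexicon is a representative,
swappable list organized into the four subgroups; the HCW dictionary has
47 keywords in three classes (occupation, degree, association), with
short acronyms such as `MD` requiring exact-case standalone tokens, plus
an optional guard that discounts acronym hits doubling as state
abbreviations when another state alias co-occurs ("Road trip through MD
and VA"). State resolution prefers the GPS-derived `place` field over the
self-reported `location`, full state names over USPS abbreviations, and
the longest full name on conflicts ("Kansas City, Missouri" resolves to
Missouri). Users resolving to more than one state are excluded from
geographic analyses only.

# Trends and intervals

Proportions are matched tweets over all eligible (post-URL-filter) tweets
per period and stratum; weeks are ISO weeks (Monday start), months are
calendar months, all timestamps UTC. Intervals are Wilson score intervals
(robust for the small numerators of low-volume state-months); a Wald
option exists for comparison with normal-approximation intervals. For
cohort topic usage, the per-user average divides by all users in the
cohort including those with zero tweets on the topic, and the
HCW-to-general log-ratio applies a Haldane-style half-tweet to both
cohorts' totals when either average is zero, flagged in the output, so
every topic gets a finite ratio.

# Topic model

Latent Dirichlet allocation is fitted by collapsed Gibbs sampling
implemented in C++ with R's RNG, so one `set.seed()` makes the whole
chain — and every downstream output — deterministic. The sampler was
chosen over variational inference because its sufficient statistics admit
exact count-conservation invariants that are cheap to audit along the
chain (`check_lda_state()`, `resume_lda()`); the suite also cross-checks
its long-run topic-word marginals against an independently coded naive
(uncollapsed) sampler on a toy corpus. Priors default to symmetric
`alpha = 50/K`, `beta = 0.01`. Preprocessing lower-cases, removes a
pinned stopword list snapshot (shipped, so upstream drift cannot change
results), numbers and symbols, and merges adjacent token pairs occurring
at least `bigram_min_count` times into single bigram tokens.

Held-out perplexity is `exp(-mean per-token log-likelihood)` under
posterior-mean topic-word rows, with held-out document mixtures estimated
by a fixed number of fold-in Gibbs sweeps. Coherence is the intrinsic
UMass variant — mean over ordered top-term pairs of
`log((D(wi, wj) + 1) / D(wj))` with document counts from the training
corpus; an absent top term is handled by the +1 smoothing with the
denominator floored at one document. Model size is selected by a rule
that uses both diagnostics: among candidate `K` whose mean held-out
perplexity lies within a relative tolerance (default 5%) of the grid
minimum, pick the coherence maximizer. The tolerance default was fixed by
pilot runs on planted five-topic corpora (1000 documents, vocabulary 200,
mean length 60), where the rule recovers the planted count in all ten
replicates; the full diagnostic table is returned so users can apply any
other rule. The reference configuration for real corpora records `K = 16`
as the pipeline default. For share series each document is hard-assigned
its modal topic (argmax of smoothed doc-topic counts, lowest index on
ties) so period shares are mutually exclusive and sum to one.

# Interrupted time series

The segmented regression is ordinary least squares of the daily
proportion on `[1, t, P, tP]` over a symmetric window (default 15 days
each side): `t` runs 1..2w starting on the first pre-policy day — the
intercept is therefore the modelled level just before the window, a
convention recorded prominently because it fixes the intercept's meaning —
and the policy day itself is the first post-policy day (`P = 1`).
Classical standard errors are the default, matching standard ITS
reference implementations; Newey–West errors are available by flag and
the Durbin–Watson statistic is always reported so users can judge serial
correlation themselves. Missing days inside the window are linearly
interpolated with a warning; more than 20% missing, or a missing edge
day, refuses to fit naming the dates. Significance uses two-sided tests
at .05 with no multiplicity correction across states, noted in the output
metadata. Window-length sensitivity refits at several windows; note that
because `t` restarts at 1 in each window, the intercept and step estimate
re-parameterize exactly with the window's time origin while both slopes
are window-invariant — the sensitivity table's sign-stability summary
refers to the step and slope-change estimates.

# Cohort comparison

The HCW and general-population proportion series are paired per ISO week
(monthly pairing is a config option) and compared with the Wilcoxon
matched-pairs signed-rank test: zero differences removed, midranks for
ties, `W` the sum of positive-difference ranks. For up to 25 effective
pairs the two-sided p-value is exact, computed from the full distribution
of `W` over all `2^n` sign assignments via a generating-function
convolution on doubled ranks (doubling makes midranks integers, so the
p-value is bit-identical to literal enumeration, which remains the test
oracle); beyond that, a normal approximation with tie correction and
continuity correction is used, and the suite checks the two agree within
0.01 in the crossover range. Summaries are medians with 25th/75th
percentiles under the linear-interpolation convention.

# The synthetic corpus generator

The generator is first-class, tested code. Its defaults describe a
desk-scale study: ~10,000 tweets from 400 users over February–July 2020
across twelve US states, per-tweet subgroup emission probabilities with
the depression > anxiety >> insomnia > addiction ordering and roughly a
5% overall mental-health rate, an HCW subpopulation with elevated rates
in all four subgroups (largest for insomnia), URL/retweet/non-English
noise (15/20/10%), 2% multi-state users, spam users emitting exactly
`spam_threshold + 100` matching tweets so the spam filter's effect is
deterministic, and planted post-lockdown step/slope changes
(delta, gamma) in four states taken from published state-level ITS
estimates, applied in policy-relative coordinates (post-policy level =
baseline + delta + gamma × days-since-policy, 1-based; with a window-w
design this implies a fitted step of delta − gamma·w and interaction
gamma). Two fractions are deliberately scaled up from observational
corpora — the HCW share (5% of users) and the geolocatable share (90%) —
because at 10,000 tweets the literal shares (~1% and ~19%) would leave
per-period cohort and state counts too sparse for any estimate to be
meaningful; the rate *ratios* and planted (delta, gamma) values are kept
faithful. One global seed drives independent per-component substreams, so
adding a component never perturbs another's draws and regeneration is
byte-identical.

Signal tweets draw a single topic per tweet from cohort-specific topic
weights (one topic is emitted twice as often by HCW users) and then
tokens from that topic's word distribution; this degenerate-mixture
special case of the LDA generative process keeps per-cohort planted topic
rates exactly computable. The separate `generate_lda_corpus()` implements
the full mixed-membership process (per-document Dirichlet mixtures) and
backs the topic-model tests. What the generator does *not* emulate —
natural language, reply networks, bursty daily volume, platform bots —
bounds what passing tests show about real data: they demonstrate that the
estimators recover what the model plants, not that the lexicons or the
segmented-linear model are adequate for any particular real stream.

# Numerical and scale choices

Simulation sizes in the suite were chosen to make each statistical check
informative at desk scale: 2000 replicates for the size of the policy
test (a 3-SE binomial band at 0.05 spans about ±0.015), 500 per window
for interval coverage, 10,000 random samples for the exact-test oracle
equivalence, and a 1000-document planted corpus with 2000 Gibbs sweeps
for topic recovery. The pipeline's LDA default of 200 sweeps is a
pragmatic fit setting for exploratory runs; convergence-sensitive results
should raise it. Degenerate inputs are handled explicitly: empty
documents are dropped before fitting (all-empty is an error), an
all-zero-difference comparison returns a flagged degenerate result rather
than a p-value, fewer than six effective pairs triggers a low-power
warning, and a zero denominator under a period with matches is treated as
inconsistent input, not as zero.

# Known limitations

Lexicon presence is not a clinical diagnosis; negation and sarcasm are
out of scope. The language filter trusts the stream's language tag. State
resolution uses state names and USPS abbreviations only (no city-level
gazetteer). The ITS design is a single-group segmented regression — no
control series, so estimates are associations. The run manifest records
wall-clock times and is therefore the one output file excluded from the
byte-identity determinism guarantee.
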