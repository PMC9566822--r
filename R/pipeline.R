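#' Build and validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list, fills defaults, rejects
#' unknown keys, and validates the result. The resolved configuration is
#' echoed into the output directory by [run_pipeline()] so a run is fully
#' reproducible from its outputs.
#'
#' @param config Path to a YAML file or a named list of overrides.
#' @return A validated list of class `pipeline_config`.
#' @section Keys:
#' `input_stream` (path or `NULL` to generate a synthetic corpus),
#' `output_dir`, `study_window` (two dates), `mh_lexicon`, `hcw_lexicon`,
#' `gazetteer` (paths, `NULL` for packaged defaults), `spam_threshold`,
#' `granularity` (trend/comparison period), `topics` (list: `k`,
#' `alpha` or `NULL`, `beta`, `n_iter`, `bigram_min_count`, `top_n`),
#' `its` (list: `policy_dates` named vector, `window_days`,
#' `sensitivity_windows`), `synth` (overrides for [synth_config()] when
#' generating), `seed`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    input_stream = NULL,
    output_dir = tempfile("infovigil_run_"),
    study_window = c("2020-02-01", "2020-07-31"),
    mh_lexicon = NULL, hcw_lexicon = NULL, gazetteer = NULL,
    spam_threshold = 1000,
    granularity = "week",
    topics = list(k = 16, alpha = NULL, beta = 0.01, n_iter = 200,
                  bigram_min_count = 20, top_n = 10),
    its = list(policy_dates = default_policy_dates(), window_days = 15,
               sensitivity_windows = c(10, 15, 20, 25)),
    synth = list(),
    seed = 1L)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  for (nested in c("topics", "its")) {
    unknown <- setdiff(names(config[[nested]]), names(defaults[[nested]]))
    if (length(unknown))
      stop("unknown ", nested, " config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg$study_window <- as.Date(unlist(cfg$study_window))
  stopifnot(length(cfg$study_window) == 2, cfg$study_window[1] <= cfg$study_window[2])
  if (length(cfg$its$policy_dates) == 0)
    stop("ITS requested but no policy dates configured")
  cfg$its$policy_dates <- stats::setNames(as.Date(unlist(cfg$its$policy_dates)),
                                          names(cfg$its$policy_dates))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' Run the full infoveillance pipeline
#'
#' Stages run in a fixed order — ingest, lexicon labelling, trends, topics,
#' cohort comparison, interrupted time series — each writing its outputs
#' before the next starts, so a failure in stage *k* leaves the outputs of
#' earlier stages intact. With `input_stream = NULL` a synthetic corpus is
#' generated first (stage `generate`) under the global seed, which then
#' drives every stochastic stage: a rerun with an identical configuration
#' reproduces every data output byte for byte (the manifest's wall-clock
#' fields are the only non-deterministic outputs).
#'
#' @param config A [pipeline_config()] (or anything it accepts).
#' @return The run manifest (list), invisibly: config hash, package
#'   version, per-stage input/output counts and wall-clock seconds, and
#'   accumulated warnings. All stage outputs are files under
#'   `config$output_dir`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$output_dir, f)
  manifest <- list(config_hash = rlang::hash(unclass(cfg)),
                   package_version = as.character(utils::packageVersion("infovigil")),
                   stages = list(), warnings = character())
  echo <- unclass(cfg)
  echo$study_window <- as.character(echo$study_window)
  echo$its$policy_dates <- as.list(stats::setNames(
    as.character(cfg$its$policy_dates), names(cfg$its$policy_dates)))
  yaml::write_yaml(echo, out("config_resolved.yaml"))

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)),
      warning = function(w) {
        manifest$warnings <<- c(manifest$warnings,
                                paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    manifest$stages[[name]] <<- list(
      wall_clock_s = round(proc.time()[["elapsed"]] - t0, 3),
      counts = attr(res, "counts") %||% list())
    res
  }

  mh_lex <- if (is.null(cfg$mh_lexicon)) read_mh_lexicon() else read_mh_lexicon(cfg$mh_lexicon)
  hcw_lex <- if (is.null(cfg$hcw_lexicon)) read_hcw_lexicon() else read_hcw_lexicon(cfg$hcw_lexicon)
  gaz <- if (is.null(cfg$gazetteer)) read_state_gazetteer() else read_state_gazetteer(cfg$gazetteer)

  stream_path <- cfg$input_stream
  truth <- NULL
  if (is.null(stream_path)) {
    stream_path <- out("synthetic_stream.jsonl")
    truth <- stage("generate", {
      sc <- do.call(synth_config, utils::modifyList(list(seed = cfg$seed),
                                                    cfg$synth))
      generate_corpus(sc, stream_path, lexicon = mh_lex,
                      truth_path = out("ground_truth.json"))
    })
  }

  filt <- stage("ingest", {
    records <- read_tweet_stream(stream_path, study_window = cfg$study_window)
    res <- apply_filters(records, mh_lex, spam_threshold = cfg$spam_threshold)
    jsonlite::write_json(unclass(res$report), out("filter_report.json"),
                         auto_unbox = TRUE, digits = NA)
    attr(res, "counts") <- unclass(res$report)
    res
  })

  lab <- stage("lexicon", {
    kept <- filt$kept
    kept$hcw <- identify_hcw(kept$user_description, hcw_lex, state_guard = gaz)
    kept$cohort <- ifelse(kept$hcw, "hcw", "general")
    elig <- filt$eligible
    elig$hcw <- identify_hcw(elig$user_description, hcw_lex, state_guard = gaz)
    elig$cohort <- ifelse(elig$hcw, "hcw", "general")
    resolved <- tibble(user_id = elig$user_id,
                       state = resolve_state(elig$place, elig$user_location, gaz))
    ustate <- assign_user_state(resolved)
    kept$state <- ustate$state[match(kept$user_id, ustate$user_id)]
    elig$state <- ustate$state[match(elig$user_id, ustate$user_id)]
    utils::write.csv(ustate, out("user_states.csv"), row.names = FALSE)
    res <- list(kept = kept, eligible = elig, user_states = ustate)
    attr(res, "counts") <- list(
      matched = nrow(kept), hcw_tweets = sum(kept$hcw),
      geolocated_users = sum(ustate$status == "assigned"),
      multi_state_excluded = sum(ustate$status == "excluded"))
    res
  })

  trends_res <- stage("trends", {
    overall <- aggregate_proportions(lab$kept, lab$eligible,
                                     granularity = cfg$granularity,
                                     by = "subgroup")
    state_month <- aggregate_proportions(
      lab$kept[!is.na(lab$kept$state), ],
      lab$eligible[!is.na(lab$eligible$state), ],
      granularity = "month", by = "state")
    utils::write.csv(overall, out("trend_subgroup.csv"), row.names = FALSE)
    utils::write.csv(state_month, out("trend_state_month.csv"), row.names = FALSE)
    res <- list(overall = overall, state_month = state_month)
    attr(res, "counts") <- list(periods = length(unique(overall$period_start)))
    res
  })

  topics_res <- stage("topics", {
    prep <- preprocess_for_topics(lab$kept$text, doc_ids = lab$kept$tweet_id,
                                  bigram_min_count = cfg$topics$bigram_min_count)
    k <- cfg$topics$k
    a <- if (is.null(cfg$topics$alpha)) 50 / k else cfg$topics$alpha
    st <- fit_lda(prep$docs, K = k, alpha = a, beta = cfg$topics$beta,
                  n_iter = cfg$topics$n_iter, seed = cfg$seed)
    tt <- top_terms(st, prep$vocab, top_n = cfg$topics$top_n)
    dates <- as.Date(lab$kept$created_at)[match(prep$doc_ids, lab$kept$tweet_id)]
    shares <- topic_share_series(st, dates, granularity = "month")
    utils::write.csv(tt, out("topic_top_terms.csv"), row.names = FALSE)
    utils::write.csv(shares, out("topic_shares.csv"), row.names = FALSE)
    modal <- max.col(st$n_dk + st$alpha, ties.method = "first")
    assign_tbl <- tibble(tweet_id = prep$doc_ids,
                         user_id = lab$kept$user_id[match(prep$doc_ids,
                                                          lab$kept$tweet_id)],
                         topic = modal)
    roster <- unique(lab$eligible[, c("user_id", "cohort")])
    avg <- per_user_topic_average(assign_tbl, roster)
    wide <- tidyr::pivot_wider(avg, names_from = "cohort", values_from = "avg")
    n_users <- table(roster$cohort)
    if (!("hcw" %in% names(wide))) wide$hcw <- 0
    lr <- log_topic_ratio(wide$hcw, wide$general,
                          n_hcw_users = as.integer(n_users["hcw"]),
                          n_gen_users = as.integer(n_users["general"]))
    usage <- tibble(topic = wide$topic, avg_hcw = wide$hcw,
                    avg_gen = wide$general, log_ratio = lr$log_ratio,
                    smoothed = lr$smoothed)
    utils::write.csv(usage, out("topic_usage_by_cohort.csv"), row.names = FALSE)
    res <- list(state = st, prep = prep, usage = usage, shares = shares)
    attr(res, "counts") <- list(docs_fit = length(prep$docs),
                                docs_dropped = prep$n_dropped,
                                vocabulary = nrow(prep$vocab))
    res
  })

  compare_res <- stage("compare", {
    rows <- lapply(MH_SUBGROUPS, function(sg) {
      has_sg <- vapply(lab$kept$subgroups, function(s) sg %in% s, logical(1))
      num <- lab$kept[has_sg, ]
      h <- aggregate_proportions(num[num$cohort == "hcw", ],
                                 lab$eligible[lab$eligible$cohort == "hcw", ],
                                 granularity = cfg$granularity)
      g <- aggregate_proportions(num[num$cohort == "general", ],
                                 lab$eligible[lab$eligible$cohort == "general", ],
                                 granularity = cfg$granularity)
      pr <- build_paired_series(h, g)
      wt <- wilcoxon_signed_rank(pr)
      tibble(subgroup = sg,
             hcw_median_pct = 100 * wt$summary_x$median,
             hcw_q25_pct = 100 * wt$summary_x$q25,
             hcw_q75_pct = 100 * wt$summary_x$q75,
             general_median_pct = 100 * wt$summary_y$median,
             general_q25_pct = 100 * wt$summary_y$q25,
             general_q75_pct = 100 * wt$summary_y$q75,
             W = wt$W, n_effective = wt$n_effective,
             p_value = wt$p_value, method = wt$method)
    })
    tab <- dplyr::bind_rows(rows)
    utils::write.csv(tab, out("cohort_comparison.csv"), row.names = FALSE)
    attr(tab, "counts") <- list(subgroups = nrow(tab))
    tab
  })

  its_res <- stage("its", {
    rows <- lapply(names(cfg$its$policy_dates), function(st_name) {
      kd <- lab$kept[!is.na(lab$kept$state) & lab$kept$state == st_name, ]
      ed <- lab$eligible[!is.na(lab$eligible$state) & lab$eligible$state == st_name, ]
      daily <- aggregate_proportions(kd, ed, granularity = "day")
      series <- tibble(date = daily$period_start, proportion = daily$proportion)
      pd <- cfg$its$policy_dates[[st_name]]
      fit <- tryCatch(
        fit_segmented_ols(build_its_design(series, pd, cfg$its$window_days)),
        error = function(e) {
          warning("state ", st_name, " skipped: ", conditionMessage(e))
          NULL
        })
      if (is.null(fit)) return(NULL)
      cf <- fit$coefficients
      sens <- tryCatch({
        s <- sensitivity_analysis(series, pd, cfg$its$sensitivity_windows)
        s$state <- st_name
        s
      }, error = function(e) {
        warning("sensitivity for ", st_name, " skipped: ", conditionMessage(e))
        NULL
      })
      tibble(state = st_name, policy_date = as.character(pd),
             intercept = cf$estimate[1], p_intercept = cf$p_value[1],
             time = cf$estimate[2], p_time = cf$p_value[2],
             policy = cf$estimate[3], p_policy = cf$p_value[3],
             time_policy = cf$estimate[4], p_time_policy = cf$p_value[4],
             f_statistic = fit$f_statistic, f_p_value = fit$f_p_value,
             durbin_watson = fit$durbin_watson,
             sensitivity = list(sens))
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    tab <- dplyr::bind_rows(rows)
    sens_all <- if (nrow(tab)) dplyr::bind_rows(tab$sensitivity) else tibble()
    tab$sensitivity <- NULL
    # per the source design: .05 two-sided threshold, no multiplicity
    # correction across states (noted here as output metadata)
    utils::write.csv(tab, out("its_by_state.csv"), row.names = FALSE)
    utils::write.csv(sens_all, out("its_sensitivity.csv"), row.names = FALSE)
    attr(tab, "counts") <- list(states = nrow(tab))
    tab
  })

  manifest$outputs <- sort(setdiff(list.files(cfg$output_dir),
                                   "run_manifest.json"))
  jsonlite::write_json(manifest, out("run_manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, truth = truth,
                 results = list(filter = filt$report, trends = trends_res,
                                topics = topics_res$usage,
                                compare = compare_res, its = its_res),
                 output_dir = cfg$output_dir))
}

#' Write consolidated report files for a pipeline run
#'
#' Collects the table-shaped stage outputs of a finished run into a single
#' JSON summary alongside the per-stage CSVs (trend series, state table,
#' cohort comparison, ITS table). Empty sections are marked explicitly.
#'
#' @param output_dir A directory produced by [run_pipeline()].
#' @param report_path Output path (default `summary_report.json` inside
#'   `output_dir`).
#' @return The report list, invisibly.
#' @export
write_reports <- function(output_dir, report_path = file.path(output_dir,
                                                              "summary_report.json")) {
  if (!dir.exists(output_dir)) stop("output directory not found: ", output_dir)
  read_csv_or_empty <- function(f) {
    p <- file.path(output_dir, f)
    if (!file.exists(p)) return("EMPTY")
    tryCatch({
      out <- utils::read.csv(p)
      if (nrow(out) == 0) "EMPTY" else out
    }, error = function(e) "EMPTY")
  }
  fr_path <- file.path(output_dir, "filter_report.json")
  report <- list(
    filter_report = if (file.exists(fr_path))
      tryCatch(jsonlite::read_json(fr_path), error = function(e) "EMPTY")
    else "EMPTY",
    trend_subgroup = read_csv_or_empty("trend_subgroup.csv"),
    trend_state_month = read_csv_or_empty("trend_state_month.csv"),
    topic_usage = read_csv_or_empty("topic_usage_by_cohort.csv"),
    cohort_comparison = read_csv_or_empty("cohort_comparison.csv"),
    its_by_state = read_csv_or_empty("its_by_state.csv"))
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report)
}
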