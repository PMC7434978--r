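# Choice-log CSV reader/writer, run configuration, JSON reports and the
# end-to-end pipeline. The CSV dialect is fixed: comma separator, "." decimal
# point, UTF-8, "\n" newlines, booleans as 0/1, mandatory header.

.log_columns <- c("bee_id", "group", "phase", "bout_index", "choice_index",
                  "disc_id", "disc_x", "disc_y", "size_class_chosen",
                  "correct", "reward_received")
.log_phases <- c("training", "refresh", "learning_test", "novel_shape_test",
                 "novel_color_test")

#' Write a choice log to CSV
#'
#' @param log A choice-log data.frame (schema of [simulate_bee()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_choice_log <- function(log, path) {
  miss <- setdiff(.log_columns, names(log))
  if (length(miss))
    stop("choice log lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- log[, .log_columns]
  out$correct <- as.integer(out$correct)
  out$reward_received <- as.integer(out$reward_received)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, eol = "\n",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a choice log CSV
#'
#' Enforces the schema: exact column set, 0/1 boolean flags, the invariant
#' `reward_received => correct`, no rewards in test phases, strictly
#' increasing `choice_index` within each bout, and no duplicate
#' (bee, bout, choice) rows. Violations raise errors citing data line
#' numbers (header = line 1). Rows are returned ordered by bee, bout and
#' choice index with logical flag columns.
#'
#' @param path CSV file path.
#' @return A choice-log data.frame.
#' @export
read_choice_log <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  miss <- setdiff(.log_columns, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(df), .log_columns)
  if (length(extra))
    stop("unknown column(s): ", paste(extra, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) {
    warning("empty choice log (header only)", call. = FALSE)
    df$correct <- logical(0)
    df$reward_received <- logical(0)
    return(df[, .log_columns])
  }
  line <- seq_len(nrow(df)) + 1L  # data line numbers in the file
  for (col in c("correct", "reward_received")) {
    bad <- !(df[[col]] %in% c(0L, 1L))
    if (any(bad))
      stop(sprintf("column '%s' must be 0/1 (first offending line %d)",
                   col, line[which(bad)[1]]), call. = FALSE)
    df[[col]] <- df[[col]] == 1L
  }
  bad_phase <- !(df$phase %in% .log_phases)
  if (any(bad_phase))
    stop(sprintf("unknown phase '%s' (line %d)",
                 df$phase[which(bad_phase)[1]], line[which(bad_phase)[1]]),
         call. = FALSE)
  viol <- df$reward_received & !df$correct
  if (any(viol))
    stop(sprintf("reward_received = 1 with correct = 0 (line %d)",
                 line[which(viol)[1]]), call. = FALSE)
  test_rew <- df$reward_received &
    df$phase %in% c("learning_test", "novel_shape_test", "novel_color_test")
  if (any(test_rew))
    stop(sprintf("reward_received = 1 in an unrewarded test phase (line %d)",
                 line[which(test_rew)[1]]), call. = FALSE)
  key <- paste(df$bee_id, df$bout_index, df$choice_index)
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1]
    stop(sprintf("duplicate (bee, bout, choice) row (line %d)", line[dup]),
         call. = FALSE)
  }
  ord <- order(df$bee_id, df$bout_index, df$choice_index)
  df <- df[ord, , drop = FALSE]
  line <- line[ord]
  bout_key <- paste(df$bee_id, df$bout_index)
  same <- head(bout_key, -1) == tail(bout_key, -1)
  jump <- tail(df$choice_index, -1) - head(df$choice_index, -1)
  bad_seq <- same & jump != 1L
  first_of_bout <- !duplicated(bout_key)
  bad_start <- first_of_bout & df$choice_index != 1L
  if (any(bad_start))
    stop(sprintf("bout does not start at choice_index 1 (line %d)",
                 line[which(bad_start)[1]]), call. = FALSE)
  if (any(bad_seq))
    stop(sprintf("non-consecutive choice_index within a bout (line %d)",
                 line[which(bad_seq)[1] + 1L]), call. = FALSE)
  rownames(df) <- NULL
  df
}

.config_schema <- list(
  arena = c("n_discs", "n_rewarded", "disc_diameter", "grid_columns",
            "grid_rows", "horizontal_spacing", "vertical_spacing",
            "max_choices_per_bout"),
  agent = c("strategy", "contingency", "rule_accuracy_min",
            "rule_accuracy_max", "rule_learning_rate", "wsls_fidelity",
            "switch_bout", "wsls_memory", "test_revert_after"),
  cohort = c("n_bees", "group_larger", "group_smaller", "n_bouts",
             "n_test_choices", "n_refresh"),
  analysis = c("block_size", "alpha", "rewards_needed", "max_errors",
               "condition_on"),
  seed = NULL,
  output = c("dir"))

#' Read a run configuration (YAML or JSON)
#'
#' Schema-validated: unknown top-level sections or keys within a section are
#' rejected. Recognised sections: `arena`, `agent`, `cohort`, `analysis`,
#' `seed`, `output`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of configuration sections.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(.config_schema))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (sec in names(cfg)) {
    allowed <- .config_schema[[sec]]
    if (is.null(allowed)) next
    bad <- setdiff(names(cfg[[sec]]), allowed)
    if (length(bad))
      stop(sprintf("unknown key(s) in section '%s': %s", sec,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  cfg
}

#' Write an analysis report as JSON
#'
#' Serialises a named list of results (statistics, test results, config
#' echo) with stable key order; identical inputs produce byte-identical
#' files.
#'
#' @param results Named list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null",
                       force = TRUE)
  invisible(path)
}

.unclass_result <- function(x) {
  if (inherits(x, "test_result") || inherits(x, "switch_report") ||
      inherits(x, "transition_model") || inherits(x, "conditional_probs"))
    x <- unclass(x)
  if (is.list(x) && !is.data.frame(x)) lapply(x, .unclass_result) else x
}

#' Run the full pipeline: simulate, analyse, model, report
#'
#' Simulates a cohort, writes the choice log, computes block summaries and
#' choices per bout, fits the per-bee Markov models on the final block and
#' compares them to observed accuracy, runs switch detection and the
#' unrewarded-test analyses, and writes everything (with a config echo) as
#' JSON. Stages that cannot be computed are reported as explicit nulls.
#'
#' @param config A configuration list as returned by [read_run_config()];
#'   missing entries fall back to the defaults of the underlying functions.
#' @param seed Master seed (overrides `config$seed` when given).
#' @param out_dir Output directory (overrides `config$output$dir`).
#' @return The report list, invisibly; side effects: `choice_log.csv`,
#'   `block_summaries.csv` and `report.json` in `out_dir`.
#' @export
run_pipeline <- function(config = list(), seed = NULL, out_dir = NULL) {
  if (is.null(seed)) seed <- config$seed %||% 1L
  if (is.null(out_dir)) out_dir <- config$output$dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  arena <- do.call(arena_config, config$arena %||% list())
  agent_args <- config$agent %||%
    list(strategy = "hybrid", switch_bout = 21L)
  agent <- do.call(agent_spec, agent_args)
  co <- config$cohort %||% list()
  an <- config$analysis %||% list()
  block_size <- an$block_size %||% 10L
  alpha <- an$alpha %||% 0.05
  stop_rule <- stopping_rule(an$rewards_needed %||% 3L,
                             an$max_errors %||% 2L)

  log <- simulate_cohort(
    n_bees = co$n_bees %||% 18L,
    group_mix = c(larger = co$group_larger %||% 10L,
                  smaller = co$group_smaller %||% 8L),
    agent = agent, master_seed = seed, arena = arena,
    n_bouts = co$n_bouts %||% 30L,
    n_test_choices = co$n_test_choices %||% 10L,
    n_refresh = co$n_refresh %||% 2L)
  write_choice_log(log, file.path(out_dir, "choice_log.csv"))

  summaries <- block_summaries(log, block_size = block_size)
  utils::write.csv(summaries, file.path(out_dir, "block_summaries.csv"),
                   row.names = FALSE)
  cpb <- choices_per_bout(log, block_size = block_size)

  last_block <- max(summaries$block_index[!summaries$partial])
  model_cmp <- tryCatch({
    bees <- sort(unique(log$bee_id))
    blk_log <- log[log$phase == "training" &
                     assign_blocks(log$bout_index, block_size) == last_block, ]
    pred <- vapply(bees, function(b) {
      tm <- estimate_transition_model(blk_log[blk_log$bee_id == b, ])
      predict_bout_performance(tm, stop_rule)$perf
    }, numeric(1))
    obs <- summaries$accuracy_all[summaries$block_index == last_block]
    names(obs) <- summaries$bee_id[summaries$block_index == last_block]
    list(block = last_block, predicted_mean = mean(pred),
         observed_mean = mean(obs),
         test = compare_model_to_observed(obs, pred[names(obs)]))
  }, error = function(e) NULL)

  switch_rep <- tryCatch(
    detect_strategy_switch(summaries, arena = arena, alpha = alpha),
    error = function(e) NULL)
  tests <- tryCatch({
    acc <- lapply(c(learning = "learning_test",
                    novel_shape = "novel_shape_test",
                    novel_color = "novel_color_test"),
                  function(ph) {
      a <- test_accuracy(log, ph)
      list(mean = mean(a),
           vs_chance = test_above_chance(
             a, chance_level(arena$n_discs, arena$n_rewarded, "none")))
    })
    acc$split_half <- split_half_test_performance(log)
    acc$training_test_correlation <- training_test_correlation(
      summaries, test_accuracy(log, "learning_test"))
    acc
  }, error = function(e) NULL)

  report <- list(
    version = "1",
    config = list(seed = seed, arena = unclass(arena),
                  agent = unclass(agent), block_size = block_size,
                  alpha = alpha, stop_rule = unclass(stop_rule)),
    chance_levels = list(
      first = chance_level(arena$n_discs, arena$n_rewarded, "none"),
      win_stay = chance_level(arena$n_discs, arena$n_rewarded, "correct"),
      lose_switch = chance_level(arena$n_discs, arena$n_rewarded,
                                 "incorrect")),
    block_summaries = summaries,
    choices_per_bout = cpb$summary,
    model_comparison = .unclass_result(model_cmp),
    switch_report = .unclass_result(switch_rep),
    unrewarded_tests = .unclass_result(tests))
  write_report(report, file.path(out_dir, "report.json"))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
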