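#' Read an analysis configuration from YAML or JSON
#'
#' @param path file path ending in .yaml/.yml or .json.
#' @return a configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("config file not found: %s", path))
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort_config("config must be a .yaml/.yml or .json file")
  }
}

.as_trial_design <- function(design, seed) {
  if (inherits(design, "trial_design")) return(design)
  if (!is.list(design)) abort_config("'design' must be a list or trial_design")
  effect <- design$effect %||% 0
  cp <- if (effect > 0) effect_cell_params(effect) else null_cell_params()
  trial_design(n_mbct = design$n_mbct %||% 29L,
               n_control = design$n_control %||% 23L,
               lists_per_assessment = design$lists_per_assessment %||% 3L,
               cell_params = cp,
               seed = design$seed %||% seed)
}

.validate_analysis_config <- function(config) {
  if (!is.list(config)) abort_config("config must be a list or a config file")
  if (is.null(config$seed)) abort_config("config must provide a seed")
  has_input <- !is.null(config$input)
  has_design <- !is.null(config$design)
  if (has_input == has_design) {
    abort_config("config must name exactly one of 'input' or 'design'")
  }
  if (has_input &&
      (is.null(config$input$events) || is.null(config$input$lists))) {
    abort_config("config$input must give 'events' and 'lists' paths")
  }
  np <- config$n_perm %||% 1000L
  if (!is.numeric(np) || np < 1) abort_config("n_perm must be >= 1")
  invisible(config)
}

#' Run the full recall-dynamics analysis
#'
#' Orchestrates an end-to-end run: load (or simulate) a study, score it,
#' compute every pooled estimate, run the permutation tests for the
#' within-group changes and the group-by-time interaction of each
#' requested metric and category, and write a deterministic report bundle:
#' `estimates.csv`, `results.json`, `table2_recall_percent.csv` (the
#' group-by-time percent grid), `table3_pvalues.csv` (the p-value grid for
#' negative/positive; neutral in `table3_neutral.csv`), `changes.csv`
#' (T1-to-T2 deltas per group and category), and `manifest.json`. Reruns
#' with an identical configuration are byte-identical.
#'
#' @param config configuration list or path to a YAML/JSON file. Required
#'   fields: `seed`, and exactly one of `input` (a list with `events` and
#'   `lists` CSV paths) or `design` (a [trial_design()] or a list with
#'   `n_mbct`, `n_control`, `lists_per_assessment`, optional `effect`).
#'   Optional: `n_perm` (default 1000), `metrics` (default pstart, pstay,
#'   pstop).
#' @param out_dir output directory (default `config$out_dir`); created if
#'   needed.
#' @return invisibly, a list with the study, estimates, results, grids and
#'   file paths.
#' @export
run_full_analysis <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  .validate_analysis_config(config)
  out_dir <- out_dir %||% config$out_dir %||% abort_config(
    "an output directory is required (config$out_dir or out_dir)")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  metrics <- config$metrics %||% c("pstart", "pstay", "pstop")
  n_perm <- as.integer(config$n_perm %||% 1000L)
  seed <- as.integer(config$seed)

  if (!is.null(config$input)) {
    study <- load_study(config$input$events, config$input$lists,
                        lists_per_assessment =
                          config$lists_per_assessment %||% 3L)
    message(sprintf("loaded study: %d events", nrow(study$events)))
  } else {
    design <- .as_trial_design(config$design, seed)
    study <- simulate_trial(design)
    message(sprintf("simulated trial: %d participants, %d events",
                    nrow(participants(study)), nrow(study$events)))
  }
  study <- score_study(study)
  retained <- sum(study$events$classification == "target")
  message(sprintf("scored: %d retained target recalls", retained))

  estimates <- dynamics_table(study)
  write_estimates(estimates, file.path(out_dir, "estimates.csv"))

  ## permutation tests: control change, MBCT change, interaction
  set.seed(seed)
  test_grid <- expand.grid(metric = metrics, category = CATEGORIES,
                           effect_row = c("control", "MBCT", "interaction"),
                           stringsAsFactors = FALSE)
  test_seeds <- sample.int(2^31 - 2, nrow(test_grid))
  results <- vector("list", nrow(test_grid))
  n_undefined <- 0L
  for (i in seq_len(nrow(test_grid))) {
    g <- test_grid[i, ]
    results[[i]] <- tryCatch({
      if (g$effect_row == "interaction") {
        permutation_test(study, g$metric, g$category, "interaction",
                         n_perm = n_perm, seed = test_seeds[i])
      } else {
        permutation_test(study, g$metric, g$category, "time_within_group",
                         group = g$effect_row, n_perm = n_perm,
                         seed = test_seeds[i])
      }
    }, rdyn_undefined_error = function(e) {
      n_undefined <<- n_undefined + 1L
      structure(list(metric = g$metric, category = g$category,
                     effect = if (g$effect_row == "interaction")
                       "interaction" else "time_within_group",
                     group = if (g$effect_row == "interaction")
                       NA_character_ else g$effect_row,
                     observed_stat = NA_real_, n_perm = n_perm,
                     p_value = NA_real_, sidedness = "two_sided",
                     seed = test_seeds[i], null_mean = NA_real_,
                     null_sd = NA_real_, n_redraws = 0L,
                     exhaustive = FALSE, undefined = TRUE,
                     message = conditionMessage(e)),
                class = "permutation_result")
    })
  }
  if (n_undefined > 0) {
    message(sprintf("warning: %d test(s) undefined (empty cells)",
                    n_undefined))
  }
  write_results(results, file.path(out_dir, "results.json"))

  p_of <- function(metric, category, row) {
    for (r in results) {
      grp_ok <- if (row == "interaction") r$effect == "interaction"
        else r$effect == "time_within_group" && identical(r$group, row)
      if (r$metric == metric && r$category == category && grp_ok) {
        return(r$p_value)
      }
    }
    NA_real_
  }
  grid_for <- function(cats) {
    rows <- expand.grid(row = c("control", "MBCT", "interaction"),
                        metric = metrics, stringsAsFactors = FALSE)
    out <- data.frame(metric = rows$metric, effect_row = rows$row,
                      stringsAsFactors = FALSE)
    for (cat in cats) {
      out[[cat]] <- mapply(p_of, rows$metric, rep(cat, nrow(rows)), rows$row)
    }
    out
  }
  table3 <- grid_for(c("negative", "positive"))
  utils::write.csv(table3, file.path(out_dir, "table3_pvalues.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(grid_for("neutral"),
                   file.path(out_dir, "table3_neutral.csv"),
                   row.names = FALSE, quote = FALSE)

  pct <- estimates[estimates$metric == "recall_pct", ]
  table2 <- stats::reshape(
    pct[c("category", "group", "timepoint", "value")],
    direction = "wide", idvar = c("category", "group"),
    timevar = "timepoint")
  names(table2) <- sub("^value\\.", "", names(table2))
  utils::write.csv(table2, file.path(out_dir, "table2_recall_percent.csv"),
                   row.names = FALSE, quote = FALSE)

  dyn <- estimates[estimates$metric %in% metrics, ]
  wide <- stats::reshape(
    dyn[c("metric", "category", "group", "timepoint", "value")],
    direction = "wide", idvar = c("metric", "category", "group"),
    timevar = "timepoint")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide$delta <- wide$T2 - wide$T1
  utils::write.csv(wide, file.path(out_dir, "changes.csv"),
                   row.names = FALSE, quote = FALSE)

  manifest <- list(
    package = "recalldyn",
    version = as.character(utils::packageVersion("recalldyn")),
    seed = seed, n_perm = n_perm, metrics = metrics,
    config = config[setdiff(names(config), "design")],
    counts = list(participants = nrow(participants(study)),
                  lists = length(unique(study$lists$list_id)),
                  events = nrow(study$events),
                  retained_recalls = retained,
                  undefined_tests = n_undefined))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("report bundle written to %s", out_dir))

  invisible(list(study = study, estimates = estimates, results = results,
                 table2 = table2, table3 = table3, changes = wide,
                 manifest = manifest, out_dir = out_dir))
}

#' Calibration of the permutation tests by simulation
#'
#' Simulates trials across a grid of planted effect magnitudes and reports
#' the rejection rate of the chosen test at level `alpha` with an exact
#' binomial confidence interval. The zero-effect row estimates the type-I
#' error. Stimulus lists are built once and shared across simulated trials
#' (as in a real study, where the lists are fixed); per-trial seeds are
#' drawn once from `seed`, so rows of the effect grid use common random
#' numbers.
#'
#' @param config list with fields `n_sims`, `alpha` (default 0.05),
#'   `effect_grid` (default `c(0, 0.15)`), `design` (a [trial_design()] or
#'   list; its `cell_params` supply the T1 baseline), `metric` (default
#'   "pstay"), `category` (default "negative"), `effect_type` (default
#'   "interaction"), `n_perm` (default 1000), `seed`.
#' @return data.frame with one row per effect size: n_sims, n_reject,
#'   rejection rate and 95% CI.
#' @export
run_calibration <- function(config) {
  if (is.character(config)) config <- read_config(config)
  n_sims <- config$n_sims %||% abort_config("config must give n_sims")
  if (!is.numeric(n_sims) || n_sims < 1) abort_config("n_sims must be >= 1")
  alpha <- config$alpha %||% 0.05
  if (alpha <= 0 || alpha > 1) abort_config("alpha must lie in (0, 1]")
  effect_grid <- config$effect_grid %||% c(0, 0.15)
  metric <- config$metric %||% "pstay"
  category <- config$category %||% "negative"
  effect_type <- config$effect_type %||% "interaction"
  group <- config$group %||% "MBCT"
  n_perm <- as.integer(config$n_perm %||% 1000L)
  seed <- as.integer(config$seed %||% 1L)
  design <- .as_trial_design(config$design %||% list(), seed)
  base <- design$cell_params[["MBCT.T1"]]

  set.seed(seed)
  sim_seeds <- sample.int(2^31 - 2, n_sims)
  lists <- build_list_sets(synthetic_word_norms(), design$list_spec,
                           n_lists = design$lists_per_assessment, n_sets = 2L)

  rows <- lapply(effect_grid, function(e) {
    cp <- if (e == 0) null_cell_params(base) else
      effect_cell_params(e, base)
    rejections <- vapply(seq_len(n_sims), function(i) {
      d <- trial_design(design$n_mbct, design$n_control,
                        design$lists_per_assessment, design$list_spec,
                        cell_params = cp, seed = sim_seeds[i])
      study <- simulate_trial(d, lists = lists)
      p <- permutation_test(study, metric, category, effect_type,
                            group = if (effect_type == "time_within_group")
                              group else NULL,
                            n_perm = n_perm,
                            seed = (sim_seeds[i] + 7L) %% (2^31 - 1L))$p_value
      p <= alpha
    }, logical(1))
    k <- sum(rejections)
    ci <- stats::binom.test(k, n_sims)$conf.int
    data.frame(effect = e, n_sims = n_sims, n_reject = k, rate = k / n_sims,
               ci_lo = ci[1], ci_hi = ci[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
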