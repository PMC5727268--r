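#' Run configuration for the end-to-end pipeline
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed for simulation and splitting.
#' @param input Optional CSV of CMAP matrices
#'   (`subject,condition,intensity_pct_mt,vpp_uv`); when `NULL` a synthetic
#'   cohort is generated.
#' @param n_subjects Cohort size when simulating, default 16.
#' @param modes Normalization modes to fit.
#' @param train_fraction,stratified Split parameters (see
#'   [split_config()]).
#' @param cost SVM regularization.
#' @param schedule,window Protocol geometry.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, input = NULL, n_subjects = 16L,
                       modes = c("per_trial", "baseline"),
                       train_fraction = 0.7, stratified = TRUE, cost = 1,
                       schedule = stimulus_schedule(),
                       window = epoch_window()) {
  if (!is.null(input) && !file.exists(input))
    stop("input file not found: ", input)
  structure(list(out_dir = out_dir, seed = seed, input = input,
                 n_subjects = n_subjects, modes = modes,
                 train_fraction = train_fraction, stratified = stratified,
                 cost = cost, schedule = schedule, window = window),
            class = "run_config")
}

#' Run the full multi-CMAP analysis pipeline
#'
#' Simulate (or load) a cohort of CMAP amplitude matrices, normalize and
#' fit the linear nerve model per condition in each mode, label and split
#' the (a, b) points, train the SVM intervention criterion on the
#' baseline-normalized training set, evaluate it on its test set and on the
#' per-trial-normalized points of all subjects (cross-normalization
#' transfer), and run paired t-tests on the slope between all condition
#' pairs. Writes `params.csv`, `report.json`, `comparisons.csv` and
#' `run.log` into `cfg$out_dir`; `params.csv` is byte-identical across
#' reruns with the same seed.
#'
#' @param cfg A [run_config()].
#' @return The report bundle (named list), invisibly also written to disk.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  matrices <- stage("input", {
    if (is.null(cfg$input)) {
      generate_cohort(sim_config(seed = cfg$seed,
                                 n_subjects = cfg$n_subjects,
                                 schedule = cfg$schedule,
                                 window = cfg$window))
    } else {
      read_cmap_csv(cfg$input, schedule = cfg$schedule)
    }
  })

  params <- stage("fit", fit_cohort(matrices, modes = cfg$modes))
  non_conducting <- attr(params, "non_conducting")
  params_path <- file.path(cfg$out_dir, "params.csv")
  utils::write.csv(params[, c("subject", "condition", "mode", "a", "b")],
                   params_path, row.names = FALSE, quote = FALSE)

  scfg <- split_config(cfg$train_fraction, seed = cfg$seed,
                       stratified = cfg$stratified)
  eval_res <- stage("classify",
                    cross_normalization_eval(matrices, scfg, cost = cfg$cost))

  comparisons <- stage("compare", do.call(rbind, lapply(
    intersect(cfg$modes, unique(params$mode)), function(m)
      compare_all_pairs(params, parameter = "a", mode = m,
                        drop_unpaired = TRUE))))
  utils::write.csv(comparisons, file.path(cfg$out_dir, "comparisons.csv"),
                   row.names = FALSE, quote = FALSE)

  report <- list(
    seed = cfg$seed,
    n_subjects = length(matrices),
    overall_accuracy = eval_res$baseline_test$overall_accuracy,
    per_condition = as.list(eval_res$baseline_test$per_condition),
    transfer = list(
      overall_accuracy = eval_res$transfer$overall_accuracy,
      per_condition = as.list(eval_res$transfer$per_condition)),
    boundary = list(w_a = eval_res$boundary$w_a,
                    w_b = eval_res$boundary$w_b,
                    bias = eval_res$boundary$bias),
    non_conducting = if (nrow(non_conducting)) non_conducting else NULL)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  cfg_json <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg[c("seed", "n_subjects", "modes", "train_fraction",
                             "stratified", "cost")],
                       cfg_json, auto_unbox = TRUE)
  log_lines <- c(
    sprintf("cmaplin %s on R %s", as.character(utils::packageVersion("cmaplin")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed: %d", cfg$seed),
    sprintf("config md5: %s", unname(tools::md5sum(cfg_json))),
    sprintf("non-conducting (subject, condition): %s",
            if (nrow(non_conducting))
              paste(non_conducting$subject, non_conducting$condition,
                    sep = ":", collapse = ", ") else "none"))
  writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
  unlink(cfg_json)

  invisible(list(params = params, report = report, comparisons = comparisons,
                 boundary = eval_res$boundary,
                 non_conducting = non_conducting))
}
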