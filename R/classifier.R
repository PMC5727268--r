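#' Label fitted model parameters healthy or injured
#'
#' The intervention criterion treats the initial and lightest-injury
#' conditions (0, 1) as healthy and the severe conditions (2, 3) as
#' injured.
#'
#' @param params Data frame with at least `a`, `b`, `condition` columns
#'   (as from [fit_cohort()]); rows with `NA` parameters (non-conducting
#'   conditions) are dropped.
#' @return The data frame with a `label` factor
#'   (`levels = c("healthy", "injured")`) added.
#' @export
label_points <- function(params) {
  if (!all(c("a", "b", "condition") %in% names(params)))
    stop("params must have columns a, b, condition")
  params <- params[!is.na(params$a), , drop = FALSE]
  if (!all(params$condition %in% 0:3))
    stop("unknown condition index: ",
         paste(setdiff(unique(params$condition), 0:3), collapse = ", "))
  params$label <- factor(ifelse(params$condition %in% c(0L, 1L),
                                "healthy", "injured"),
                         levels = c("healthy", "injured"))
  params
}

#' Train/test split configuration
#'
#' @param train_fraction Fraction of points in the training set (0, 1);
#'   default 0.7.
#' @param seed RNG seed making the split reproducible.
#' @param stratified Preserve label proportions (default TRUE).
#' @return An object of class `split_config`.
#' @export
split_config <- function(train_fraction = 0.7, seed = 1L, stratified = TRUE) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  structure(list(train_fraction = train_fraction, seed = seed,
                 stratified = stratified), class = "split_config")
}

#' Split labelled points into training and test sets
#'
#' The training set has exactly `floor(train_fraction * N)` points (so 64
#' points at 0.7 give 44/20). Stratified splitting allocates per-label
#' counts by largest remainder, preserving label proportions; the split is
#' deterministic for a fixed seed and exhaustive (train and test partition
#' the input).
#'
#' @param points Labelled data frame from [label_points()].
#' @param cfg A [split_config()].
#' @return List with elements `train` and `test`.
#' @export
split_data <- function(points, cfg = split_config()) {
  stopifnot(inherits(cfg, "split_config"))
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 points to split")
  n_train <- floor(cfg$train_fraction * n)
  if (n_train < 1L || n_train >= n)
    stop("train_fraction leaves an empty train or test set")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (cfg$stratified) {
    if (!"label" %in% names(points)) stop("stratified split needs labels")
    cnt <- table(points$label)
    if (any(cnt < 2L))
      stop("impossible stratification: need >= 2 points per label")
    target <- cfg$train_fraction * cnt
    take <- floor(target)
    rem <- n_train - sum(take)
    if (rem > 0) {
      order_rem <- order(target - take, decreasing = TRUE)
      take[order_rem[seq_len(rem)]] <- take[order_rem[seq_len(rem)]] + 1L
    }
    train_idx <- unlist(lapply(names(cnt), function(l) {
      idx <- which(points$label == l)
      sample(idx, take[[l]])
    }), use.names = FALSE)
  } else {
    train_idx <- sample.int(n, n_train)
  }
  list(train = points[sort(train_idx), , drop = FALSE],
       test = points[setdiff(seq_len(n), train_idx), , drop = FALSE])
}

#' Train the linear SVM intervention criterion
#'
#' Fits a soft-margin, linear-kernel support vector machine on the features
#' `(a, b)` and returns the separating line. Features are not standardized
#' by default, matching the raw parameter scatter; opt in with
#' `scale = TRUE` if `a` and `b` have very different dynamic ranges.
#'
#' @param train Labelled data frame (needs `a`, `b`, `label`; both labels
#'   present).
#' @param cost Soft-margin regularization C, default 1.
#' @param scale Standardize features before fitting (default FALSE).
#' @return An object of class `decision_boundary` with weights `w_a`,
#'   `w_b`, `bias`, oriented so `w . (a, b) + bias >= 0` means healthy,
#'   and `training_meta`.
#' @export
train_svm <- function(train, cost = 1, scale = FALSE) {
  if (!all(c("a", "b", "label") %in% names(train)))
    stop("train must have columns a, b, label")
  if (length(unique(train$label)) < 2L)
    stop("single-class input: need both healthy and injured points")
  fit <- e1071::svm(label ~ a + b, data = train, kernel = "linear",
                    cost = cost, scale = scale)
  w <- drop(t(fit$coefs) %*% as.matrix(fit$SV))
  bias <- -fit$rho
  # orient the normal toward the healthy side
  dv <- as.matrix(train[, c("a", "b")]) %*% w + bias
  if (mean(dv[train$label == "healthy"]) < mean(dv[train$label == "injured"])) {
    w <- -w; bias <- -bias
  }
  if (all(w == 0)) stop("degenerate boundary: zero weight vector")
  structure(list(w_a = unname(w[["a"]]), w_b = unname(w[["b"]]),
                 bias = unname(bias), kernel = "linear",
                 training_meta = list(n_train = nrow(train), cost = cost,
                                      scaled = scale,
                                      mode = unique(train$mode))),
            class = "decision_boundary")
}

#' @export
print.decision_boundary <- function(x, ...) {
  cat(sprintf("Linear SVM boundary: %.4f a + %.4f b + %.4f = 0 (n_train = %d)\n",
              x$w_a, x$w_b, x$bias, x$training_meta$n_train))
  cat("healthy side: w . (a, b) + bias >= 0\n")
  invisible(x)
}

#' Classify model points with a trained boundary
#'
#' Points exactly on the boundary are assigned `healthy` (the tie rule is
#' arbitrary and documented; it only matters on a measure-zero set).
#'
#' @param boundary A [train_svm()] result.
#' @param points Data frame with `a`, `b` columns.
#' @return Factor of predicted labels, levels `c("healthy", "injured")`.
#' @export
classify <- function(boundary, points) {
  stopifnot(inherits(boundary, "decision_boundary"))
  dv <- boundary$w_a * points$a + boundary$w_b * points$b + boundary$bias
  factor(ifelse(dv >= 0, "healthy", "injured"),
         levels = c("healthy", "injured"))
}

#' Classification accuracy, overall and per condition
#'
#' @param predicted,truth Equal-length label vectors.
#' @param condition Optional condition index per point for the
#'   per-condition breakdown.
#' @return List with `overall_accuracy` (percent), `n`, `n_correct`, and
#'   (if `condition` given) `per_condition` named percent vector.
#' @export
evaluate_classification <- function(predicted, truth, condition = NULL) {
  if (length(predicted) == 0L) stop("empty input")
  if (length(predicted) != length(truth))
    stop("predicted and truth lengths differ")
  hit <- as.character(predicted) == as.character(truth)
  out <- list(overall_accuracy = 100 * mean(hit),
              n = length(hit), n_correct = sum(hit))
  if (!is.null(condition)) {
    out$per_condition <- vapply(split(hit, condition), function(h)
      100 * mean(h), 0)
  }
  out
}

#' Cross-normalization transfer evaluation
#'
#' Reproduces the transfer protocol: the SVM is trained on the
#' baseline-normalized training split, then used to classify the
#' *per-trial*-normalized points of all subjects, reporting accuracy per
#' nerve condition. This tests whether a criterion learned with a baseline
#' recording transfers to the baseline-free normalization used when no
#' pre-injury recording exists.
#'
#' @param matrices List of [cmap_matrix()] (each supporting both
#'   normalizations).
#' @param cfg A [split_config()].
#' @param cost SVM regularization, default 1.
#' @return List with `boundary`, `baseline_test` (accuracy of the
#'   baseline-mode test split), `transfer` (overall + per-condition
#'   accuracy on the per-trial points), and `non_conducting`.
#' @export
cross_normalization_eval <- function(matrices, cfg = split_config(),
                                     cost = 1) {
  params <- fit_cohort(matrices, modes = c("per_trial", "baseline"))
  nc <- attr(params, "non_conducting")
  pts <- label_points(params)
  bl <- pts[pts$mode == "baseline", , drop = FALSE]
  pt <- pts[pts$mode == "per_trial", , drop = FALSE]
  sp <- split_data(bl, cfg)
  boundary <- train_svm(sp$train, cost = cost)
  baseline_test <- evaluate_classification(classify(boundary, sp$test),
                                           sp$test$label, sp$test$condition)
  transfer <- evaluate_classification(classify(boundary, pt), pt$label,
                                      pt$condition)
  list(boundary = boundary, baseline_test = baseline_test,
       transfer = transfer, non_conducting = nc, seed = cfg$seed)
}
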