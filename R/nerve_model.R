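#' Normalize stimulus intensities to the percent scale
#'
#' Maps the five intensities P1..P5 to `x[n] = (P[n] - P[1]) / P[5] * 100`,
#' so the first level is 0 and the scale is invariant to the units of P
#' (mA or %MT give identical output).
#'
#' @param levels Five strictly increasing intensities with `P5 > 0`.
#' @return Numeric vector `x_pct` with `x_pct[1] == 0`.
#' @examples
#' normalize_stimulus(c(100, 110, 120, 130, 140))
#' @export
normalize_stimulus <- function(levels) {
  if (any(diff(levels) <= 0)) stop("levels must be strictly increasing")
  p5 <- levels[length(levels)]
  if (p5 <= 0) stop("P5 must be > 0")
  (levels - levels[1L]) / p5 * 100
}

#' Baseline-based response normalization
#'
#' Normalizes the responses of one nerve condition against the *initial*
#' (pre-injury) condition:
#' `y[n] = (CMAP[n,x] - CMAP[1,x]) / CMAP[5,0] * 100`, with the denominator
#' fixed to the baseline condition's maximal-intensity response. Requires a
#' pre-injury recording; scaling a condition's responses scales its output
#' (equivariance).
#'
#' @param m A [cmap_matrix()].
#' @param condition Condition index 0..3.
#' @return Numeric `y_pct` (length 5) with `y_pct[1] == 0`.
#' @export
normalize_baseline <- function(m, condition) {
  v <- .condition_row(m, condition)
  base <- m$vpp[1L, ]
  if (anyNA(base)) stop("baseline response absent: initial condition missing")
  if (base[5L] <= 0) stop("baseline response absent: CMAP at 140% MT is zero")
  (v - v[1L]) / base[5L] * 100
}

#' Per-trial (baseline-free) response normalization
#'
#' Self-normalizes each condition by its own maximal-intensity response:
#' `y[n] = (CMAP[n,x] - CMAP[1,x]) / CMAP[5,x] * 100`. No baseline is
#' needed, and the output is invariant under uniform scaling of the
#' condition's responses -- injury is detected only through a change in the
#' *shape* of the recruitment curve, not its overall size.
#'
#' @inheritParams normalize_baseline
#' @return Numeric `y_pct` (length 5) with `y_pct[1] == 0`.
#' @export
normalize_per_trial <- function(m, condition) {
  v <- .condition_row(m, condition)
  if (v[5L] <= 0)
    stop("response absent; nerve non-conducting at 140% MT ",
         "(condition ", condition, ")")
  (v - v[1L]) / v[5L] * 100
}

.condition_row <- function(m, condition) {
  stopifnot(inherits(m, "cmap_matrix"))
  if (!condition %in% 0:3) stop("unknown condition index: ", condition)
  v <- m$vpp[condition + 1L, ]
  if (anyNA(v)) stop("condition ", condition, " not recorded for subject ",
                     m$subject_id)
  v
}

#' Normalized stimulus-response curve for one condition
#'
#' @inheritParams normalize_baseline
#' @param mode `"per_trial"` (baseline-free) or `"baseline"`.
#' @return An object of class `normalized_curve` with fields `x_pct`,
#'   `y_pct`, `mode`, `condition_index`.
#' @export
normalized_curve <- function(m, condition, mode = c("per_trial", "baseline")) {
  mode <- match.arg(mode)
  y <- switch(mode,
              per_trial = normalize_per_trial(m, condition),
              baseline = normalize_baseline(m, condition))
  structure(list(x_pct = normalize_stimulus(m$schedule$levels_pct_mt),
                 y_pct = unname(y), mode = mode,
                 condition_index = condition,
                 subject_id = m$subject_id),
            class = "normalized_curve")
}

#' Fit the linear nerve model y = a x + b
#'
#' Ordinary least squares on the normalized stimulus-response pairs, solved
#' from the normal equations with a design matrix `[1, x]`. The slope `a`
#' (percent response per percent intensity) is the nerve-function feature:
#' it falls as the suprathreshold recruitment curve flattens with injury.
#' Fields are named, never positional, so the (intercept, slope) ordering
#' of the solution vector cannot be confused.
#'
#' @param x Normalized stimulus intensities (or a [normalized_curve()], in
#'   which case `y` is ignored), at least 2 distinct values.
#' @param y Normalized responses.
#' @param mode,condition_index Optional annotations carried on the fit.
#' @return An object of class `nerve_model` with elements `a`, `b`,
#'   `residual_ss`, `fitted`, `x`, `y`, `mode`, `condition_index`.
#' @examples
#' fit_nerve_model(c(0, 1, 2), c(1, 3, 5))  # a = 2, b = 1
#' @export
fit_nerve_model <- function(x, y = NULL, mode = NA_character_,
                            condition_index = NA_integer_) {
  if (inherits(x, "normalized_curve")) {
    crv <- x
    x <- crv$x_pct; y <- crv$y_pct
    mode <- crv$mode; condition_index <- crv$condition_index
  }
  if (length(x) != length(y) || length(x) < 2L)
    stop("need matching x and y with at least 2 points")
  if (length(unique(x)) < 2L)
    stop("singular design: all x values identical")
  X <- cbind(intercept = 1, slope = x)
  theta <- solve(crossprod(X), crossprod(X, y))
  a <- theta["slope", 1L]
  b <- theta["intercept", 1L]
  fitted <- a * x + b
  structure(list(a = unname(a), b = unname(b),
                 residual_ss = sum((y - fitted)^2),
                 fitted = fitted, x = x, y = y, mode = mode,
                 condition_index = condition_index),
            class = "nerve_model")
}

#' @export
print.nerve_model <- function(x, ...) {
  lab <- if (!is.na(x$mode)) sprintf(" (%s, condition %s)", x$mode,
                                     x$condition_index) else ""
  cat(sprintf("Linear nerve model%s: y = %.4f x + %.4f\n", lab, x$a, x$b))
  invisible(x)
}

#' @export
coef.nerve_model <- function(object, ...) c(a = object$a, b = object$b)

#' @export
predict.nerve_model <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else newdata
  object$a * x + object$b
}

#' @export
residuals.nerve_model <- function(object, ...) object$y - object$fitted

#' @export
fitted.nerve_model <- function(object, ...) object$fitted

#' @export
summary.nerve_model <- function(object, ...) {
  n <- length(object$x)
  out <- list(coefficients = coef(object),
              residual_ss = object$residual_ss,
              sigma = sqrt(object$residual_ss / max(n - 2L, 1L)),
              n = n, mode = object$mode,
              condition_index = object$condition_index)
  class(out) <- "summary.nerve_model"
  out
}

#' @export
print.summary.nerve_model <- function(x, ...) {
  cat(sprintf("Linear nerve model: a = %.4f, b = %.4f\n",
              x$coefficients["a"], x$coefficients["b"]))
  cat(sprintf("n = %d, residual SS = %.4g, residual SD = %.4g\n",
              x$n, x$residual_ss, x$sigma))
  invisible(x)
}

#' @export
plot.nerve_model <- function(x, ...) {
  plot(x$x, x$y, xlab = "stimulus intensity (%)",
       ylab = "normalized Vpp (%)",
       main = sprintf("y = %.3f x + %.3f", x$a, x$b), ...)
  graphics::abline(x$b, x$a)
  invisible(x)
}

#' Fit the nerve model for every condition of a CMAP matrix
#'
#' @param m A [cmap_matrix()].
#' @param mode Normalization mode, `"per_trial"` or `"baseline"`.
#' @param raw_intensity Fit on raw P1..P5 (in %MT) instead of the
#'   normalized percent scale (comparison option; default FALSE).
#' @return Data frame with columns `subject, condition, mode, a, b,
#'   residual_ss`. Non-conducting or missing conditions appear with `NA`
#'   parameters and are listed in attribute `"non_conducting"`.
#' @export
fit_conditions <- function(m, mode = c("per_trial", "baseline"),
                           raw_intensity = FALSE) {
  mode <- match.arg(mode)
  rows <- lapply(0:3, function(cond) {
    fit <- tryCatch({
      if (raw_intensity) {
        v <- .condition_row(m, cond)
        fit_nerve_model(m$schedule$levels_pct_mt, unname(v), mode = mode,
                        condition_index = cond)
      } else {
        fit_nerve_model(normalized_curve(m, cond, mode))
      }
    }, error = function(e) e)
    if (inherits(fit, "error"))
      data.frame(subject = m$subject_id, condition = cond, mode = mode,
                 a = NA_real_, b = NA_real_, residual_ss = NA_real_,
                 note = conditionMessage(fit))
    else
      data.frame(subject = m$subject_id, condition = cond, mode = mode,
                 a = fit$a, b = fit$b, residual_ss = fit$residual_ss,
                 note = "")
  })
  out <- do.call(rbind, rows)
  nc <- out[is.na(out$a), c("subject", "condition", "note")]
  attr(out, "non_conducting") <- nc
  out
}

#' Fit both normalizations across a cohort of CMAP matrices
#'
#' @param matrices List of [cmap_matrix()].
#' @param modes Normalization modes to fit.
#' @return Stacked data frame from [fit_conditions()], with attribute
#'   `"non_conducting"` aggregating skipped (subject, condition) pairs.
#' @export
fit_cohort <- function(matrices, modes = c("per_trial", "baseline")) {
  parts <- list()
  nc <- list()
  for (mode in modes) {
    for (m in matrices) {
      f <- fit_conditions(m, mode)
      parts[[length(parts) + 1L]] <- f
      nci <- attr(f, "non_conducting")
      if (nrow(nci)) nc[[length(nc) + 1L]] <- cbind(nci, mode = mode)
    }
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  attr(out, "non_conducting") <-
    if (length(nc)) do.call(rbind, nc) else
      data.frame(subject = character(), condition = integer(),
                 note = character(), mode = character())
  out
}
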