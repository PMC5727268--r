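#' Paired comparison of a model parameter between two nerve conditions
#'
#' Paired t-test on per-subject differences of a fitted parameter between
#' two conditions: `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees
#' of freedom, two-sided p-value. Subjects missing either condition (e.g.
#' non-conducting) are an error, listed by id. A zero-variance, nonzero
#' mean difference yields `t = +/-Inf`, `p = 0` with a degenerate-variance
#' warning; identical values yield `t = 0`, `p = 1`.
#'
#' @param params Data frame from [fit_cohort()] (single mode, or pass
#'   `mode`).
#' @param parameter `"a"` (slope) or `"b"` (intercept).
#' @param pair Two condition indices `c(i, j)`; differences are `i - j`.
#' @param mode Normalization mode to select when `params` holds several.
#' @param drop_unpaired Drop subjects missing one condition (e.g.
#'   non-conducting, excluded upstream) instead of erroring; default FALSE.
#' @return One-row data frame: `condition_i, condition_j, parameter, mode,
#'   n, mean_diff, t, df, p`.
#' @export
compare_conditions <- function(params, parameter = c("a", "b"),
                               pair = c(0L, 3L), mode = NULL,
                               drop_unpaired = FALSE) {
  parameter <- match.arg(parameter)
  if (!is.null(mode)) params <- params[params$mode == mode, , drop = FALSE]
  m <- unique(params$mode)
  if (length(m) > 1L)
    stop("params holds several modes (", paste(m, collapse = ", "),
         "); pass mode=")
  vi <- params[params$condition == pair[1L] & !is.na(params$a), ]
  vj <- params[params$condition == pair[2L] & !is.na(params$a), ]
  subj <- intersect(vi$subject, vj$subject)
  unpaired <- setdiff(union(vi$subject, vj$subject), subj)
  if (length(unpaired) && !drop_unpaired)
    stop("unpaired subjects (missing one condition): ",
         paste(unpaired, collapse = ", "))
  if (length(subj) < 2L) stop("need >= 2 paired subjects")
  d <- vi[[parameter]][match(subj, vi$subject)] -
    vj[[parameter]][match(subj, vj$subject)]
  n <- length(d)
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (md == 0) {
      t_stat <- 0; p <- 1
    } else {
      warning("degenerate variance: constant nonzero difference")
      t_stat <- sign(md) * Inf; p <- 0
    }
  } else {
    t_stat <- md / (sdd / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1L)
  }
  data.frame(condition_i = pair[1L], condition_j = pair[2L],
             parameter = parameter, mode = m %||% NA_character_,
             n = n, mean_diff = md, t = t_stat, df = n - 1L, p = p)
}

#' All pairwise condition comparisons
#'
#' Runs [compare_conditions()] for the six condition pairs. Two-sided, no
#' multiple-comparison correction by default; `adjust = "bonferroni"` is
#' available.
#'
#' @inheritParams compare_conditions
#' @param adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @return Data frame of six comparison rows (plus `p_adj` if adjusted).
#' @export
compare_all_pairs <- function(params, parameter = "a", mode = NULL,
                              adjust = "none", drop_unpaired = FALSE) {
  pairs <- utils::combn(0:3, 2L)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k)
    compare_conditions(params, parameter, pair = pairs[, k], mode = mode,
                       drop_unpaired = drop_unpaired)))
  if (adjust != "none") out$p_adj <- stats::p.adjust(out$p, method = adjust)
  out
}
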