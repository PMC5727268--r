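#' Grand-averaged CMAP amplitude matrix
#'
#' The pipeline's central table: grand-averaged peak-to-peak amplitudes
#' (uV) indexed by nerve condition (rows: 0 = initial, 1..3 = damage
#' levels) and stimulus intensity (columns: P1..P5). Rows of `NA` mark
#' conditions not recorded (allowed only with `partial = TRUE`); a
#' condition whose 140 %MT response has disappeared is represented by a
#' (near-)zero fifth column and is flagged non-conducting downstream, not
#' removed here.
#'
#' @param vpp Numeric 4 x 5 matrix of amplitudes (uV), rows conditions
#'   0..3, columns intensities 1..5.
#' @param schedule A [stimulus_schedule()].
#' @param subject_id Subject identifier.
#' @param partial Allow missing (all-`NA`) condition rows.
#' @return An object of class `cmap_matrix`.
#' @export
cmap_matrix <- function(vpp, schedule = stimulus_schedule(),
                        subject_id = "s1", partial = FALSE) {
  vpp <- as.matrix(vpp)
  if (!all(dim(vpp) == c(4L, 5L)))
    stop("vpp must be a 4 x 5 matrix (conditions 0..3 x intensities 1..5)")
  row_na <- apply(vpp, 1L, function(r) all(is.na(r)))
  if (any(is.na(vpp)) && (!partial || !all(is.na(vpp[row_na, ]))))
    stop("NA amplitudes allowed only as whole missing rows with partial = TRUE")
  ok <- vpp[!row_na, , drop = FALSE]
  if (any(!is.finite(ok)) || any(ok < 0))
    stop("amplitudes must be finite and >= 0")
  dimnames(vpp) <- list(condition = 0:3, intensity = 1:5)
  structure(list(vpp = vpp, schedule = schedule, subject_id = subject_id),
            class = "cmap_matrix")
}

#' @export
print.cmap_matrix <- function(x, ...) {
  cat(sprintf("CMAP amplitude matrix, subject %s (uV):\n", x$subject_id))
  print(round(x$vpp, 1))
  invisible(x)
}

#' Read / write CMAP matrices as CSV
#'
#' Long format with columns `subject,condition,intensity_pct_mt,vpp_uv`;
#' one file can hold a whole cohort.
#'
#' @param path CSV path.
#' @param schedule Schedule attached to each matrix on read.
#' @return `read_cmap_csv`: a list of [cmap_matrix()] (one per subject).
#' @export
read_cmap_csv <- function(path, schedule = stimulus_schedule()) {
  df <- utils::read.csv(path)
  need <- c("subject", "condition", "intensity_pct_mt", "vpp_uv")
  if (!all(need %in% names(df)))
    stop("expected columns ", paste(need, collapse = ","))
  lapply(split(df, df$subject), function(d) {
    vpp <- matrix(NA_real_, 4L, 5L)
    lev <- sort(unique(d$intensity_pct_mt))
    for (i in seq_len(nrow(d))) {
      col <- match(d$intensity_pct_mt[i], lev)
      vpp[d$condition[i] + 1L, col] <- d$vpp_uv[i]
    }
    cmap_matrix(vpp, schedule = schedule, subject_id = as.character(d$subject[1L]),
                partial = anyNA(vpp))
  })
}

#' @rdname read_cmap_csv
#' @param matrices A [cmap_matrix()] or list of them.
#' @export
write_cmap_csv <- function(matrices, path) {
  if (inherits(matrices, "cmap_matrix")) matrices <- list(matrices)
  rows <- do.call(rbind, lapply(matrices, function(m) {
    lev <- m$schedule$levels_pct_mt
    data.frame(subject = m$subject_id,
               condition = rep(0:3, times = 5L),
               intensity_pct_mt = rep(lev, each = 4L),
               vpp_uv = as.vector(m$vpp))
  }))
  rows <- rows[!is.na(rows$vpp_uv), ]
  rows <- rows[order(rows$subject, rows$condition, rows$intensity_pct_mt), ]
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
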