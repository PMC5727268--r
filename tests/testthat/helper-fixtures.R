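# shared fixtures, built in code at test time

# bare epoch constructor for feature-extraction tests (bypasses segmentation)
make_epoch <- function(samples, fs = 2000, pre_n = 10, intensity = 1L,
                       train = 1L, cond = 0L) {
  structure(list(samples = samples, fs = fs, intensity_index = intensity,
                 train_index = train, condition_index = cond,
                 trigger_index = NA_integer_, pre_n = pre_n),
            class = "cmap_epoch")
}

# random valid CMAP matrix: positive, loosely increasing rows
rand_cmap_matrix <- function(subject = "s1") {
  base <- sort(runif(5, 50, 600))
  rows <- t(sapply(1:4, function(i) pmax(base * runif(1, 0.2, 1.2) +
                                           rnorm(5, 0, 5), 1)))
  cmap_matrix(rows, subject_id = subject)
}

# two well-separated Gaussian clouds in (a, b), labelled
separable_points <- function(n_per = 20, gap = 5) {
  data.frame(
    a = c(rnorm(n_per, gap, 0.3), rnorm(n_per, 0, 0.3)),
    b = c(rnorm(n_per, 0, 0.3), rnorm(n_per, 0, 0.3)),
    condition = rep(c(0L, 3L), each = n_per),
    mode = "per_trial",
    label = factor(rep(c("healthy", "injured"), each = n_per),
                   levels = c("healthy", "injured")))
}

# brute-force SSE grid search oracle for the linear fit. The search runs on
# double-centered data, yc ~ a*xc + b0 with xc = x - mean(x) and
# yc = y - mean(y) (the SSE surface is separable there, so a zooming uniform
# grid brackets the optimum in each coordinate and b0 is near 0), then maps
# back to the intercept b = mean(y) + b0 - a*mean(x). Staged 61 x 61 grids;
# each next stage spans +/- 2 grid steps around the incumbent minimum.
grid_fit <- function(x, y, half_range = 6, stages = 4) {
  n <- length(x)
  xc <- x - mean(x)
  yc <- y - mean(y)
  sxx <- sum(xc^2); sxy <- sum(xc * yc); syy <- sum(yc^2)
  ctr <- c(0, 0); hr <- half_range
  for (s in seq_len(stages)) {
    a <- seq(ctr[1] - hr, ctr[1] + hr, length.out = 61)
    b0 <- seq(ctr[2] - hr, ctr[2] + hr, length.out = 61)
    sse <- outer(a, b0, function(ag, bg)
      syy - 2 * ag * sxy + ag^2 * sxx + n * bg^2)
    k <- arrayInd(which.min(sse), dim(sse))
    ctr <- c(a[k[1]], b0[k[2]])
    hr <- 2 * (2 * hr / 60)
  }
  c(a = ctr[1], b = mean(y) + ctr[2] - ctr[1] * mean(x))
}
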