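test_that("condition labels map initial/damage1 to healthy, damage2/3 to injured", {
  set.seed(21)
  mats <- lapply(sprintf("s%02d", 1:16), rand_cmap_matrix)
  params <- fit_cohort(mats, modes = "baseline")
  pts <- label_points(params)
  expect_equal(sum(pts$label == "healthy"), 32)
  expect_equal(sum(pts$label == "injured"), 32)
  expect_equal(unique(pts$label[pts$condition == 1]), factor("healthy",
               levels = c("healthy", "injured")))
  expect_equal(unique(pts$label[pts$condition == 2]), factor("injured",
               levels = c("healthy", "injured")))
  bad <- params; bad$condition[1] <- 7L
  expect_error(label_points(bad), "unknown condition")
})

test_that("splits have exact floor sizes, are seeded, stratified and exhaustive", {
  set.seed(22)
  pts <- separable_points(n_per = 32)   # 64 points
  sp <- split_data(pts, split_config(0.7, seed = 5))
  expect_equal(nrow(sp$train), 44)
  expect_equal(nrow(sp$test), 20)
  expect_equal(as.vector(table(sp$train$label)), c(22, 22))

  sp2 <- split_data(pts, split_config(0.7, seed = 5))
  expect_identical(sp$train, sp2$train)

  sp3 <- split_data(separable_points(n_per = 5), split_config(0.5, seed = 1))
  expect_equal(nrow(sp3$train), 5)
  expect_equal(nrow(sp3$test), 5)

  # exhaustive and disjoint
  got <- sort(c(rownames(sp$train), rownames(sp$test)))
  expect_equal(got, sort(rownames(pts)))
  expect_length(intersect(rownames(sp$train), rownames(sp$test)), 0)

  one_class <- pts[pts$label == "healthy", ]
  expect_error(split_data(one_class, split_config(0.7, seed = 1)),
               "stratification")
  # plain random splitting stays available
  sp4 <- split_data(pts, split_config(0.7, seed = 5, stratified = FALSE))
  expect_equal(nrow(sp4$train), 44)
})

test_that("the linear SVM separates separable clouds and tolerates XOR labels", {
  set.seed(23)
  pts <- separable_points()
  bnd <- train_svm(pts)
  expect_equal(as.character(classify(bnd, pts)), as.character(pts$label))

  xor <- data.frame(a = c(0, 1.1, 0, 1), b = c(0, 0, 1, 1.1),
                    label = factor(c("healthy", "injured", "injured",
                                     "healthy"),
                                   levels = c("healthy", "injured")),
                    mode = "baseline")
  bnd2 <- train_svm(xor)   # soft margin absorbs the non-separable case
  acc <- evaluate_classification(classify(bnd2, xor), xor$label)
  expect_lt(acc$overall_accuracy, 100)

  expect_error(train_svm(pts[pts$label == "healthy", ]), "single-class")
})

test_that("a two-point training set yields the perpendicular bisector", {
  two <- data.frame(a = c(1, 0), b = c(0, 0),
                    label = factor(c("healthy", "injured"),
                                   levels = c("healthy", "injured")),
                    mode = "baseline")
  bnd <- train_svm(two)
  expect_equal(bnd$w_b, 0, tolerance = 1e-6)
  expect_equal(-bnd$bias / bnd$w_a, 0.5, tolerance = 1e-6)  # line a = 0.5
  expect_gt(bnd$w_a, 0)  # healthy side is a > 0.5
})

test_that("classification follows the sign rule with healthy ties and mirror symmetry", {
  bnd <- structure(list(w_a = 1, w_b = 0, bias = -0.5, kernel = "linear",
                        training_meta = list(n_train = 2)),
                   class = "decision_boundary")
  on_line <- data.frame(a = 0.5, b = 3)
  expect_equal(as.character(classify(bnd, on_line)), "healthy")
  mirrored <- data.frame(a = c(0.5 + 0.2, 0.5 - 0.2), b = c(0, 0))
  expect_equal(as.character(classify(bnd, mirrored)),
               c("healthy", "injured"))
})

test_that("accuracy is a percentage with per-condition breakdown, order-invariant", {
  p <- factor(rep("healthy", 4)); t <- factor(rep("healthy", 4))
  expect_equal(evaluate_classification(p, t)$overall_accuracy, 100)

  p16 <- rep("healthy", 16); t16 <- p16; t16[7] <- "injured"
  ev <- evaluate_classification(p16, t16)
  expect_equal(ev$overall_accuracy, 93.75)
  expect_equal(round(ev$overall_accuracy, 1), 93.8)

  expect_error(evaluate_classification(factor(), factor()), "empty")
  expect_error(evaluate_classification(p16, t16[-1]), "differ")

  set.seed(24)
  pred <- sample(c("healthy", "injured"), 40, TRUE)
  truth <- sample(c("healthy", "injured"), 40, TRUE)
  perm <- sample(40)
  expect_equal(evaluate_classification(pred, truth)$overall_accuracy,
               evaluate_classification(pred[perm], truth[perm])$overall_accuracy)

  cond <- rep(0:3, each = 10)
  ev2 <- evaluate_classification(pred, truth, cond)
  expect_named(ev2$per_condition, c("0", "1", "2", "3"))
})

test_that("training recovers separable labels across random geometries", {
  for (seed in 1:20) {
    set.seed(seed)
    pts <- separable_points(n_per = 10, gap = runif(1, 3, 10))
    pts$b <- pts$b + rnorm(1, 0, 2)           # translate
    bnd <- train_svm(pts)
    acc <- evaluate_classification(classify(bnd, pts), pts$label)
    expect_equal(acc$overall_accuracy, 100)
  }
})

test_that("cross-normalization transfer reuses the baseline-trained boundary", {
  # matrices whose conditions share CMAP5 with the baseline: both
  # normalizations coincide, so fitted parameters are mode-independent
  set.seed(25)
  mats <- lapply(sprintf("s%02d", 1:8), function(id) {
    base <- sort(runif(5, 100, 600))
    rows <- t(sapply(1:4, function(i) {
      r <- base + c(rnorm(4, 0, 10), 0)   # same 5th column
      pmax(r, 1)
    }))
    cmap_matrix(rows, subject_id = id)
  })
  params <- fit_cohort(mats)
  pt <- params[params$mode == "per_trial", c("a", "b")]
  bl <- params[params$mode == "baseline", c("a", "b")]
  expect_equal(pt, bl, ignore_attr = TRUE)

  res <- cross_normalization_eval(mats, split_config(seed = 2))
  expect_named(res$transfer$per_condition, c("0", "1", "2", "3"))
  expect_equal(res$transfer$n, 32)

  # default synthetic cohort: initial condition transfers at least as well
  # as damage2 (the hardest condition)
  cohort <- generate_cohort(sim_config(seed = 1))
  res2 <- cross_normalization_eval(cohort, split_config(seed = 1))
  expect_gte(res2$transfer$per_condition[["0"]],
             res2$transfer$per_condition[["2"]])
  expect_equal(res2$transfer$n, 64)
})
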