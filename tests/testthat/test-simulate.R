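test_that("a fully recruited population saturates across all intensities", {
  pop <- axon_population(thresholds = runif(50, 0.5, 0.95),
                         amps = rep(2, 50))
  v <- simulate_amplitudes(pop, injury_model(), 0, noise_sd_uv = 0, seed = 1)
  expect_true(all(v == v[1]))
  expect_equal(unname(v[1]), 100)
})

test_that("severe blocking removes the expected share of recruitable amplitude", {
  # expectation over nerves: draw a fresh population per replicate (with
  # full selectivity the block is deterministic given the population)
  set.seed(31)
  frac <- replicate(500, {
    pop <- axon_population(thresholds = runif(200, 0.5, 0.95))
    v <- simulate_amplitudes(pop, injury_model(), 3, noise_sd_uv = 0)
    unname(v[5]) / sum(pop$amps)
  })
  se <- sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - 0.25), 2 * se)

  # and over blocking draws at zero selectivity for a fixed nerve
  pop <- axon_population(thresholds = runif(200, 0.5, 0.95), seed = 32)
  set.seed(32)
  unsel <- injury_model(selectivity = rep(0, 4))
  frac2 <- replicate(500, {
    v <- simulate_amplitudes(pop, unsel, 3, noise_sd_uv = 0)
    unname(v[5]) / sum(pop$amps)
  })
  se2 <- sd(frac2) / sqrt(length(frac2))
  expect_lt(abs(mean(frac2) - 0.25), 2 * se2)
})

test_that("cohort generation is deterministic and has the designed shape", {
  c1 <- generate_cohort(sim_config(seed = 1))
  c2 <- generate_cohort(sim_config(seed = 1))
  expect_length(c1, 16)
  expect_true(all(vapply(c1, function(m) all(dim(m$vpp) == c(4, 5)), TRUE)))
  expect_identical(lapply(c1, `[[`, "vpp"), lapply(c2, `[[`, "vpp"))
  c3 <- generate_cohort(sim_config(seed = 2))
  expect_false(identical(c1[[1]]$vpp, c3[[1]]$vpp))
})

test_that("median fitted slope falls strictly with damage level in both modes", {
  cohort <- generate_cohort(sim_config(seed = 1))
  params <- fit_cohort(cohort)
  for (mode in c("per_trial", "baseline")) {
    med <- sapply(0:3, function(cc)
      median(params$a[params$mode == mode & params$condition == cc]))
    expect_true(all(diff(med) < 0), label = paste("monotone medians,", mode))
  }
})

test_that("uniform (unselective) blocking is invisible to per-trial normalization", {
  trap <- injury_model(selectivity = c(0, 0, 0, 0))
  gap <- function(injury) {
    cohort <- generate_cohort(sim_config(seed = 1), injury = injury)
    params <- fit_cohort(cohort, modes = "per_trial")
    med <- sapply(c(0, 3), function(cc)
      median(params$a[params$condition == cc]))
    med[1] - med[2]
  }
  g_trap <- gap(trap)
  g_default <- gap(injury_model())
  expect_gt(g_default, 0.5)
  expect_lt(abs(g_trap), 0.2 * g_default)
})

test_that("expected raw amplitudes are non-increasing in damage level at every intensity", {
  pop <- axon_population(seed = 33)
  set.seed(33)
  mean_v <- sapply(0:3, function(lev)
    rowMeans(replicate(200, as.numeric(
      simulate_amplitudes(pop, injury_model(), lev, noise_sd_uv = 0)))))
  # columns are damage levels; allow Monte-Carlo slack of 2 SE (~ sqrt(n))
  for (i in 1:5) {
    diffs <- diff(mean_v[i, ])
    expect_true(all(diffs < mean_v[i, 1] * 0.02 + 1e-9),
                label = paste("intensity", i))
  }
})

test_that("simulated recordings carry ground truth and honour the schedule", {
  pop <- axon_population(seed = 34)
  cfg <- sim_config(seed = 34)
  rec <- simulate_recording(pop, injury_model(), 2, cfg, seed = 34)
  expect_length(rec$meta$trigger_index, 4 * 5)
  expect_length(rec$meta$programmed_vpp, 5)
  expect_equal(rec$meta$condition_index, 2)
  # triggers sit 1 s apart within trains (fs samples)
  d <- diff(rec$meta$trigger_index)
  expect_true(all(d[c(1:4, 6:9, 11:14, 16:19)] == cfg$fs))
  rec2 <- simulate_recording(pop, injury_model(), 2, cfg, seed = 34)
  expect_identical(rec$emg, rec2$emg)
})
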