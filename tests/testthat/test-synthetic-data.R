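test_that("zero burst rate gives an empty train and invalid parameters error", {
  p <- pure_profile(rate = 0)
  tr <- simulate_flip_train(p, 10, seed = 1, fish_pars = unit_fish())
  expect_length(tr$times_s, 0)
  expect_error(behavior_profile(baseline_burst_rate = NaN),
               class = "tailflip_parameter_error")
  expect_error(behavior_profile(within_burst_flip_rate = c(5, 2)),
               class = "tailflip_parameter_error")
  expect_error(simulate_flip_train(p, 0), class = "tailflip_parameter_error")
})

test_that("flip count matches the closed-form compound-Poisson mean", {
  ## bursts at rate r/min, geometric flips per burst (mean 6):
  ## E[flips] = r * T * 6; Monte-Carlo mean over 200 seeds must sit within
  ## the 99% CI around that value
  p <- pure_profile(rate = 10)
  r <- 10; T_min <- 10; mean_burst <- p$flips_per_burst_mean
  counts <- vapply(1:200, function(s) {
    length(simulate_flip_train(p, T_min, seed = s, fish_pars = unit_fish())$times_s)
  }, numeric(1))
  expected <- r * T_min * mean_burst
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 2.58 * se + 0.01 * expected)
})

test_that("within-burst inter-flip intervals always lie in 0.2-0.5 s", {
  p <- behavior_profile()
  for (s in 1:5) {
    tr <- simulate_flip_train(p, 10, seed = s)
    gaps <- diff(tr$times_s)
    same_burst <- diff(tr$burst_id) == 0L
    if (any(same_burst)) {
      expect_true(all(gaps[same_burst] >= 0.2 - 1e-9))
      expect_true(all(gaps[same_burst] <= 0.5 + 1e-9))
    }
    ## bouts are serialized: every gap respects the flip refractory
    expect_true(all(gaps >= 0.2 - 1e-9))
    expect_true(!is.unsorted(tr$times_s, strictly = TRUE))
  }
})

test_that("rendered traces superpose kernels, noise, drift and keep truth", {
  mm0 <- measurement_model(noise_sd = 0, gain_drift_amplitude = 0,
                           artifact_rate = 0)
  empty <- flip_train(numeric(0), 1)
  x <- render_trace(empty, mm0, seed = 1)
  expect_true(all(x$samples == 0))          # flat at baseline
  ## 5 flips, noise-free: exactly 5 sharp transients above half amplitude
  tr <- flip_train(c(5, 5.4, 5.8, 6.2, 6.6), 1)
  x <- render_trace(tr, mm0, seed = 1)
  d <- abs(diff(x$samples))
  peaks <- which(d > 0.5 * max(d) & d >= c(0, d)[seq_along(d)] &
                   d >= c(d, 0)[seq_along(d) + 1])
  expect_identical(length(peaks), 5L)
  ## doubling gain drift leaves the ground-truth log untouched
  mm1 <- measurement_model(gain_drift_amplitude = 0.3)
  mm2 <- measurement_model(gain_drift_amplitude = 0.6)
  expect_identical(render_trace(tr, mm1, seed = 2)$truth,
                   render_trace(tr, mm2, seed = 2)$truth)
  ## kernel wider than the minimum inter-flip interval is a config error
  expect_error(render_trace(flip_train(c(1, 1.01), 1),
                            measurement_model(kernel_width_s = 0.04)),
               class = "tailflip_configuration_error")
})

test_that("trajectories stay in the arena and frame counts are exact", {
  p <- behavior_profile()
  pos <- simulate_trajectory(p, 1, fps = 10, seed = 3)
  expect_identical(nrow(pos), 600L)          # 1 min at 10 fps
  expect_true(all(pos[, 1] >= 0 & pos[, 1] <= 90))
  expect_true(all(pos[, 2] >= 0 & pos[, 2] <= 80))
  still <- simulate_trajectory(pure_profile(rate = 0), 1, fps = 10, seed = 4,
                               fish_pars = unit_fish())
  expect_true(all(diff(still[, 1]) == 0) && all(diff(still[, 2]) == 0))
  expect_error(simulate_trajectory(p, 1, arena_mm = c(-1, 80)),
               class = "tailflip_parameter_error")
})

test_that("studies are reproducible and reject invalid designs", {
  d <- study_design(list(list(label = "saline", profile = profile_preset("saline"),
                              n_fish = 12),
                         list(label = "acid5", profile = profile_preset("acid5"),
                              n_fish = 6),
                         list(label = "acid10", profile = profile_preset("acid10"),
                              n_fish = 8)),
                    seed = 9)
  s1 <- simulate_study(d)
  s2 <- simulate_study(d)
  expect_identical(s1, s2)                   # same seed, same records
  expect_length(s1$fish, 26L)
  expect_error(study_design(list(list(label = "a", profile = profile_preset("flat"),
                                      n_fish = 2),
                                 list(label = "a", profile = profile_preset("flat"),
                                      n_fish = 2))),
               class = "tailflip_design_error")
  expect_error(study_design(list(list(label = "a", n_fish = 2))),
               class = "tailflip_design_error")
})

test_that("adding a group leaves existing fish streams unchanged", {
  g1 <- list(label = "a", profile = profile_preset("flat"), n_fish = 3)
  g2 <- list(label = "b", profile = profile_preset("acid10"), n_fish = 3)
  one <- simulate_study(study_design(list(g1), seed = 5))
  two <- simulate_study(study_design(list(g1, g2), seed = 5))
  expect_identical(one$fish[[2]], two$fish[[2]])
})

test_that("pre and post distributions are exchangeable under the null", {
  ## no acclimation trend, flat effect curve: per-fish pre and post counts
  ## come from the same law (KS across 200 fish must not reject at 1%)
  p <- behavior_profile(acclimation_trend = 0, response_cv = 0)
  pre <- numeric(200); post <- numeric(200)
  for (i in 1:200) {
    pars <- tailflip:::draw_fish_pars(p, seed = i)
    pre[i] <- mean(simulate_activity_series(p, 30, "pre", seed = 1e5 + i,
                                            fish_pars = pars)$values)
    post[i] <- mean(simulate_activity_series(p, 30, "post", seed = 2e5 + i,
                                             fish_pars = pars)$values)
  }
  expect_gt(suppressWarnings(ks.test(pre, post)$p.value), 0.01)
})

test_that("series-level mean flips/min matches the generator mean", {
  p <- pure_profile(rate = 20)
  v <- unlist(lapply(1:50, function(s)
    simulate_activity_series(p, 20, seed = s, fish_pars = unit_fish())$values))
  expected <- 20 * p$flips_per_burst_mean
  expect_lt(abs(mean(v) - expected) / expected, 0.02)
})

test_that("ground-truth CSV export round-trips events and manifest", {
  d <- study_design(list(list(label = "a", profile = profile_preset("flat"),
                              n_fish = 2)),
                    baseline_min = 2, post_min = 2, seed = 3)
  st <- simulate_study(d, level = "trace")
  dir <- tempfile()
  paths <- write_study_csv(st, dir)
  ev <- read.csv(paths[["events"]])
  expect_setequal(unique(ev$phase), c("pre", "post"))
  n_truth <- sum(vapply(st$fish, function(r)
    length(r$pre$truth$times_s) + length(r$post$truth$times_s), numeric(1)))
  expect_identical(nrow(ev), as.integer(n_truth))
  man <- read.csv(paths[["manifest"]])
  expect_identical(nrow(man), 2L)
  expect_true(all(c("gain", "acclim_amp", "response") %in% names(man)))
})
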