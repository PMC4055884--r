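test_that("speed follows displacement: stationary, straight line, circle", {
  still <- matrix(5, 1200, 2)
  expect_identical(speed_from_trajectory(still, fps = 10)$values, rep(0, 2))
  line <- cbind(seq(0, 1199, by = 1), 0)         # 1 mm per frame at 10 fps
  expect_equal(speed_from_trajectory(line, fps = 10)$values, c(10, 10))
  ## circle of radius r, period T: mean speed 2*pi*r/T within 2%
  r <- 20; T_s <- 10; fps <- 10
  tt <- seq(0, 120 - 1 / fps, by = 1 / fps)
  circ <- cbind(45 + r * cos(2 * pi * tt / T_s), 40 + r * sin(2 * pi * tt / T_s))
  v <- speed_from_trajectory(circ, fps = fps)$values
  expect_lt(max(abs(v - 2 * pi * r / T_s)) / (2 * pi * r / T_s), 0.02)
  expect_error(speed_from_trajectory(cbind(c(0, NA), c(0, 1)), 10),
               class = "tailflip_input_error")
})

test_that("stable window picks the last 20 minutes and its median", {
  pre <- activity_series(1:60, phase = "pre")        # minutes 0..59
  sw <- stable_window(pre, 20)
  expect_identical(sw$bounds, c(40L, 60L))
  expect_identical(sw$median, median(41:60))
  const <- activity_series(rep(7, 30))
  expect_identical(stable_window(const, 20)$median, 7)
  expect_identical(stable_window(const, 30)$median, 7) # window = full series
  expect_error(stable_window(activity_series(1:10), 20),
               class = "tailflip_input_error")
})

test_that("normalization is percent of baseline and guards zero baselines", {
  s <- activity_series(c(40, 20, 40), phase = "post")
  ns <- normalize_activity(s, 40)
  expect_equal(ns$values, c(100, 50, 100))
  expect_equal(ns$minute_since_injection, 30:32)     # recovery offset
  expect_error(normalize_activity(s, 0), class = "tailflip_normalization_error")
  ## invariance to rescaling the fish's raw activity
  k <- 3.7
  ns2 <- normalize_activity(activity_series(k * c(40, 20, 40), phase = "post"),
                            k * 40)
  expect_equal(ns2$values, ns$values)
})

test_that("normalizing a fish's own stable window centres its median at 100", {
  set.seed(11)
  pre <- activity_series(rpois(60, 80), phase = "pre")
  sw <- stable_window(pre)
  z <- 100 * pre$values[pre$minute_index >= sw$bounds[1]] / sw$median
  expect_identical(median(z), 100)
})

test_that("binning drops the trailing partial bin and conserves means", {
  ns <- normalize_activity(activity_series(rep(50, 80), phase = "post"), 50)
  b <- suppressMessages(bin_series(ns, 15))
  expect_identical(nrow(b), 5L)                      # 75 of 80 min used
  expect_identical(b$bin_start_min, c(30, 45, 60, 75, 90))
  expect_true(all(b$value == 100))
  ## equal-size bins: mean of bin values equals overall mean
  set.seed(2)
  ns2 <- normalize_activity(activity_series(rpois(60, 60), phase = "post"), 60)
  b2 <- bin_series(ns2, 15)
  expect_equal(mean(b2$value), mean(ns2$values), tolerance = 1e-12)
  ## idempotence at equal widths: re-binning binned values changes nothing
  expect_equal(suppressMessages(bin_series(ns, 15)), b)
})

test_that("normalize_study excludes fish that cannot be normalized", {
  p <- profile_preset("flat")
  dsg <- study_design(list(list(label = "a", profile = p, n_fish = 3)), seed = 4)
  study <- simulate_study(dsg)
  ## sabotage one fish: an all-zero baseline cannot define a reference
  study$fish[[2]]$pre$values[] <- 0
  b <- normalize_study(study)
  expect_identical(attr(b, "excluded"), "a_02")
  expect_setequal(unique(b$fish_id), c("a_01", "a_03"))
})
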