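test_that("winsorize matches the brute-force sort-and-replace oracle", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 100)
  expect_identical(sort(winsorize(x, 0.1)), c(2, 2, 3, 4, 5, 6, 7, 8, 9, 9))
  expect_identical(winsorize(c(5, 5, 5), 0.1), c(5, 5, 5))
  expect_identical(winsorize(x, 0), x)
  set.seed(31)
  for (n in c(3, 7, 10, 23, 50)) {
    y <- rlnorm(n)
    for (g in c(0, 0.05, 0.1, 0.2, 0.45)) {
      expect_equal(winsorize(y, g), winsorize_oracle(y, g))
    }
  }
  expect_error(winsorize(numeric(0)), class = "tailflip_input_error")
  expect_error(winsorize(1:5, 0.5), class = "tailflip_parameter_error")
})

test_that("winsorized mean and SE agree with direct formula oracles", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 100)
  expect_equal(winsorized_mean(x, 0.1), 5.5)
  expect_equal(winsorized_mean(rep(3.2, 6)), 3.2)
  expect_equal(winsorized_mean(x, 0), mean(x))
  expect_equal(winsorized_se(x, 0.1), winsorized_se_oracle(x, 0.1))
  expect_equal(winsorized_se(x, 0), sd(x) / sqrt(length(x)))
  expect_identical(winsorized_se(rep(2, 8)), 0)
  set.seed(7)
  y <- rexp(17)
  expect_equal(winsorized_se(y, 0.1), winsorized_se_oracle(y, 0.1))
  expect_error(winsorized_se(1), class = "tailflip_input_error")
})

test_that("winsorized estimators are equivariant, resistant and monotone", {
  set.seed(5)
  x <- rlnorm(25)
  a <- -2.5; b <- 7
  expect_equal(winsorized_mean(a * x + b), a * winsorized_mean(x) + b)
  expect_equal(winsorized_se(a * x + b), abs(a) * winsorized_se(x))
  ## breakdown: exploding the single largest value changes nothing (n >= 10)
  y <- x
  y[which.max(y)] <- 1e12
  expect_equal(winsorized_mean(y), winsorized_mean(x))
  ## monotonicity: increasing any value never decreases the mean
  for (i in sample(25, 8)) {
    z <- x
    z[i] <- z[i] + runif(1, 0, 3)
    expect_gte(winsorized_mean(z), winsorized_mean(x) - 1e-12)
  }
})

test_that("winsor_summary tabulates group-by-bin cells", {
  d <- data.frame(group = rep(c("a", "b"), each = 6),
                  bin_start_min = rep(c(30, 45, 60), 4),
                  value = c(100, 90, 80, 104, 94, 84, 50, 45, 40, 54, 49, 44),
                  fish_id = rep(c("f1", "f2", "f3", "f4"), each = 3))
  s <- winsor_summary(d)
  expect_identical(nrow(s), 6L)
  expect_true(all(s$n == 2))
  expect_equal(s$winsorized_mean[s$group == "a" & s$bin_start_min == 30], 102)
})
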