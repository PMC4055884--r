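ld_from <- function(values, groups, bins) {
  ## values: matrix fish x bins
  d <- expand.grid(fish_id = seq_len(nrow(values)), bin = bins)
  d$group <- rep(groups, length(bins))
  d$value <- as.vector(values)
  longitudinal_data(d, fish = "fish_id", group = "group", time = "bin",
                    value = "value")
}

test_that("relative effects match the direct mid-rank oracle", {
  ## A = {1,2}, B = {3,4}, one bin: mean ranks 1.5 and 3.5 over N = 4
  ld <- ld_from(cbind(c(1, 2, 3, 4)), c("A", "A", "B", "B"), 0)
  expect_equal(unname(relative_effects(ld)[, 1]), c(0.25, 0.75))
  ## one group, one bin
  ld1 <- ld_from(cbind(c(5, 1, 9)), rep("A", 3), 0)
  expect_equal(unname(relative_effects(ld1)[1, 1]), 0.5)
  ## identical value multisets between groups at every bin: group symmetry
  ## (ranks are pooled over bins, so the rows must coincide cell by cell,
  ## and when every cell shares one multiset all effects are exactly 0.5)
  v <- cbind(c(1, 2, 3, 1, 2, 3), c(8, 9, 7, 9, 7, 8))
  ld2 <- ld_from(v, rep(c("A", "B"), each = 3), c(0, 15))
  re2 <- relative_effects(ld2)
  expect_equal(re2["A", ], re2["B", ])
  u <- cbind(c(4, 7, 1, 9, 4, 7, 1, 9), c(9, 4, 7, 1, 1, 9, 4, 7))
  ld3 <- ld_from(u, rep(c("A", "B"), each = 4), c(0, 15))
  expect_true(all(relative_effects(ld3) == 0.5))
})

test_that("cell relative effects average to one half", {
  set.seed(13)
  for (i in 1:10) {
    n <- sample(4:8, 2)                       # possibly unbalanced
    v <- matrix(rlnorm(sum(n) * 3), sum(n), 3)
    ld <- ld_from(v, rep(c("A", "B"), n), c(0, 1, 2))
    re <- relative_effects(ld)
    wts <- as.vector(table(ld$grp))           # n-weighted mean is exact
    expect_equal(sum(re * wts) / (ncol(re) * sum(wts)), 0.5)
    if (n[1] == n[2]) expect_equal(mean(re), 0.5)   # unweighted, balanced
  }
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(17)
  v <- matrix(rlnorm(40), 10, 4)
  ld <- ld_from(v, rep(c("A", "B"), each = 5), 1:4)
  ld_t <- ld_from(exp(v / 2) + v^3, rep(c("A", "B"), each = 5), 1:4)
  expect_equal(relative_effects(ld), relative_effects(ld_t))
  for (e in c("group", "time", "interaction")) {
    expect_equal(ats_test(ld, e)$p_value, ats_test(ld_t, e)$p_value)
  }
})

test_that("a large constant shift separates groups decisively", {
  set.seed(19)
  v <- matrix(rnorm(100), 20, 5)
  v[11:20, ] <- v[11:20, ] + 50
  ld <- ld_from(v, rep(c("A", "B"), each = 10), 1:5)
  expect_lt(ats_test(ld, "group")$p_value, 0.001)
  expect_lt(pairwise_group_test(ld, c("A", "B"))$p_value, 0.001)
})

test_that("guards: unknown groups, self pairs, empty subsets, tiny groups", {
  set.seed(23)
  v <- matrix(rnorm(24), 8, 3)
  ld <- ld_from(v, rep(c("A", "B"), each = 4), 1:3)
  expect_error(pairwise_group_test(ld, c("A", "A")),
               class = "tailflip_input_error")
  expect_error(pairwise_group_test(ld, c("A", "C")),
               class = "tailflip_input_error")
  expect_error(window_subset_test(ld, numeric(0)),
               class = "tailflip_input_error")
  expect_error(window_subset_test(ld, 99), class = "tailflip_input_error")
  one <- ld_from(cbind(c(1, 2, 3)), c("A", "A", "B"), 0)
  expect_error(ats_test(one, "group"), class = "tailflip_estimation_error")
})

test_that("window subsets reduce correctly", {
  set.seed(29)
  v <- matrix(rnorm(60), 12, 5)
  v[7:12, ] <- v[7:12, ] + 0.8
  ld <- ld_from(v, rep(c("A", "B"), each = 6), seq(30, 90, by = 15))
  full <- ats_test(ld, "group")
  all_bins <- window_subset_test(ld, ld$times)
  expect_equal(all_bins$statistic, full$statistic)
  expect_equal(all_bins$p_value, full$p_value)
  ## a single-bin subset is a two-sample rank problem: its relative effects
  ## must match the direct two-sample mid-rank computation
  w <- window_subset_test(ld, 45)
  r <- rank(v[, 2])
  expect_equal(unname(w$relative_effects[, 1]),
               (c(mean(r[1:6]), mean(r[7:12])) - 0.5) / 12)
})

test_that("single-bin subset decisions track the exact Wilcoxon test", {
  set.seed(37)
  agree <- 0L
  for (i in 1:40) {
    shift <- sample(c(0, 0, 2.5, 4), 1)
    v <- matrix(rnorm(20), 10, 2)
    v[6:10, ] <- v[6:10, ] + shift
    ld <- ld_from(v, rep(c("A", "B"), each = 5), 1:2)
    p_ats <- window_subset_test(ld, 1)$p_value
    p_w <- wilcox.test(v[1:5, 1], v[6:10, 1], exact = TRUE)$p.value
    agree <- agree + ((p_ats < 0.05) == (p_w < 0.05))
  }
  expect_gte(agree / 40, 0.9)
})

test_that("incomplete fish are removed case-wise with a message", {
  d <- expand.grid(fish_id = paste0("f", 1:6), bin = c(0, 1))
  d$group <- rep(rep(c("A", "B"), each = 3), 2)
  d$value <- rnorm(12)
  d <- d[-2, ]                                # f2 misses bin 0
  expect_message(ld <- longitudinal_data(d, fish = "fish_id", group = "group",
                                         time = "bin", value = "value"),
                 "incomplete")
  expect_identical(attr(ld, "excluded"), "f2")
  expect_identical(nrow(ld$Y), 5L)
})
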