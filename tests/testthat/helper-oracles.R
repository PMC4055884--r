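## Shared fixtures and independent oracles for the test suite.

## greedy one-to-one matching of detected to true events within a tolerance
match_events <- function(truth, detected, tol_s = 0.05) {
  used <- rep(FALSE, length(detected))
  hits <- 0L
  for (t in truth) {
    j <- which(!used & abs(detected - t) <= tol_s)
    if (length(j)) {
      used[j[which.min(abs(detected[j] - t))]] <- TRUE
      hits <- hits + 1L
    }
  }
  list(recall = hits / max(1L, length(truth)),
       precision = hits / max(1L, length(detected)))
}

## brute-force winsorization oracle: sort, replace, restore order
winsorize_oracle <- function(x, gamma) {
  n <- length(x)
  g <- floor(gamma * n)
  s <- sort(x)
  if (g > 0) {
    s[seq_len(g)] <- s[g + 1]
    s[(n - g + 1):n] <- s[n - g]
  }
  s[rank(x, ties.method = "first")]
}

## direct evaluation of the stated Winsorized-SE formula
winsorized_se_oracle <- function(x, gamma) {
  n <- length(x)
  g <- floor(gamma * n)
  sw <- sd(winsorize_oracle(x, gamma))
  sw / ((1 - 2 * g / n) * sqrt(n))
}

## deterministic per-fish latents (gain 1, no acclimation, no response
## heterogeneity) for event-level tests
unit_fish <- function() list(gain = 1, acclim_amp = 0, response = 1)

## a profile with all between/within-fish variability switched off
pure_profile <- function(rate = 10, ...) {
  behavior_profile(baseline_burst_rate = rate, acclimation_trend = 0,
                   between_fish_cv = 0, within_fish_noise_cv = 0,
                   response_cv = 0, ...)
}

## two-group ATS group-effect statistic on pre-ranked data, for the
## permutation oracle (relabels whole fish; ranks are label-free)
ats_group_stat_ranked <- function(R, idx1, Tp) {
  t_bins <- ncol(R)
  R1 <- R[idx1, , drop = FALSE]
  R2 <- R[-idx1, , drop = FALSE]
  pbar <- c(colMeans(R1), colMeans(R2))
  V <- matrix(0, 2 * t_bins, 2 * t_bins)
  V[1:t_bins, 1:t_bins] <- cov(R1) / nrow(R1)
  V[(t_bins + 1):(2 * t_bins), (t_bins + 1):(2 * t_bins)] <- cov(R2) / nrow(R2)
  tr1 <- sum(diag(Tp %*% V))
  if (tr1 <= 0) return(NA_real_)
  drop(pbar %*% Tp %*% pbar) / tr1
}

perm_group_p <- function(Y, n1, draws = 2000, seed = 1) {
  set.seed(seed)
  n <- nrow(Y)
  R <- matrix(rank(Y, ties.method = "average"), n, ncol(Y)) / length(Y)
  Tp <- tailflip:::ats_projection(2, ncol(Y), "group")
  obs <- ats_group_stat_ranked(R, seq_len(n1), Tp)
  cnt <- 0L
  for (b in seq_len(draws)) {
    s <- ats_group_stat_ranked(R, sample(n, n1), Tp)
    if (!is.na(s) && s >= obs) cnt <- cnt + 1L
  }
  (1 + cnt) / (1 + draws)
}

## quick two-group series-level study -> longitudinal dataset
quick_two_group <- function(n_per_group, factor_b = 1, seed = 1,
                            post_min = 80, profile_a = profile_preset("flat")) {
  pb <- profile_a
  pb$effect_curve <- effect_constant(factor_b)
  pb$label <- NULL
  dsg <- study_design(list(list(label = "a", profile = profile_a, n_fish = n_per_group),
                           list(label = "b", profile = pb, n_fish = n_per_group)),
                      post_min = post_min, seed = seed)
  longitudinal_data(normalize_study(simulate_study(dsg)))
}
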