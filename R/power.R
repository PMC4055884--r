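## Simulation-based power and minimal sample size for the full analysis
## chain: simulate a two-group study at the series level (per-minute counts;
## detector bypassed, as normalization cancels detection efficiency),
## normalize, bin, and apply the rank-based pairwise test.

#' Power-analysis specification
#'
#' The default generator is two groups identical except for a sustained
#' multiplicative difference in post-treatment activity of `delta` percent
#' of baseline: the reference group holds its baseline level (flat effect
#' curve) while the comparison group sits `delta` percentage points lower in
#' normalized activity across all post-treatment bins. Variability comes
#' from the shipped behavioral defaults (between- and within-fish CVs,
#' response heterogeneity).
#'
#' @param delta Sustained difference between the groups, percentage points
#'   of normalized activity (>= 0). Default 10.
#' @param n_grid Ascending candidate numbers of fish per group.
#' @param alpha Significance level (default 0.05).
#' @param target_power Power sought by [minimal_n()] (default 0.80,
#'   conventional).
#' @param reps Monte-Carlo replicates per grid point; at least 100 for
#'   reported estimates. Default 500.
#' @param seed Integer seed; every replicate's study seed derives from it.
#' @param profile Template [behavior_profile()] for both groups (effect
#'   curves are overridden by `delta`).
#' @param baseline_min,recovery_min,post_min,bin_width_min Timeline passed
#'   to the simulated designs.
#' @return Object of class `power_spec`.
#' @export
power_spec <- function(delta = 10, n_grid = c(5, 10, 15, 20, 25, 30),
                       alpha = 0.05, target_power = 0.80, reps = 500,
                       seed = 1L, profile = behavior_profile(),
                       baseline_min = 60, recovery_min = 30, post_min = 80,
                       bin_width_min = 15) {
  check_number(delta, "delta", lower = 0)
  if (!is.numeric(n_grid) || length(n_grid) < 1L || any(n_grid < 2) ||
      is.unsorted(n_grid, strictly = TRUE)) {
    stop_tf("tailflip_parameter_error", "`n_grid` must be ascending, all >= 2")
  }
  check_number(alpha, "alpha", lower = 1e-6, upper = 0.5)
  check_number(target_power, "target_power", lower = 1e-6, upper = 1 - 1e-6)
  check_number(reps, "reps", lower = 1)
  structure(list(delta = delta, n_grid = as.integer(n_grid), alpha = alpha,
                 target_power = target_power, reps = as.integer(reps),
                 seed = as.integer(seed), profile = profile,
                 baseline_min = baseline_min, recovery_min = recovery_min,
                 post_min = post_min, bin_width_min = bin_width_min),
            class = "power_spec")
}

power_design <- function(spec, n, seed) {
  ref <- spec$profile
  ref$effect_curve <- effect_constant(1)
  ref$label <- "reference"
  trt <- spec$profile
  trt$effect_curve <- effect_constant(max(0, 1 - spec$delta / 100))
  trt$label <- "treatment"
  study_design(list(list(label = "reference", profile = ref, n_fish = n),
                    list(label = "treatment", profile = trt, n_fish = n)),
               baseline_min = spec$baseline_min,
               recovery_min = spec$recovery_min, post_min = spec$post_min,
               bin_width_min = spec$bin_width_min, seed = seed)
}

#' Estimate power at a given group size
#'
#' Fraction of Monte-Carlo replicates in which the rank-based pairwise test
#' rejects at `alpha`; each replicate simulates both groups at the series
#' level, normalizes each fish to its stable pre-treatment median, bins, and
#' applies [pairwise_group_test()].
#'
#' @param spec A [power_spec()].
#' @param n Fish per group.
#' @return List: `power`, `se` (binomial), `n`, `reps`.
#' @export
estimate_power <- function(spec, n) {
  stopifnot(inherits(spec, "power_spec"))
  check_number(n, "n", lower = 2)
  if (spec$reps < 100) {
    warning("fewer than 100 replicates: low-precision power estimate",
            call. = FALSE)
  }
  rej <- logical(spec$reps)
  for (r in seq_len(spec$reps)) {
    dsg <- power_design(spec, n, seed = derive_seed(spec$seed, r, salt = n))
    study <- simulate_study(dsg, level = "series")
    binned <- normalize_study(study)
    ld <- longitudinal_data(binned)
    p <- pairwise_group_test(ld, c("reference", "treatment"))$p_value
    rej[r] <- is.finite(p) && p < spec$alpha
  }
  pw <- mean(rej)
  list(power = pw, se = sqrt(pw * (1 - pw) / spec$reps), n = as.integer(n),
       reps = spec$reps)
}

#' Minimal sample size reaching the target power
#'
#' Walks the ascending `n_grid`, estimating power at each candidate size,
#' and returns the smallest n whose estimated power reaches
#' `target_power`, together with the whole power curve. Deterministic for a
#' fixed `spec$seed`.
#'
#' @param spec A [power_spec()].
#' @return List: `n_min`, `curve` (data.frame n / power / se / reps), plus
#'   the spec's alpha and target.
#' @export
minimal_n <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  if (spec$delta == 0) {
    stop_tf("tailflip_power_error",
            "delta = 0: target power equals the significance level and is unattainable")
  }
  ests <- lapply(spec$n_grid, function(n) estimate_power(spec, n))
  curve <- do.call(rbind, lapply(ests, function(e)
    data.frame(n = e$n, power = e$power, se = e$se, reps = e$reps)))
  hit <- curve$n[curve$power >= spec$target_power]
  n_min <- if (length(hit)) min(hit) else NA_integer_
  if (is.na(n_min)) {
    stop_tf("tailflip_power_error",
            "no n in the grid reaches power %.2f (max attained %.3f at n = %d); extend n_grid",
            spec$target_power, max(curve$power), curve$n[which.max(curve$power)])
  }
  list(n_min = n_min, curve = curve, alpha = spec$alpha,
       target_power = spec$target_power, delta = spec$delta, seed = spec$seed)
}
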