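#' Pre-treatment baseline trend and heteroscedasticity summary
#'
#' Quantifies the two features of pre-treatment behavior that motivate the
#' stable-window normalization rule: (i) the early decline -- fish are more
#' active at the start of a recording, so activity normalized to the
#' last-`stable_window_min` median sits above 100% early on; and (ii) the
#' early excess variability -- across-fish error bars are several times
#' larger at the beginning of the recording than in the stable window.
#'
#' A cohort of `n_fish` pre-treatment recordings is simulated at the series
#' level with the given profile, each fish is normalized to the median of
#' its own stable window, and two statistics are computed:
#' \describe{
#' \item{elevation_pct}{20% Winsorized mean of all normalized minute values
#'   in the first `early_span_min` minutes, minus 100: the mean percent
#'   elevation of early activity over the stable level.}
#' \item{se_ratio}{Winsorized standard error across fish of the per-fish
#'   mean normalized activity in the first `first_bin_min` minutes, divided
#'   by the same quantity for the stable window.}
#' }
#'
#' @param n_fish Cohort size (default 27).
#' @param seed Integer seed.
#' @param profile A [behavior_profile()] (default: shipped defaults).
#' @param baseline_min Pre-treatment recording length, minutes (default 60).
#' @param stable_window_min Stable window, minutes (default 20).
#' @param early_span_min Early span for the elevation estimate (default 40).
#' @param first_bin_min First recording bin width for the SE ratio
#'   (default 5).
#' @param gamma_per_tail Winsorization fraction (default 0.10).
#' @return List: `elevation_pct`, `se_ratio`, `n_fish`.
#' @export
baseline_trend_summary <- function(n_fish = 27, seed = 1L,
                                   profile = behavior_profile(),
                                   baseline_min = 60, stable_window_min = 20,
                                   early_span_min = 40, first_bin_min = 5,
                                   gamma_per_tail = 0.10) {
  check_number(n_fish, "n_fish", lower = 2)
  dsg <- study_design(list(list(label = "baseline", profile = profile,
                                n_fish = n_fish)),
                      baseline_min = baseline_min, seed = seed)
  study <- simulate_study(dsg, level = "series", phases = "pre")
  early <- numeric(0)
  first_bin <- numeric(n_fish)
  stable <- numeric(n_fish)
  for (i in seq_along(study$fish)) {
    pre <- study$fish[[i]]$pre
    sw <- stable_window(pre, stable_window_min)
    if (sw$median <= 0) {
      first_bin[i] <- NA; stable[i] <- NA
      next
    }
    z <- 100 * pre$values / sw$median
    early <- c(early, z[pre$minute_index < early_span_min])
    first_bin[i] <- mean(z[pre$minute_index < first_bin_min])
    stable[i] <- mean(z[pre$minute_index >= sw$bounds[1]])
  }
  ok <- is.finite(first_bin) & is.finite(stable)
  list(elevation_pct = winsorized_mean(early, gamma_per_tail) - 100,
       se_ratio = winsorized_se(first_bin[ok], gamma_per_tail) /
         winsorized_se(stable[ok], gamma_per_tail),
       n_fish = sum(ok))
}
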