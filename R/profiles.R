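#' Behavioral profile of a treatment group
#'
#' A `behavior_profile` parameterises the generator of burst-structured
#' swimming: zebrafish swim in short bursts of consecutive tail-flips at an
#' instantaneous rate of 2--5 flips/s, with bursts initiated as a Poisson
#' process whose intensity is modulated over time by an acclimation trend
#' (pre-treatment) or a treatment effect curve (post-treatment).
#'
#' The default parameters are calibrated to the assay's reported behavior:
#' untreated fish differ widely in absolute activity (lognormal between-fish
#' gain, CV 0.5); early pre-treatment activity is elevated and decays
#' exponentially so that the first 40 min average about 20% above the
#' last-20-min median, with inflated minute-to-minute variability while the
#' fish acclimates.
#'
#' @param baseline_burst_rate Expected burst initiations per minute for an
#'   average fish at its stable baseline. Default 20 (a swim bout every
#'   3 s, i.e. ~120 flips/min).
#' @param within_burst_flip_rate Length-2 numeric, bounds of the instantaneous
#'   within-burst flip rate in flips/s. Default `c(2, 5)`.
#' @param flips_per_burst_mean Mean number of flips per burst (geometric law
#'   on 1, 2, ...). Together with the flip rate this fixes the burst-duration
#'   distribution. Default 6.
#' @param acclimation_trend Fractional elevation of the burst intensity at the
#'   start of the pre-treatment recording relative to the stable level
#'   (population mean; per-fish amplitudes are lognormal with
#'   `acclimation_cv`). Default 0.65.
#' @param acclimation_tau Exponential decay time constant of the acclimation
#'   elevation, minutes. Default 15.
#' @param acclimation_cv Between-fish CV of the acclimation amplitude.
#'   Default 0.9.
#' @param acclimation_noise_inflation Multiplier on the within-fish noise CV
#'   at recording start, decaying with `acclimation_tau`; models the noisier
#'   behavior of unsettled fish. Default 2.
#' @param effect_curve Function of time since injection (minutes, >= 0)
#'   returning a multiplicative activity factor >= 0. Applied in the
#'   post-treatment phase only. Default: constant 1.
#' @param between_fish_cv CV of the lognormal per-fish baseline activity
#'   multiplier. Default 0.5.
#' @param within_fish_noise_cv CV of the lognormal minute-to-minute intensity
#'   noise within a fish. Default 0.15.
#' @param response_cv CV of the lognormal per-fish post-treatment response
#'   multiplier (fish-level heterogeneity of the treatment response, shared
#'   by all post-treatment minutes of a fish). Default 0.05.
#' @param label Optional group label attached to simulated fish.
#' @return An object of class `behavior_profile`.
#' @seealso [effect_logistic()], [profile_preset()], [simulate_flip_train()]
#' @export
behavior_profile <- function(baseline_burst_rate = 20,
                             within_burst_flip_rate = c(2, 5),
                             flips_per_burst_mean = 6,
                             acclimation_trend = 0.65,
                             acclimation_tau = 15,
                             acclimation_cv = 0.9,
                             acclimation_noise_inflation = 2,
                             effect_curve = effect_constant(1),
                             between_fish_cv = 0.5,
                             within_fish_noise_cv = 0.15,
                             response_cv = 0.05,
                             label = NULL) {
  check_number(baseline_burst_rate, "baseline_burst_rate", lower = 0)
  if (!is.numeric(within_burst_flip_rate) || length(within_burst_flip_rate) != 2L ||
      any(!is.finite(within_burst_flip_rate)) ||
      within_burst_flip_rate[1] <= 0 ||
      within_burst_flip_rate[1] > within_burst_flip_rate[2]) {
    stop_tf("tailflip_parameter_error",
            "`within_burst_flip_rate` must satisfy 0 < low <= high")
  }
  check_number(flips_per_burst_mean, "flips_per_burst_mean", lower = 1)
  check_number(acclimation_trend, "acclimation_trend", lower = 0)
  check_number(acclimation_tau, "acclimation_tau", lower = 1e-6)
  check_number(acclimation_cv, "acclimation_cv", lower = 0)
  check_number(acclimation_noise_inflation, "acclimation_noise_inflation", lower = 0)
  check_number(between_fish_cv, "between_fish_cv", lower = 0)
  check_number(within_fish_noise_cv, "within_fish_noise_cv", lower = 0)
  check_number(response_cv, "response_cv", lower = 0)
  if (!is.function(effect_curve)) {
    stop_tf("tailflip_parameter_error", "`effect_curve` must be a function")
  }
  structure(
    list(baseline_burst_rate = baseline_burst_rate,
         within_burst_flip_rate = within_burst_flip_rate,
         flips_per_burst_mean = flips_per_burst_mean,
         acclimation_trend = acclimation_trend,
         acclimation_tau = acclimation_tau,
         acclimation_cv = acclimation_cv,
         acclimation_noise_inflation = acclimation_noise_inflation,
         effect_curve = effect_curve,
         between_fish_cv = between_fish_cv,
         within_fish_noise_cv = within_fish_noise_cv,
         response_cv = response_cv,
         label = label),
    class = "behavior_profile"
  )
}

#' @export
print.behavior_profile <- function(x, ...) {
  cat("<behavior_profile>",
      if (!is.null(x$label)) paste0(" '", x$label, "'"), "\n", sep = "")
  cat(sprintf("  bursts/min: %.3g   flips/burst (mean): %.3g   flip rate: %g-%g /s\n",
              x$baseline_burst_rate, x$flips_per_burst_mean,
              x$within_burst_flip_rate[1], x$within_burst_flip_rate[2]))
  cat(sprintf("  acclimation: +%.0f%% (tau %g min, fish CV %.2g)\n",
              100 * x$acclimation_trend, x$acclimation_tau, x$acclimation_cv))
  cat(sprintf("  CVs: between-fish %.2g, within-fish %.2g, response %.2g\n",
              x$between_fish_cv, x$within_fish_noise_cv, x$response_cv))
  f <- vapply(c(30, 60, 105), x$effect_curve, numeric(1))
  cat(sprintf("  effect factor at 30/60/105 min post-injection: %.2f / %.2f / %.2f\n",
              f[1], f[2], f[3]))
  invisible(x)
}

#' Treatment effect curves
#'
#' Effect curves map time since injection (minutes) to a multiplicative
#' activity factor. `effect_constant()` is flat; `effect_logistic()` moves
#' from 1 toward an asymptote with a logistic onset, the shape used for the
#' shipped treatment presets (suppression by acid, partial protection by
#' morphine, block of that protection by naloxone).
#'
#' @param factor Constant activity factor (>= 0).
#' @param asymptote Late-time activity factor approached by the curve.
#' @param onset_min Time of half-maximal effect, minutes after injection.
#' @param slope_min Logistic time scale (minutes).
#' @return A function `f(t_min) -> factor`.
#' @export
effect_constant <- function(factor = 1) {
  check_number(factor, "factor", lower = 0)
  force(factor)
  function(t_min) rep_len(factor, length(t_min))
}

#' @rdname effect_constant
#' @export
effect_logistic <- function(asymptote, onset_min = 15, slope_min = 8) {
  check_number(asymptote, "asymptote", lower = 0)
  check_number(onset_min, "onset_min")
  check_number(slope_min, "slope_min", lower = 1e-9)
  function(t_min) {
    w <- 1 / (1 + exp(-(t_min - onset_min) / slope_min))
    1 + (asymptote - 1) * w
  }
}

#' Shipped treatment-group presets
#'
#' Behavioral profiles for the treatment arms of the assay, differing only in
#' their effect curve. Asymptotic normalized activity levels (percent of the
#' pre-treatment baseline) are: saline control 80, 5% acetic acid 65,
#' 10% acetic acid 45, morphine 3 mg/kg + acid 58, morphine 6 mg/kg + acid 70,
#' morphine 6 mg/kg + naloxone 6 mg/kg + acid 48, and `"flat"` (no effect,
#' factor 1) for null simulations.
#'
#' @param preset Character, one of the labels below.
#' @param ... Passed to [behavior_profile()] to override other parameters.
#' @return A `behavior_profile`.
#' @export
profile_preset <- function(preset = c("saline", "acid5", "acid10",
                                      "morphine3_acid", "morphine6_acid",
                                      "morphine6_naloxone_acid", "flat"),
                           ...) {
  preset <- match.arg(preset)
  asym <- c(saline = 0.80, acid5 = 0.65, acid10 = 0.45,
            morphine3_acid = 0.58, morphine6_acid = 0.70,
            morphine6_naloxone_acid = 0.48, flat = 1)[[preset]]
  curve <- if (preset == "flat") effect_constant(1) else effect_logistic(asym)
  behavior_profile(effect_curve = curve, label = preset, ...)
}

#' Forward measurement model of the impedance biosensor channel
#'
#' Describes how a tail-flip train becomes a sampled 100 Hz trace: each flip
#' contributes a sharp biphasic transient, on top of additive Gaussian noise,
#' a slow multiplicative gain drift, and sporadic artifact spikes. The kernel
#' is one windowed sine cycle, 40 ms wide, so its spectrum extends beyond
#' 20 Hz as required to resolve individual flips within a burst.
#'
#' @param sample_rate Samples per second; must exceed twice the 40 Hz upper
#'   band edge. Default 100.
#' @param kernel_width_s Width of the biphasic flip transient in seconds.
#'   Default 0.04.
#' @param kernel_amplitude Peak amplitude of the transient (trace units).
#' @param noise_sd Additive white-noise standard deviation (trace units).
#' @param gain_drift_amplitude Log-amplitude of the slow sinusoidal gain
#'   drift (0 disables).
#' @param gain_drift_period_s Period of the gain drift, seconds.
#' @param artifact_rate Spurious sharp transients per minute (Poisson).
#' @param artifact_amplitude Amplitude of artifact transients.
#' @return An object of class `measurement_model`.
#' @export
measurement_model <- function(sample_rate = 100,
                              kernel_width_s = 0.04,
                              kernel_amplitude = 1,
                              noise_sd = 0.1,
                              gain_drift_amplitude = 0.3,
                              gain_drift_period_s = 600,
                              artifact_rate = 0.5,
                              artifact_amplitude = 2) {
  check_number(sample_rate, "sample_rate", lower = 80 + 1e-9)
  check_number(kernel_width_s, "kernel_width_s", lower = 1e-4)
  check_number(kernel_amplitude, "kernel_amplitude", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(gain_drift_amplitude, "gain_drift_amplitude", lower = 0)
  check_number(gain_drift_period_s, "gain_drift_period_s", lower = 1)
  check_number(artifact_rate, "artifact_rate", lower = 0)
  check_number(artifact_amplitude, "artifact_amplitude", lower = 0)
  ## kernel must be short enough that its spectrum reaches ~1/(2 width) Hz;
  ## 40 ms -> content beyond 20 Hz.
  if (1 / (2 * kernel_width_s) < 10) {
    stop_tf("tailflip_parameter_error",
            "kernel too wide: spectrum would not resolve within-burst flips")
  }
  structure(
    list(sample_rate = sample_rate, kernel_width_s = kernel_width_s,
         kernel_amplitude = kernel_amplitude, noise_sd = noise_sd,
         gain_drift_amplitude = gain_drift_amplitude,
         gain_drift_period_s = gain_drift_period_s,
         artifact_rate = artifact_rate,
         artifact_amplitude = artifact_amplitude),
    class = "measurement_model"
  )
}

#' @export
print.measurement_model <- function(x, ...) {
  cat(sprintf("<measurement_model> %g Hz, kernel %g ms x %.2g, noise sd %.3g\n",
              x$sample_rate, 1000 * x$kernel_width_s, x$kernel_amplitude,
              x$noise_sd))
  cat(sprintf("  gain drift: exp(%.2g sin), period %g s; artifacts %.2g/min x %.2g\n",
              x$gain_drift_amplitude, x$gain_drift_period_s,
              x$artifact_rate, x$artifact_amplitude))
  invisible(x)
}

#' Study design: groups, sample sizes and timeline
#'
#' The timeline mirrors the assay protocol: fish are acclimated to the test
#' chamber for 30 min (unrecorded), a 60 min pre-treatment baseline is
#' recorded, the fish is anesthetized and injected (time 0), allowed 30 min
#' to recover (unrecorded), and post-treatment activity is recorded for
#' 80 min, i.e. until 110 min after the injection.
#'
#' @param groups List of group specifications; each element is a list with
#'   `label` (unique character), `profile` (a [behavior_profile()]), and
#'   `n_fish` (>= 1).
#' @param acclimation_min,baseline_min,recovery_min,post_min Timeline in
#'   minutes; defaults 30 / 60 / 30 / 80.
#' @param bin_width_min Width of reporting bins, minutes (15 for the
#'   biosensor arm, 10 for the video arm).
#' @param seed Integer study seed; per-fish streams are derived from it so
#'   adding a group or fish leaves other fish's data unchanged.
#' @return An object of class `study_design`.
#' @export
study_design <- function(groups,
                         acclimation_min = 30, baseline_min = 60,
                         recovery_min = 30, post_min = 80,
                         bin_width_min = 15, seed = 1L) {
  if (!is.list(groups) || length(groups) < 1L) {
    stop_tf("tailflip_design_error", "`groups` must be a non-empty list")
  }
  labels <- vapply(groups, function(g) as.character(g$label %||% g$profile$label %||% NA_character_),
                   character(1))
  if (anyNA(labels)) stop_tf("tailflip_design_error", "every group needs a label")
  if (anyDuplicated(labels)) {
    stop_tf("tailflip_design_error", "duplicate group labels: %s",
            paste(labels[duplicated(labels)], collapse = ", "))
  }
  groups <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    if (is.null(g$profile) || !inherits(g$profile, "behavior_profile")) {
      stop_tf("tailflip_design_error", "group '%s' has no behavior_profile", labels[i])
    }
    n <- g$n_fish %||% NA
    check_number(n, sprintf("n_fish[%s]", labels[i]), lower = 1)
    list(label = labels[i], profile = g$profile, n_fish = as.integer(n))
  })
  for (nm in c("acclimation_min", "baseline_min", "recovery_min", "post_min")) {
    check_number(get(nm), nm, lower = 0)
  }
  check_number(bin_width_min, "bin_width_min", lower = 1)
  check_number(seed, "seed")
  structure(
    list(groups = groups, acclimation_min = acclimation_min,
         baseline_min = baseline_min, recovery_min = recovery_min,
         post_min = post_min, bin_width_min = bin_width_min,
         seed = as.integer(seed)),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design>\n")
  for (g in x$groups) cat(sprintf("  %-24s n = %d\n", g$label, g$n_fish))
  cat(sprintf("  timeline (min): acclimation %g | baseline %g | injection | recovery %g | post %g\n",
              x$acclimation_min, x$baseline_min, x$recovery_min, x$post_min))
  cat(sprintf("  bins: %g min, seed %d\n", x$bin_width_min, x$seed))
  invisible(x)
}

## time-varying intensity modulation (relative to stable baseline) for a fish
## t_min: minutes since phase start. amp: this fish's acclimation amplitude.
acclimation_factor <- function(t_min, amp, tau) 1 + amp * exp(-t_min / tau)
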