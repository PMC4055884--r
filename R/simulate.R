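## Ground-truthed generator: burst point process -> flip trains -> rendered
## biosensor traces / arena trajectories / per-minute activity series.

#' Tail-flip event train
#'
#' @param times_s Event times in seconds from phase start, strictly increasing.
#' @param duration_min Span of the recording, minutes.
#' @param phase `"pre"` or `"post"`.
#' @param fish_id Label.
#' @param source `"truth"` (generator) or `"detected"`.
#' @param burst_id Optional integer burst membership per event (ground truth
#'   only).
#' @return An object of class `flip_train`.
#' @export
flip_train <- function(times_s, duration_min, phase = "pre", fish_id = "fish1",
                       source = "truth", burst_id = NULL) {
  times_s <- as.numeric(times_s)
  if (length(times_s) && (any(!is.finite(times_s)) || is.unsorted(times_s, strictly = TRUE) ||
                          times_s[1] < 0 || times_s[length(times_s)] > duration_min * 60)) {
    stop_tf("tailflip_input_error",
            "event times must be strictly increasing within [0, duration]")
  }
  phase <- match.arg(phase, c("pre", "post"))
  structure(list(times_s = times_s, duration_min = duration_min, phase = phase,
                 fish_id = fish_id, source = source, burst_id = burst_id),
            class = "flip_train")
}

#' @export
print.flip_train <- function(x, ...) {
  cat(sprintf("<flip_train> %s/%s (%s): %d flips over %g min (%.1f/min)\n",
              x$fish_id, x$phase, x$source, length(x$times_s), x$duration_min,
              length(x$times_s) / x$duration_min))
  invisible(x)
}

#' Sampled biosensor trace
#'
#' @param samples Numeric vector, arbitrary impedance units.
#' @param sample_rate Hz.
#' @param phase,fish_id Metadata.
#' @param truth Optional ground-truth [flip_train()] retained by the
#'   forward model.
#' @export
biosensor_trace <- function(samples, sample_rate = 100, phase = "pre",
                            fish_id = "fish1", truth = NULL) {
  check_number(sample_rate, "sample_rate", lower = 1e-9)
  if (any(!is.finite(samples))) {
    stop_tf("tailflip_input_error", "trace samples must be finite")
  }
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 phase = match.arg(phase, c("pre", "post")),
                 fish_id = fish_id, truth = truth),
            class = "biosensor_trace")
}

#' @export
print.biosensor_trace <- function(x, ...) {
  cat(sprintf("<biosensor_trace> %s/%s: %d samples @ %g Hz (%.1f min)%s\n",
              x$fish_id, x$phase, length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate / 60,
              if (!is.null(x$truth)) sprintf(", truth: %d flips",
                                             length(x$truth$times_s)) else ""))
  invisible(x)
}

#' Per-minute activity series
#'
#' One activity value per minute (tail-flips/min from the biosensor arm, or
#' mm/s from the video arm), indexed by whole minutes from phase start.
#'
#' @param values Non-negative activity values, one per minute.
#' @param minute_index Integer minutes from phase start (0-based); default
#'   `seq_along(values) - 1`.
#' @param phase,fish_id,metric Metadata; `metric` is `"flips"` or `"speed"`.
#' @export
activity_series <- function(values, minute_index = seq_along(values) - 1L,
                            phase = "pre", fish_id = "fish1",
                            metric = c("flips", "speed")) {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop_tf("tailflip_input_error", "activity values must be finite and >= 0")
  }
  if (length(values) != length(minute_index) || anyDuplicated(minute_index)) {
    stop_tf("tailflip_input_error", "one value per minute required")
  }
  structure(list(values = values, minute_index = as.integer(minute_index),
                 phase = match.arg(phase, c("pre", "post")),
                 fish_id = fish_id, metric = match.arg(metric)),
            class = "activity_series")
}

#' @export
print.activity_series <- function(x, ...) {
  cat(sprintf("<activity_series> %s/%s (%s): %d min, mean %.2f\n",
              x$fish_id, x$phase, x$metric, length(x$values), mean(x$values)))
  invisible(x)
}

#' @export
as.data.frame.activity_series <- function(x, ...) {
  data.frame(fish_id = x$fish_id, phase = x$phase, metric = x$metric,
             minute_index = x$minute_index, value = x$values,
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## per-fish latent parameters (drawn once per fish, shared across phases)

draw_fish_pars <- function(profile, seed) {
  with_seed(seed, {
    list(
      gain = rlnorm_cv(1, 1, profile$between_fish_cv),
      acclim_amp = if (profile$acclimation_trend > 0)
        rlnorm_cv(1, profile$acclimation_trend, profile$acclimation_cv) else 0,
      response = rlnorm_cv(1, 1, profile$response_cv)
    )
  })
}

## per-minute burst intensity (bursts/min) and noise CV for one phase
minute_intensity <- function(profile, pars, duration_min, phase, recovery_min = 30) {
  t_mid <- seq_len(ceiling(duration_min)) - 0.5
  if (phase == "pre") {
    mod <- acclimation_factor(t_mid, pars$acclim_amp, profile$acclimation_tau)
    cv <- profile$within_fish_noise_cv *
      (1 + (if (profile$acclimation_trend > 0) profile$acclimation_noise_inflation else 0) *
         exp(-t_mid / profile$acclimation_tau))
    resp <- 1
  } else {
    mod <- profile$effect_curve(recovery_min + t_mid)
    if (any(!is.finite(mod)) || any(mod < 0)) {
      stop_tf("tailflip_parameter_error", "effect_curve returned invalid factors")
    }
    cv <- rep_len(profile$within_fish_noise_cv, length(t_mid))
    resp <- pars$response
  }
  list(lambda = profile$baseline_burst_rate * pars$gain * resp * mod, cv = cv)
}

#' Simulate a tail-flip train
#'
#' Bursts are initiated by an inhomogeneous Poisson process whose intensity is
#' the profile's baseline burst rate modulated by the acclimation trend
#' (pre-treatment) or effect curve (post-treatment) and by lognormal
#' minute-to-minute noise. Each burst carries a geometric number of flips
#' (mean `flips_per_burst_mean`) whose inter-flip intervals are drawn so the
#' instantaneous rate lies within `within_burst_flip_rate` (2--5 flips/s by
#' default, i.e. intervals in 0.2--0.5 s).
#'
#' @param profile A [behavior_profile()].
#' @param duration_min Recording length in minutes (> 0).
#' @param phase `"pre"` or `"post"` (selects acclimation vs effect-curve
#'   modulation).
#' @param seed Integer seed (optional).
#' @param fish_id Label.
#' @param fish_pars Per-fish latent parameters from an enclosing study
#'   simulation; drawn internally when `NULL`.
#' @param recovery_min Minutes between injection and the start of a
#'   post-treatment recording (effect-curve time offset). Default 30.
#' @return A [flip_train()] with ground-truth burst membership.
#' @export
simulate_flip_train <- function(profile, duration_min, phase = c("pre", "post"),
                                seed = NULL, fish_id = "fish1",
                                fish_pars = NULL, recovery_min = 30) {
  phase <- match.arg(phase)
  check_number(duration_min, "duration_min", lower = 1e-9)
  with_seed(seed, {
    if (is.null(fish_pars)) fish_pars <- draw_fish_pars(profile, seed = NULL)
    mi <- minute_intensity(profile, fish_pars, duration_min, phase, recovery_min)
    eps <- rlnorm_cv(length(mi$lambda), 1, mi$cv)
    lam <- mi$lambda * eps
    n_bursts <- rpois(length(lam), lam)
    ## candidate initiation times of an inhomogeneous Poisson process
    starts <- unlist(lapply(seq_along(n_bursts), function(m) {
      if (n_bursts[m] == 0L) return(numeric(0))
      sort(runif(n_bursts[m], (m - 1) * 60, m * 60))
    }), use.names = FALSE)
    times <- numeric(0); bursts <- integer(0)
    p <- 1 / profile$flips_per_burst_mean
    lo <- profile$within_burst_flip_rate[1]; hi <- profile$within_burst_flip_rate[2]
    min_gap <- 1 / hi      # a fish has one tail: bouts cannot overlap, and
    prev_end <- -min_gap   # consecutive bouts are separated like flips are
    for (b in seq_along(starts)) {
      t0 <- max(starts[b], prev_end + min_gap)
      nf <- 1L + rgeom(1, p)
      gaps <- if (nf > 1L) 1 / runif(nf - 1L, lo, hi) else numeric(0)
      tt <- t0 + c(0, cumsum(gaps))
      keep <- tt <= duration_min * 60
      times <- c(times, tt[keep])
      bursts <- c(bursts, rep.int(b, sum(keep)))
      if (any(keep)) prev_end <- max(tt[keep])
    }
    flip_train(times, duration_min, phase, fish_id, "truth", bursts)
  })
}

## biphasic flip transient: positive then negative half, zero mean, with one
## sharp central edge -- the spectral content extends well beyond 20 Hz at
## the default 40 ms width
flip_kernel <- function(mm) {
  k <- max(2L, 2L * round(mm$kernel_width_s * mm$sample_rate / 2))
  mm$kernel_amplitude * rep(c(1, -1), each = k %/% 2L)
}

#' Render a flip train into a sampled biosensor trace
#'
#' Forward model of the measurement channel: each flip contributes one sharp
#' biphasic transient; sporadic artifact spikes, additive Gaussian noise and
#' a slow multiplicative gain drift are then applied. The ground-truth train
#' is retained in the result, untouched by any measurement setting.
#'
#' @param train A [flip_train()].
#' @param mm A [measurement_model()].
#' @param seed Optional integer seed.
#' @return A [biosensor_trace()] with `$truth` set to `train`.
#' @export
render_trace <- function(train, mm = measurement_model(), seed = NULL) {
  fs <- mm$sample_rate
  n <- ceiling(train$duration_min * 60 * fs)
  if (length(train$times_s) > 1L) {
    if (mm$kernel_width_s > min(diff(train$times_s))) {
      stop_tf("tailflip_configuration_error",
              "flip kernel wider than the minimum inter-flip interval")
    }
  }
  with_seed(seed, {
    ker <- flip_kernel(mm)
    x <- numeric(n + 2L * length(ker))
    add_events <- function(x, t_s, ker, amp = 1) {
      if (!length(t_s)) return(x)
      start <- round((t_s - length(ker) / fs / 2) * fs) + length(ker) + 1L
      for (j in seq_along(ker)) {     # kernel is short (~5 samples)
        idx <- start + j - 1L
        add <- amp * ker[j]
        x[idx] <- x[idx] + if (length(add) == 1L) add else add
      }
      x
    }
    x <- add_events(x, train$times_s, ker)
    if (mm$artifact_rate > 0) {
      n_art <- rpois(1, mm$artifact_rate * train$duration_min)
      if (n_art > 0) {
        t_art <- runif(n_art, 0, train$duration_min * 60)
        aker <- mm$artifact_amplitude * c(0, 1, -1, 0)
        x <- add_events(x, t_art, aker)
      }
    }
    x <- x[(length(ker) + 1L):(length(ker) + n)]
    if (mm$noise_sd > 0) x <- x + rnorm(n, 0, mm$noise_sd)
    if (mm$gain_drift_amplitude > 0) {
      phi <- runif(1, 0, 2 * pi)
      tt <- (seq_len(n) - 1) / fs
      x <- x * exp(mm$gain_drift_amplitude *
                     sin(2 * pi * tt / mm$gain_drift_period_s + phi))
    }
    biosensor_trace(x, fs, train$phase, train$fish_id, truth = train)
  })
}

#' Simulate a 2-D arena trajectory for the video arm
#'
#' Correlated random walk in a rectangular arena (default 9 cm x 8 cm,
#' i.e. 90 mm x 80 mm) sampled at `fps` frames per second; the expected
#' per-frame displacement scales with the fish's current activity factor
#' (acclimation trend or effect curve, per-fish gain, minute noise), with
#' reflection at the walls.
#'
#' @param profile A [behavior_profile()].
#' @param duration_min Minutes; `fps * duration_min * 60` must be a whole
#'   number of frames.
#' @param arena_mm Numeric length 2, arena width and height in mm.
#' @param fps Frames per second (default 10; 1 min = 600 frames).
#' @param phase,seed,fish_pars,recovery_min As in [simulate_flip_train()].
#' @param mm_per_flip Distance moved per tail-flip, mm; links swimming speed
#'   to the flip process (default 3).
#' @return Matrix with columns `x`, `y` (mm), one row per frame.
#' @export
simulate_trajectory <- function(profile, duration_min, arena_mm = c(90, 80),
                                fps = 10, phase = c("pre", "post"),
                                seed = NULL, fish_pars = NULL,
                                recovery_min = 30, mm_per_flip = 3) {
  phase <- match.arg(phase)
  check_number(duration_min, "duration_min", lower = 1e-9)
  if (!is.numeric(arena_mm) || length(arena_mm) != 2L || any(arena_mm <= 0)) {
    stop_tf("tailflip_parameter_error", "`arena_mm` must be two positive lengths")
  }
  n_frames <- fps * duration_min * 60
  if (abs(n_frames - round(n_frames)) > 1e-9) {
    stop_tf("tailflip_parameter_error", "fps * duration must give a whole frame count")
  }
  n_frames <- as.integer(round(n_frames))
  with_seed(seed, {
    if (is.null(fish_pars)) fish_pars <- draw_fish_pars(profile, seed = NULL)
    mi <- minute_intensity(profile, fish_pars, duration_min, phase, recovery_min)
    ## expected speed (mm/s) per minute: flips/s * mm per flip
    eps <- rlnorm_cv(length(mi$lambda), 1, mi$cv)
    v_min <- mi$lambda * eps / 60 * profile$flips_per_burst_mean * mm_per_flip
    frame_minute <- pmin(length(v_min), (seq_len(n_frames) - 1L) %/% (fps * 60) + 1L)
    v <- v_min[frame_minute]
    pos <- matrix(0, n_frames, 2L, dimnames = list(NULL, c("x", "y")))
    pos[1L, ] <- arena_mm / 2
    if (all(v == 0)) {
      pos[] <- rep(arena_mm / 2, each = n_frames)
      return(pos)
    }
    heading <- runif(1, 0, 2 * pi)
    turn <- rnorm(n_frames, 0, 0.6)
    step <- v / fps * rexp(n_frames)   # bursty step lengths, mean v*dt
    for (i in seq_len(n_frames - 1L)) {
      heading <- heading + turn[i]
      p <- pos[i, ] + step[i] * c(cos(heading), sin(heading))
      for (d in 1:2) {                 # reflect at walls
        if (p[d] < 0) p[d] <- -p[d]
        if (p[d] > arena_mm[d]) p[d] <- 2 * arena_mm[d] - p[d]
        p[d] <- min(max(p[d], 0), arena_mm[d])
      }
      pos[i + 1L, ] <- p
    }
    pos
  })
}

#' Simulate per-minute activity directly (detector bypassed)
#'
#' Fast series-level route used for power analysis and cohort-level
#' calibration: per-minute flip counts are drawn from the compound Poisson
#' law implied by the burst process (Poisson bursts, geometric flips per
#' burst) without rendering or detecting a trace.
#'
#' @inheritParams simulate_flip_train
#' @return An [activity_series()] of flips/min.
#' @export
simulate_activity_series <- function(profile, duration_min,
                                     phase = c("pre", "post"), seed = NULL,
                                     fish_id = "fish1", fish_pars = NULL,
                                     recovery_min = 30) {
  phase <- match.arg(phase)
  check_number(duration_min, "duration_min", lower = 1e-9)
  with_seed(seed, {
    if (is.null(fish_pars)) fish_pars <- draw_fish_pars(profile, seed = NULL)
    mi <- minute_intensity(profile, fish_pars, duration_min, phase, recovery_min)
    eps <- rlnorm_cv(length(mi$lambda), 1, mi$cv)
    nb <- rpois(length(mi$lambda), mi$lambda * eps)
    p <- 1 / profile$flips_per_burst_mean
    extra <- ifelse(nb > 0, rnbinom(length(nb), size = pmax(nb, 1L), prob = p), 0L)
    flips <- nb + ifelse(nb > 0, extra, 0L)
    activity_series(flips, phase = phase, fish_id = fish_id, metric = "flips")
  })
}

#' Simulate a whole study
#'
#' Generates every fish of a [study_design()]: per-fish latent parameters
#' (baseline gain, acclimation amplitude, response multiplier) are drawn once
#' and shared between the pre- and post-treatment phases; per-fish RNG
#' streams are derived from the study seed so results are reproducible and a
#' fish's data do not depend on how many other fish are simulated.
#'
#' @param design A [study_design()].
#' @param level `"series"` simulates per-minute counts directly;
#'   `"trace"` additionally renders biosensor traces (with ground truth) from
#'   event-level flip trains.
#' @param phases Which phases to simulate (default both).
#' @param mm [measurement_model()] used when `level = "trace"`.
#' @return An object of class `study_data`: a list with `design` and `fish`,
#'   the latter one record per fish holding group, fish_id, latent truth and
#'   the simulated `pre`/`post` objects.
#' @export
simulate_study <- function(design, level = c("series", "trace"),
                           phases = c("pre", "post"),
                           mm = measurement_model()) {
  level <- match.arg(level)
  phases <- match.arg(phases, several.ok = TRUE)
  fish <- list()
  for (gi in seq_along(design$groups)) {
    g <- design$groups[[gi]]
    for (fi in seq_len(g$n_fish)) {
      fid <- sprintf("%s_%02d", g$label, fi)
      seed_pars <- derive_seed(design$seed, fi, salt = gi * 7L)
      pars <- draw_fish_pars(g$profile, seed_pars)
      rec <- list(fish_id = fid, group = g$label, truth = pars)
      for (ph in phases) {
        dur <- if (ph == "pre") design$baseline_min else design$post_min
        seed_ph <- derive_seed(design$seed, fi, salt = gi * 7L + match(ph, c("pre", "post")))
        if (level == "series") {
          rec[[ph]] <- simulate_activity_series(
            g$profile, dur, phase = ph, seed = seed_ph, fish_id = fid,
            fish_pars = pars, recovery_min = design$recovery_min)
        } else {
          tr <- simulate_flip_train(
            g$profile, dur, phase = ph, seed = seed_ph, fish_id = fid,
            fish_pars = pars, recovery_min = design$recovery_min)
          rec[[ph]] <- render_trace(tr, mm, seed = derive_seed(seed_ph, 1L, salt = 13L))
        }
      }
      fish[[length(fish) + 1L]] <- rec
    }
  }
  structure(list(design = design, fish = fish, level = level), class = "study_data")
}

#' @export
print.study_data <- function(x, ...) {
  cat(sprintf("<study_data> %d fish in %d group(s), level '%s'\n",
              length(x$fish), length(x$design$groups), x$level))
  invisible(x)
}
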