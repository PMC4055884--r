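## Per-minute activity metrics: speed from trajectories, stable-baseline
## selection, fish-wise normalization, and binning into recording periods.

#' Swimming speed from a centroid trajectory
#'
#' Speed is the change in position in two dimensions: per-frame Euclidean
#' displacement times the frame rate, averaged within each minute.
#'
#' @param positions Two-column matrix (x, y in mm), one row per frame.
#' @param fps Frames per second.
#' @param phase,fish_id Metadata.
#' @return An [activity_series()] in mm/s (`metric = "speed"`).
#' @export
speed_from_trajectory <- function(positions, fps = 10, phase = "pre",
                                  fish_id = "fish1") {
  if (!is.matrix(positions) || ncol(positions) != 2L || nrow(positions) < 2L) {
    stop_tf("tailflip_input_error", "`positions` must be a 2-column matrix with >= 2 rows")
  }
  if (any(!is.finite(positions))) {
    stop_tf("tailflip_input_error", "non-finite coordinates")
  }
  check_number(fps, "fps", lower = 1e-9)
  disp <- sqrt(rowSums(diff(positions)^2))
  speed <- disp * fps                      # mm/s, one per frame transition
  minute <- (seq_along(speed) - 1L) %/% as.integer(round(fps * 60))
  ## a 1-min movie of 600 frames yields 599 transitions; keep minutes with at
  ## least 90% of their transitions
  cnt <- table(minute)
  ok_min <- as.integer(names(cnt))[cnt >= 0.9 * fps * 60]
  sel <- minute %in% ok_min
  v <- vapply(split(speed[sel], minute[sel]), mean, numeric(1))
  activity_series(v, minute_index = as.integer(names(v)), phase = phase,
                  fish_id = fish_id, metric = "speed")
}

#' Stable pre-treatment window and its median
#'
#' Fish are more active at the start of a recording session; the baseline
#' used for normalization is therefore taken from the final, stable part of
#' the pre-treatment recording: the last `window_min` minutes (default 20),
#' whose median defines the fish's reference activity.
#'
#' @param pre An [activity_series()] from the pre-treatment phase.
#' @param window_min Window length in minutes (default 20).
#' @return List with `bounds` (half-open minute interval `[from, to)`) and
#'   `median`.
#' @export
stable_window <- function(pre, window_min = 20) {
  check_number(window_min, "window_min", lower = 1)
  n <- length(pre$values)
  if (n < window_min) {
    stop_tf("tailflip_input_error",
            "series (%d min) shorter than the stable window (%g min)", n, window_min)
  }
  last <- max(pre$minute_index)
  from <- last + 1L - as.integer(window_min)
  sel <- pre$minute_index >= from
  list(bounds = c(from, last + 1L), median = median(pre$values[sel]))
}

#' Normalize activity to the pre-treatment baseline
#'
#' Each value is expressed as a percentage of the fish's own stable
#' pre-treatment median, removing the large between-fish differences in
#' absolute activity. A non-positive baseline cannot normalize and raises a
#' `tailflip_normalization_error`; callers exclude (and report) such fish.
#'
#' @param series An [activity_series()] (typically post-treatment).
#' @param baseline_median Stable pre-treatment median of the same fish (> 0).
#' @param time_offset_min Minutes between the reference time (injection) and
#'   minute 0 of `series`; post-treatment recordings start after the
#'   30 min anesthesia recovery, so the default is 30 for post series and 0
#'   should be used for pre series.
#' @return An object of class `normalized_series`: percent values with
#'   `minute_since_injection` timestamps.
#' @export
normalize_activity <- function(series, baseline_median,
                               time_offset_min = if (series$phase == "post") 30 else 0) {
  if (!is.numeric(baseline_median) || length(baseline_median) != 1L ||
      !is.finite(baseline_median) || baseline_median <= 0) {
    stop_tf("tailflip_normalization_error",
            "baseline median must be > 0 (fish '%s' excluded)", series$fish_id)
  }
  structure(list(values = 100 * series$values / baseline_median,
                 minute_since_injection = series$minute_index + time_offset_min,
                 phase = series$phase, fish_id = series$fish_id,
                 metric = series$metric),
            class = "normalized_series")
}

#' @export
print.normalized_series <- function(x, ...) {
  cat(sprintf("<normalized_series> %s/%s: %d min, median %.1f%%\n",
              x$fish_id, x$phase, length(x$values), median(x$values)))
  invisible(x)
}

#' Bin a normalized series into recording periods
#'
#' Minute values are averaged within consecutive bins of `bin_width_min`
#' (15 min for the biosensor arm, 10 min for the video arm), timestamped by
#' bin start relative to injection. A trailing partial bin (e.g. the last
#' 5 min of an 80 min recording binned at 15 min) is dropped with a message.
#'
#' @param ns A `normalized_series` (see [normalize_activity()]).
#' @param bin_width_min Bin width in minutes.
#' @param quiet Suppress the partial-bin message.
#' @return A data.frame with columns `fish_id`, `bin_start_min`, `value`,
#'   `n_minutes`.
#' @export
bin_series <- function(ns, bin_width_min = 15, quiet = FALSE) {
  check_number(bin_width_min, "bin_width_min", lower = 1)
  t0 <- min(ns$minute_since_injection)
  rel <- ns$minute_since_injection - t0
  bin <- floor(rel / bin_width_min)
  n_full <- floor(length(ns$values) / bin_width_min)
  dropped <- length(ns$values) - n_full * bin_width_min
  if (dropped > 0 && !quiet) {
    message(sprintf("bin_series: dropping trailing partial bin (%d min) for fish '%s'",
                    as.integer(dropped), ns$fish_id))
  }
  keep <- bin < n_full
  if (!any(keep)) {
    stop_tf("tailflip_input_error", "series shorter than one bin")
  }
  v <- vapply(split(ns$values[keep], bin[keep]), mean, numeric(1))
  data.frame(fish_id = ns$fish_id,
             bin_start_min = t0 + as.numeric(names(v)) * bin_width_min,
             value = as.numeric(v),
             n_minutes = as.integer(bin_width_min),
             stringsAsFactors = FALSE)
}

#' Normalize and bin every fish of a simulated or detected study
#'
#' Convenience wrapper running the per-fish analysis chain: stable-window
#' baseline from the pre-treatment series, normalization of the
#' post-treatment series, and binning. Fish whose baseline median is not
#' positive or whose recordings are missing are excluded and listed in the
#' `excluded` attribute (the tested-versus-analyzed distinction of the
#' assay's reporting).
#'
#' @param study A `study_data` from [simulate_study()], or a list of records
#'   with `fish_id`, `group`, `pre` and `post` [activity_series()] (e.g.
#'   detected counts).
#' @param stable_window_min Stable-window length, minutes (default 20).
#' @param bin_width_min Bin width (default: the design's, else 15).
#' @return Long data.frame (`fish_id`, `group`, `bin_start_min`, `value`)
#'   with attribute `excluded`.
#' @export
normalize_study <- function(study, stable_window_min = 20, bin_width_min = NULL) {
  recs <- if (inherits(study, "study_data")) study$fish else study
  if (is.null(bin_width_min)) {
    bin_width_min <- if (inherits(study, "study_data"))
      study$design$bin_width_min else 15
  }
  out <- list(); excluded <- character(0)
  for (r in recs) {
    pre <- r$pre; post <- r$post
    ok <- !is.null(pre) && !is.null(post) &&
      inherits(pre, "activity_series") && inherits(post, "activity_series")
    if (!ok) { excluded <- c(excluded, r$fish_id); next }
    sw <- tryCatch(stable_window(pre, stable_window_min), error = function(e) NULL)
    if (is.null(sw) || sw$median <= 0) { excluded <- c(excluded, r$fish_id); next }
    ns <- tryCatch(normalize_activity(post, sw$median),
                   error = function(e) NULL)
    if (is.null(ns)) { excluded <- c(excluded, r$fish_id); next }
    b <- bin_series(ns, bin_width_min, quiet = TRUE)
    b$group <- r$group %||% NA_character_
    out[[length(out) + 1L]] <- b
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    stop_tf("tailflip_input_error", "no fish could be normalized")
  }
  attr(res, "excluded") <- excluded
  res
}
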