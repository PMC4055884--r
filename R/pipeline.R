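## Orchestration: configured, seeded, logged end-to-end runs
## (simulate -> detect -> normalize -> summarize -> test), plus plain-text
## interchange (events/manifest CSV, YAML study configs).

#' Assemble a run configuration
#'
#' @param study A [study_design()].
#' @param detector A [detector_config()] (used when `level = "trace"`).
#' @param level `"series"` (per-minute counts, detector bypassed) or
#'   `"trace"` (render and detect).
#' @param stable_window_min Stable-baseline window, minutes.
#' @param gamma_per_tail Winsorization fraction per tail.
#' @param alpha Significance level for reported tests.
#' @param out_dir Output directory (created on demand).
#' @return Object of class `run_config`.
#' @export
run_config <- function(study, detector = detector_config(),
                       level = c("series", "trace"),
                       stable_window_min = 20, gamma_per_tail = 0.10,
                       alpha = 0.05, out_dir = tempfile("tailflip_run_")) {
  structure(list(study = study, detector = detector,
                 level = match.arg(level),
                 stable_window_min = stable_window_min,
                 gamma_per_tail = gamma_per_tail, alpha = alpha,
                 out_dir = out_dir),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Checks every embedded invariant (group labels and profiles, timeline,
#' Nyquist-limited detector band, analysis settings) and returns a
#' human-readable report instead of stopping at the first failure.
#'
#' @param config A [run_config()] (or a bare [study_design()]).
#' @return data.frame (`check`, `ok`, `detail`) of class
#'   `tailflip_validation`; `all(report$ok)` indicates a runnable config.
#' @export
validate_config <- function(config) {
  if (inherits(config, "study_design")) config <- run_config(config)
  checks <- list()
  add <- function(check, ok, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(check = check, ok = ok,
                                                 detail = detail,
                                                 stringsAsFactors = FALSE)
  }
  s <- config$study
  add("study class", inherits(s, "study_design"))
  if (inherits(s, "study_design")) {
    labs <- vapply(s$groups, `[[`, character(1), "label")
    add("unique group labels", !anyDuplicated(labs), paste(labs, collapse = ", "))
    add("profiles present",
        all(vapply(s$groups, function(g) inherits(g$profile, "behavior_profile"),
                   logical(1))))
    add("n_fish >= 1", all(vapply(s$groups, `[[`, integer(1), "n_fish") >= 1L))
    add("post-injection span = recovery + post",
        s$recovery_min + s$post_min > 0,
        sprintf("%g + %g = %g min after injection",
                s$recovery_min, s$post_min, s$recovery_min + s$post_min))
    add("baseline covers stable window",
        s$baseline_min >= config$stable_window_min,
        sprintf("baseline %g min vs window %g min",
                s$baseline_min, config$stable_window_min))
    add("bin width divides usable post span",
        s$post_min >= s$bin_width_min,
        sprintf("%g min bins in %g min (%d full bins)",
                s$bin_width_min, s$post_min, floor(s$post_min / s$bin_width_min)))
  }
  d <- config$detector
  fs <- 100
  add("detector band below Nyquist",
      inherits(d, "detector_config") && d$band[2] < fs / 2,
      sprintf("band %g-%g Hz at %g Hz sampling", d$band[1], d$band[2], fs))
  add("refractory below minimum credible inter-flip interval",
      d$refractory_s <= 0.2, sprintf("%g s", d$refractory_s))
  add("gamma_per_tail in [0, 0.5)",
      config$gamma_per_tail >= 0 && config$gamma_per_tail < 0.5)
  add("alpha in (0, 0.5]", config$alpha > 0 && config$alpha <= 0.5)
  rep <- do.call(rbind, checks)
  class(rep) <- c("tailflip_validation", "data.frame")
  rep
}

#' @export
print.tailflip_validation <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf("[%s] %s%s\n", if (x$ok[i]) "ok" else "FAIL", x$check[i],
                if (nzchar(x$detail[i])) paste0(" (", x$detail[i], ")") else ""))
  }
  cat(if (all(x$ok)) "configuration valid\n" else "configuration INVALID\n")
  invisible(x)
}

#' Run a study end-to-end
#'
#' Simulates (or detects, at trace level) every fish, normalizes to stable
#' pre-treatment medians, bins, writes the Winsorized group-by-bin summary
#' (`summary.csv`), fits the rank-based longitudinal model with all pairwise
#' group contrasts (`tests.json`), and records provenance (config hash,
#' seed, package version) in every output. Reruns with the same
#' configuration are bit-identical.
#'
#' @param config A [run_config()]; validated first (invalid configs stop
#'   before any simulation).
#' @return Invisibly, a list with `summary`, `tests`, `binned`, `excluded`,
#'   `provenance`, and the paths written.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  rep <- validate_config(config)
  if (!all(rep$ok)) {
    stop_tf("tailflip_config_error", "invalid configuration:\n%s",
            paste(sprintf("- %s", rep$check[!rep$ok]), collapse = "\n"))
  }
  prov <- list(
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    seed = config$study$seed,
    package_version = as.character(utils::packageVersion("tailflip")))
  stage <- "simulate"
  out <- tryCatch({
    study <- simulate_study(config$study, level = config$level)
    recs <- if (config$level == "trace") {
      stage <- "detect"
      detect_study(study, config$detector)
    } else study$fish
    stage <- "normalize"
    binned <- normalize_study(recs,
                              stable_window_min = config$stable_window_min,
                              bin_width_min = config$study$bin_width_min)
    stage <- "summarize"
    summ <- winsor_summary(binned, config$gamma_per_tail)
    stage <- "test"
    ld <- longitudinal_data(binned)
    fit <- if (nlevels(ld$grp) >= 2L) rank_longitudinal(ld) else
      list(relative_effects = relative_effects(ld))
    pairs <- list()
    if (nlevels(ld$grp) >= 2L) {
      cmb <- utils::combn(levels(ld$grp), 2L)
      for (j in seq_len(ncol(cmb))) {
        r <- pairwise_group_test(ld, cmb[, j])
        pairs[[paste(cmb[, j], collapse = " vs ")]] <-
          list(statistic = r$statistic, df1 = r$df1, df2 = r$df2,
               p_value = r$p_value)
      }
    }
    list(study = study, binned = binned, summary = summ, fit = fit,
         pairs = pairs, excluded = attr(binned, "excluded"))
  }, tailflip_error = function(e) {
    stop_tf("tailflip_pipeline_error", "stage '%s' failed: %s",
            stage, conditionMessage(e))
  })
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  summ <- out$summary
  summ$config_hash <- prov$config_hash
  summ$seed <- prov$seed
  summary_path <- file.path(config$out_dir, "summary.csv")
  utils::write.csv(summ, summary_path, row.names = FALSE)
  tests <- list(provenance = prov,
                excluded_fish = as.list(out$excluded),
                relative_effects = out$fit$relative_effects,
                effects = lapply(out$fit[intersect(names(out$fit),
                                                   c("group", "time", "interaction"))],
                                 function(r) list(statistic = r$statistic,
                                                  df1 = r$df1, df2 = r$df2,
                                                  p_value = r$p_value)),
                pairwise = out$pairs)
  tests_path <- file.path(config$out_dir, "tests.json")
  jsonlite::write_json(tests, tests_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, matrix = "rowmajor")
  invisible(list(summary = out$summary, tests = tests, binned = out$binned,
                 excluded = out$excluded, provenance = prov,
                 paths = c(summary = summary_path, tests = tests_path)))
}

#' Write ground-truth events and manifest CSV files
#'
#' Plain-text interchange for a trace-level study: `events.csv` (fish_id,
#' phase, time_s) from the generator's ground-truth trains and
#' `manifest.csv` (fish_id, group, latent truth parameters).
#'
#' @param study `study_data` simulated with `level = "trace"`.
#' @param dir Output directory.
#' @return The two file paths, invisibly.
#' @export
write_study_csv <- function(study, dir) {
  stopifnot(inherits(study, "study_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ev <- list(); man <- list()
  for (r in study$fish) {
    for (ph in c("pre", "post")) {
      tr <- r[[ph]]
      train <- if (inherits(tr, "biosensor_trace")) tr$truth else
        if (inherits(tr, "flip_train")) tr else NULL
      if (!is.null(train) && length(train$times_s)) {
        ev[[length(ev) + 1L]] <- data.frame(fish_id = r$fish_id, phase = ph,
                                            time_s = train$times_s)
      }
    }
    man[[length(man) + 1L]] <- data.frame(
      fish_id = r$fish_id, group = r$group, gain = r$truth$gain,
      acclim_amp = r$truth$acclim_amp, response = r$truth$response)
  }
  events_path <- file.path(dir, "events.csv")
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, ev), events_path, row.names = FALSE)
  utils::write.csv(do.call(rbind, man), manifest_path, row.names = FALSE)
  invisible(c(events = events_path, manifest = manifest_path))
}

#' Build a study design from a YAML config
#'
#' Minimal schema: `seed`, optional timeline fields, and a `groups` list of
#' `{label, preset (or profile parameter overrides), n_fish}`.
#'
#' @param path YAML file.
#' @return A [study_design()].
#' @export
study_config_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  groups <- lapply(cfg$groups, function(g) {
    pr_args <- g$profile %||% list()
    profile <- if (!is.null(g$preset)) {
      do.call(profile_preset, c(list(preset = g$preset), pr_args))
    } else do.call(behavior_profile, pr_args)
    list(label = g$label, profile = profile, n_fish = g$n_fish)
  })
  study_design(groups,
               acclimation_min = cfg$acclimation_min %||% 30,
               baseline_min = cfg$baseline_min %||% 60,
               recovery_min = cfg$recovery_min %||% 30,
               post_min = cfg$post_min %||% 80,
               bin_width_min = cfg$bin_width_min %||% 15,
               seed = cfg$seed %||% 1L)
}
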