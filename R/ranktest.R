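## Rank-based nonparametric marginal model for the group x time repeated
## measures design: pooled mid-ranks, relative treatment effects, and
## ANOVA-type statistics (ATS) with moment-matched (Box-type) degrees of
## freedom. Within-fish dependence enters through the empirical covariance
## of each fish's rank vector; no distributional model is placed on the
## activity values themselves, so the analysis is invariant under strictly
## monotone transformations and robust to the extreme values typical of
## behavioral recordings.

#' Assemble a longitudinal dataset
#'
#' Builds the fish-by-time-bin layout used by the rank-based tests from a
#' long data.frame such as the output of [normalize_study()]. Each fish must
#' belong to exactly one group and contribute at most one value per time
#' bin; fish with missing bins are removed (complete-case per fish, the
#' assay's tested-versus-analyzed convention) and listed in the `excluded`
#' attribute.
#'
#' @param data Long data.frame.
#' @param fish,group,time,value Column names (defaults match
#'   [normalize_study()] output).
#' @return An object of class `longitudinal_data`: value matrix `Y`
#'   (fish x bins), factor `grp`, bin labels `times`, fish ids.
#' @export
longitudinal_data <- function(data, fish = "fish_id", group = "group",
                              time = "bin_start_min", value = "value") {
  cols <- c(fish, group, time, value)
  if (!all(cols %in% names(data))) {
    stop_tf("tailflip_input_error", "missing columns: %s",
            paste(setdiff(cols, names(data)), collapse = ", "))
  }
  d <- data.frame(fish = as.character(data[[fish]]),
                  group = as.character(data[[group]]),
                  time = data[[time]], value = as.numeric(data[[value]]),
                  stringsAsFactors = FALSE)
  if (anyNA(d)) stop_tf("tailflip_input_error", "NAs in longitudinal data")
  gmap <- unique(d[, c("fish", "group")])
  if (anyDuplicated(gmap$fish)) {
    stop_tf("tailflip_input_error", "a fish appears in more than one group")
  }
  if (anyDuplicated(d[, c("fish", "time")])) {
    stop_tf("tailflip_input_error", "more than one value per fish and time bin")
  }
  times <- sort(unique(d$time))
  fish_ids <- unique(d$fish)
  Y <- matrix(NA_real_, length(fish_ids), length(times),
              dimnames = list(fish_ids, as.character(times)))
  Y[cbind(match(d$fish, fish_ids), match(d$time, times))] <- d$value
  complete <- !apply(Y, 1L, anyNA)
  excluded <- fish_ids[!complete]
  if (length(excluded)) {
    message(sprintf("longitudinal_data: excluding %d incomplete fish (%s)",
                    length(excluded), paste(excluded, collapse = ", ")))
  }
  Y <- Y[complete, , drop = FALSE]
  grp <- factor(gmap$group[match(rownames(Y), gmap$fish)])
  structure(list(Y = Y, grp = grp, times = times, fish_ids = rownames(Y)),
            class = "longitudinal_data", excluded = excluded)
}

#' @export
print.longitudinal_data <- function(x, ...) {
  cat(sprintf("<longitudinal_data> %d fish x %d bins, groups: %s\n",
              nrow(x$Y), ncol(x$Y),
              paste(sprintf("%s (n=%d)", levels(x$grp), table(x$grp)),
                    collapse = ", ")))
  invisible(x)
}

## projection matrix for the hypothesis of no group / time / interaction
## effect on the vector of cell effects (group-major ordering)
ats_projection <- function(a, t, effect) {
  Pa <- diag(a) - 1 / a
  Pt <- diag(t) - 1 / t
  Jt <- matrix(1 / t, t, t)
  Ja <- matrix(1 / a, a, a)
  switch(effect,
         group = kronecker(Pa, Jt),
         time = kronecker(Ja, Pt),
         interaction = kronecker(Pa, Pt),
         stop_tf("tailflip_parameter_error", "unknown effect '%s'", effect))
}

## core: pooled mid-ranks, cell means, block-diagonal covariance; returns
## everything needed for relative effects and the ATS of any contrast
ats_core <- function(Y, grp) {
  n <- nrow(Y); t_bins <- ncol(Y); N <- n * t_bins
  a <- nlevels(grp)
  cnt <- tabulate(grp, nbins = a)
  if (any(cnt < 2L)) {
    stop_tf("tailflip_estimation_error",
            "each group needs at least 2 fish with complete data (got %s)",
            paste(cnt, collapse = "/"))
  }
  R <- matrix(rank(Y, ties.method = "average"), n, t_bins) / N
  pbar <- numeric(a * t_bins)
  V <- matrix(0, a * t_bins, a * t_bins)
  for (i in seq_len(a)) {
    Ri <- R[as.integer(grp) == i, , drop = FALSE]
    rows <- ((i - 1L) * t_bins + 1L):(i * t_bins)
    pbar[rows] <- colMeans(Ri)
    V[rows, rows] <- stats::cov(Ri) / nrow(Ri)
  }
  list(pbar = pbar, V = V, a = a, t = t_bins, N = N, n_i = cnt)
}

ats_quadform <- function(core, effect) {
  Tp <- ats_projection(core$a, core$t, effect)
  TV <- Tp %*% core$V
  tr1 <- sum(diag(TV))
  if (tr1 <= .Machine$double.eps) {     # degenerate (e.g. all values tied)
    return(list(statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
                p_value = 1))
  }
  Fstat <- drop(core$pbar %*% Tp %*% core$pbar) / tr1
  df1 <- tr1^2 / sum(TV * t(TV))        # tr(TVTV)
  if (effect == "group") {
    denom <- 0
    for (i in seq_len(core$a)) {
      rows <- ((i - 1L) * core$t + 1L):(i * core$t)
      denom <- denom + sum(diag(Tp[rows, rows, drop = FALSE] %*%
                                  core$V[rows, rows, drop = FALSE]))^2 /
        (core$n_i[i] - 1L)
    }
    df2 <- if (denom > 0) tr1^2 / denom else Inf
  } else {
    df2 <- Inf                          # sub-plot effects: F(df1, Inf)
  }
  list(statistic = Fstat, df1 = df1, df2 = df2,
       p_value = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

#' Relative treatment effects
#'
#' Mid-ranks are computed once over all observations pooled; the relative
#' effect of cell (group, bin) is `(mean rank in the cell - 1/2) / N`, the
#' probability that a random observation from that cell exceeds a random
#' observation from the pooled reference distribution. Values near 0.5 mean
#' "typical of the whole experiment"; the n-weighted average over all cells
#' is exactly 0.5.
#'
#' @param data A [longitudinal_data()].
#' @return Matrix (group x time bin) of relative effects in (0, 1).
#' @export
relative_effects <- function(data) {
  stopifnot(inherits(data, "longitudinal_data"))
  core <- ats_core(data$Y, data$grp)
  p <- (core$pbar * core$N - 0.5) / core$N
  matrix(p, core$a, core$t, byrow = TRUE,
         dimnames = list(levels(data$grp), as.character(data$times)))
}

#' ANOVA-type test for group, time, or interaction effects
#'
#' Quadratic form on the pooled mid-ranks with the contrast projection of
#' the chosen effect, referred to an F distribution with moment-matched
#' degrees of freedom (Box approximation). The whole-plot (group) effect
#' uses an estimated denominator df; the sub-plot effects (time,
#' group-by-time interaction) use an infinite denominator df, the standard
#' convention for this family. Within-fish dependence over bins is captured
#' by the empirical covariance of each fish's rank vector.
#'
#' @param data A [longitudinal_data()].
#' @param effect `"group"`, `"time"`, or `"interaction"`.
#' @return Object of class `rank_model_result`: statistic, df pair, p-value,
#'   relative-effects matrix, group sizes.
#' @export
ats_test <- function(data, effect = c("group", "time", "interaction")) {
  stopifnot(inherits(data, "longitudinal_data"))
  effect <- match.arg(effect)
  if (nlevels(data$grp) < 2L && effect != "time") {
    stop_tf("tailflip_estimation_error",
            "'%s' effect needs at least two groups", effect)
  }
  if (ncol(data$Y) < 2L && effect != "group") {
    stop_tf("tailflip_estimation_error",
            "'%s' effect needs at least two time bins", effect)
  }
  core <- ats_core(data$Y, data$grp)
  if (any(core$n_i < 4L)) {
    warning("fewer than 4 fish in a group: ATS degrees of freedom are unstable",
            call. = FALSE)
  }
  q <- ats_quadform(core, effect)
  structure(list(effect = effect, statistic = q$statistic, df1 = q$df1,
                 df2 = q$df2, p_value = q$p_value,
                 relative_effects = relative_effects(data),
                 n_per_group = stats::setNames(core$n_i, levels(data$grp)),
                 alpha = 0.05),
            class = "rank_model_result")
}

#' @export
print.rank_model_result <- function(x, ...) {
  cat(sprintf("<rank_model_result> ATS %s effect\n", x$effect))
  cat(sprintf("  F = %.4g, df = (%.2f, %s), p = %.4g\n",
              x$statistic, x$df1,
              if (is.finite(x$df2)) sprintf("%.2f", x$df2) else "Inf",
              x$p_value))
  cat("  relative effects:\n")
  print(round(x$relative_effects, 3))
  invisible(x)
}

#' Fit all three ATS effects at once
#'
#' @param data A [longitudinal_data()].
#' @return List with `relative_effects` and one `rank_model_result` per
#'   effect (`group`, `time`, `interaction`).
#' @export
rank_longitudinal <- function(data) {
  effects <- c("group", "time", "interaction")
  if (nlevels(data$grp) < 2L) effects <- "time"
  if (ncol(data$Y) < 2L) effects <- "group"
  res <- lapply(effects, function(e) ats_test(data, e))
  names(res) <- effects
  c(list(relative_effects = relative_effects(data)), res)
}

#' Pairwise group comparison
#'
#' ATS group-effect test restricted to two groups. No multiplicity
#' correction is applied by default (the assay reports unadjusted pairwise
#' comparisons); pass the resulting p-values to [stats::p.adjust()] with
#' `method = "holm"` if a familywise guarantee is wanted.
#'
#' @param data A [longitudinal_data()].
#' @param pair Character vector of two distinct group labels.
#' @return The pairwise `rank_model_result`.
#' @export
pairwise_group_test <- function(data, pair) {
  stopifnot(inherits(data, "longitudinal_data"))
  if (length(pair) != 2L || pair[1] == pair[2]) {
    stop_tf("tailflip_input_error", "`pair` must name two distinct groups")
  }
  if (!all(pair %in% levels(data$grp))) {
    stop_tf("tailflip_input_error", "unknown group label(s): %s",
            paste(setdiff(pair, levels(data$grp)), collapse = ", "))
  }
  keep <- data$grp %in% pair
  sub <- structure(list(Y = data$Y[keep, , drop = FALSE],
                        grp = droplevels(data$grp[keep]),
                        times = data$times,
                        fish_ids = data$fish_ids[keep]),
                   class = "longitudinal_data")
  ats_test(sub, "group")
}

#' Test restricted to a subset of time bins
#'
#' Re-runs the ATS on the named bins only (mid-ranks recomputed within the
#' subset); used e.g. to ask whether doses separate during the late part of
#' the recording period.
#'
#' @param data A [longitudinal_data()].
#' @param bins Subset of `data$times`.
#' @param effect Effect to test (default `"group"`).
#' @return A `rank_model_result`.
#' @export
window_subset_test <- function(data, bins, effect = "group") {
  stopifnot(inherits(data, "longitudinal_data"))
  if (!length(bins) || !all(bins %in% data$times)) {
    stop_tf("tailflip_input_error", "`bins` must be a non-empty subset of data$times")
  }
  sel <- data$times %in% bins
  sub <- structure(list(Y = data$Y[, sel, drop = FALSE], grp = data$grp,
                        times = data$times[sel], fish_ids = data$fish_ids),
                   class = "longitudinal_data")
  ats_test(sub, effect)
}
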