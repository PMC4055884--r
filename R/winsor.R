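## 20% Winsorized location summaries: the g smallest values are replaced by
## the (g+1)-th smallest and the g largest by the (g+1)-th largest,
## g = floor(gamma * n) per tail (gamma = 0.10 for the "20% Winsorized"
## estimator, which replaces the 10% highest and 10% lowest values).

#' Winsorize a sample
#'
#' @param x Numeric vector (n >= 1), NAs not allowed.
#' @param gamma_per_tail Fraction winsorized in each tail, in `[0, 0.5)`.
#'   Default 0.10 (the "20% Winsorized" estimator).
#' @return Vector of the same length with the `floor(gamma * n)` most extreme
#'   values in each tail replaced by the nearest retained order statistic.
#' @export
winsorize <- function(x, gamma_per_tail = 0.10) {
  if (length(x) < 1L || anyNA(x)) {
    stop_tf("tailflip_input_error", "x must be non-empty without NAs")
  }
  check_number(gamma_per_tail, "gamma_per_tail", lower = 0, upper = 0.5 - 1e-12)
  n <- length(x)
  g <- floor(gamma_per_tail * n)
  if (g == 0L) return(x)
  s <- sort(x)
  lo <- s[g + 1L]; hi <- s[n - g]
  pmin(pmax(x, lo), hi)
}

#' Winsorized mean
#'
#' Arithmetic mean of the winsorized sample; with `gamma_per_tail = 0.10`
#' this is the 20% Winsorized mean used for all graphical summaries of
#' normalized activity. Less sensitive to the extreme values (high activity
#' bursts in small time periods) typical of behavioral recordings.
#'
#' @inheritParams winsorize
#' @export
winsorized_mean <- function(x, gamma_per_tail = 0.10) {
  mean(winsorize(x, gamma_per_tail))
}

#' Standard error of the Winsorized mean
#'
#' Tukey--McLaughlin form: `s_w / ((1 - 2 g/n) * sqrt(n))`, where `s_w` is
#' the standard deviation (divisor n-1) of the winsorized sample and
#' `g = floor(gamma * n)`. Reduces to the classical `s/sqrt(n)` at
#' `gamma = 0`.
#'
#' @inheritParams winsorize
#' @export
winsorized_se <- function(x, gamma_per_tail = 0.10) {
  if (length(x) < 2L) {
    stop_tf("tailflip_input_error", "winsorized_se needs n >= 2")
  }
  n <- length(x)
  g <- floor(gamma_per_tail * n)
  sw <- stats::sd(winsorize(x, gamma_per_tail))
  sw / ((1 - 2 * g / n) * sqrt(n))
}

#' Winsorized group-by-bin summary table
#'
#' The numeric counterpart of the assay's time-course figures: for each
#' group and bin, the number of fish and the 20% Winsorized mean of
#' normalized activity with its standard error.
#'
#' @param binned Long data.frame from [normalize_study()] (columns `group`,
#'   `bin_start_min`, `value`).
#' @param gamma_per_tail Per-tail winsorization fraction, default 0.10.
#' @return data.frame with `group`, `bin_start_min`, `n`, `winsorized_mean`,
#'   `winsorized_se`.
#' @export
winsor_summary <- function(binned, gamma_per_tail = 0.10) {
  stopifnot(all(c("group", "bin_start_min", "value") %in% names(binned)))
  sp <- split(binned, list(binned$group, binned$bin_start_min), drop = TRUE)
  out <- lapply(sp, function(d) {
    data.frame(group = d$group[1], bin_start_min = d$bin_start_min[1],
               n = nrow(d),
               winsorized_mean = winsorized_mean(d$value, gamma_per_tail),
               winsorized_se = if (nrow(d) >= 2L)
                 winsorized_se(d$value, gamma_per_tail) else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$group, res$bin_start_min), , drop = FALSE]
  rownames(res) <- NULL
  res
}
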