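# Cycloheximide-chase densitometry: normalization and first-order
# degradation kinetics with half-life estimation.

#' Normalize a cycloheximide-chase time course
#'
#' Each band density is divided by its loading-control density, then
#' expressed as percent of the same replicate's t = 0 ratio, so every
#' replicate starts at exactly 100%. Per-time mean and SEM (n = replicate
#' count) across replicates are reported alongside.
#'
#' @param raw Data frame with columns `replicate`, `time_h`,
#'   `target_density`, `loading_density` (densities > 0; each replicate
#'   must include t = 0).
#' @return List with `points` (raw plus a `percent` column) and `summary`
#'   (per `time_h`: `mean`, `sem`, `n`).
#' @export
normalize_chase <- function(raw) {
  need <- c("replicate", "time_h", "target_density", "loading_density")
  if (!all(need %in% names(raw)))
    stop_input("chase table needs columns: %s", paste(need, collapse = ", "))
  if (any(raw$target_density <= 0 | raw$loading_density <= 0))
    stop_input("densities must be positive")
  if (any(raw$time_h < 0)) stop_input("negative time")
  ratio <- raw$target_density / raw$loading_density
  out <- raw
  out$percent <- NA_real_
  for (r in unique(raw$replicate)) {
    i <- raw$replicate == r
    i0 <- i & raw$time_h == 0
    if (!any(i0))
      stop_input("replicate '%s' has no t = 0 point", r)
    out$percent[i] <- 100 * ratio[i] / ratio[i0][1]
  }
  agg <- aggregate(percent ~ time_h, data = out, FUN = function(x)
    c(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)), n = length(x)))
  summary <- data.frame(time_h = agg$time_h,
                        mean = agg$percent[, "mean"],
                        sem = ifelse(is.na(agg$percent[, "sem"]), 0,
                                     agg$percent[, "sem"]),
                        n = agg$percent[, "n"])
  list(points = out, summary = summary[order(summary$time_h), ])
}

#' Fit first-order decay to a normalized chase series
#'
#' Fits `N(t) = 100 * exp(-k * t)` by nonlinear least squares with the
#' intercept pinned at 100 (the normalization guarantees t = 0 is 100%);
#' set `fix_intercept = FALSE` for an unconstrained intercept. A rate
#' below `k_tol` is reported as no detectable decay within the chase
#' window (half-life `Inf`).
#'
#' @param series Output of [normalize_chase()], or a data frame with
#'   `time_h` and `percent` columns.
#' @param fix_intercept Pin the intercept at 100 (default `TRUE`).
#' @param k_tol Detection tolerance on k in /h (default 1e-4).
#' @param conf_level Confidence level for the Wald interval on k.
#' @return List of class `decay_fit`: `k` (/h), `half_life` (h; `Inf` when
#'   no decay is detectable), `detectable`, `k_ci`, `residual_sd`, `n`.
#' @export
fit_decay <- function(series, fix_intercept = TRUE, k_tol = 1e-4,
                      conf_level = 0.95) {
  d <- if (is.list(series) && !is.data.frame(series) &&
           !is.null(series$points))
    data.frame(time_h = series$points$time_h,
               percent = series$points$percent)
  else as.data.frame(series)
  if (!all(c("time_h", "percent") %in% names(d)))
    stop_input("series needs 'time_h' and 'percent' columns")
  if (length(unique(d$time_h)) < 3)
    stop_input("need >= 3 distinct time points to fit decay")
  # log-linear start value (guarded against non-positive values)
  pos <- d$percent > 0
  k0 <- tryCatch({
    sl <- stats::coef(stats::lm(log(percent) ~ time_h, d[pos, ]))[["time_h"]]
    max(-sl, 1e-6)
  }, error = function(e) 1e-3)
  fit <- if (fix_intercept) {
    minpack.lm::nlsLM(percent ~ 100 * exp(-k * time_h), data = d,
                      start = list(k = k0), lower = c(k = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    minpack.lm::nlsLM(percent ~ n0 * exp(-k * time_h), data = d,
                      start = list(n0 = 100, k = k0),
                      lower = c(n0 = 0, k = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  est <- stats::coef(fit)
  k <- unname(est[["k"]])
  se <- tryCatch(summary(fit)$coefficients["k", "Std. Error"],
                 error = function(e) NA_real_)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  detectable <- k >= k_tol
  structure(list(
    k = k,
    half_life = if (detectable) log(2) / k else Inf,
    detectable = detectable,
    k_ci = c(lower = max(0, k - z * se), upper = k + z * se),
    residual_sd = stats::sigma(fit),
    n0 = if (fix_intercept) 100 else unname(est[["n0"]]),
    n = nrow(d)), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$detectable)
    cat(sprintf("first-order decay: k = %.4g /h, half-life = %.3g h\n",
                x$k, x$half_life))
  else cat("no detectable decay within the chase window\n")
  invisible(x)
}

#' Predicted percent remaining at a chase time
#'
#' @param fit A [fit_decay()] result.
#' @param t Time in hours (>= 0).
#' @return `100 * exp(-k t)` in percent.
#' @export
percent_remaining <- function(fit, t) {
  if (any(t < 0)) stop_input("negative time")
  100 * exp(-fit$k * t)
}

#' Percent change in half-life between two fits
#'
#' Positive values mean the mutant degrades faster (shorter half-life).
#'
#' @param reference,mutant [fit_decay()] results.
#' @return List with `percent_reduction` (`100 * (1 - t_mut / t_ref)`),
#'   `ref_half_life`, `mut_half_life` and a `flag` when either fit shows
#'   no detectable decay.
#' @export
compare_halflife <- function(reference, mutant) {
  flag <- NULL
  if (!reference$detectable && !mutant$detectable) {
    flag <- "neither protein shows detectable decay"
    pct <- 0
  } else if (!reference$detectable) {
    # stable reference, decaying mutant: any decay is a reduction
    flag <- "reference shows no detectable decay; reduction computed vs a stable reference"
    pct <- 100
  } else if (!mutant$detectable) {
    flag <- "mutant shows no detectable decay (at least as stable as reference)"
    pct <- 0
  } else {
    pct <- 100 * (1 - mutant$half_life / reference$half_life)
  }
  list(percent_reduction = pct,
       ref_half_life = reference$half_life,
       mut_half_life = mutant$half_life,
       flag = flag)
}
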