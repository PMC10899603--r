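#' Construct a DSF melt curve
#'
#' @param temperature ascending temperatures in degrees C within \[20, 100\].
#' @param fluorescence fluorescence readings (arbitrary units).
#' @param variant variant identifier.
#' @param replicate replicate identifier.
#' @return Object of class `melt_curve`: data frame with attributes
#'   `variant` and `replicate`.
#' @export
melt_curve <- function(temperature, fluorescence, variant = "WT",
                       replicate = 1L) {
  stopifnot(length(temperature) == length(fluorescence))
  if (length(temperature) < 10) stop("melt curve needs >= 10 points")
  if (any(diff(temperature) <= 0))
    stop("temperatures must be strictly increasing")
  if (min(temperature) < 20 || max(temperature) > 100)
    stop("temperatures must lie within [20, 100] C")
  out <- data.frame(temperature = temperature, fluorescence = fluorescence)
  attr(out, "variant") <- as.character(variant)
  attr(out, "replicate") <- replicate
  class(out) <- c("melt_curve", "data.frame")
  out
}

## smoothed local slope dF/dT; window must be odd >= 1. `valid` marks slope
## entries computed from fully smoothed values (edge points are unsmoothed
## and would otherwise dominate the peak search on noisy curves).
smoothed_derivative <- function(temperature, fluorescence, window = 7) {
  f <- fluorescence
  n <- length(f)
  valid <- rep(TRUE, n - 1)
  if (window > 1) {
    k <- rep(1 / window, window)
    sm <- stats::filter(f, k, sides = 2)
    f <- ifelse(is.na(sm), f, as.numeric(sm))
    hw <- (window - 1) %/% 2
    idx <- seq_len(n - 1)
    valid <- idx > hw & idx < n - hw
    if (!any(valid)) valid <- rep(TRUE, n - 1)
  }
  dT <- diff(temperature)
  list(t_mid = (temperature[-1] + temperature[-n]) / 2,
       dfdt = diff(f) / dT, valid = valid)
}

## index of the derivative peak, restricted to the smoothed interior
derivative_peak <- function(der) {
  cand <- which(der$valid)
  cand[which.max(der$dfdt[cand])]
}

#' Fit a Boltzmann sigmoid to a DSF melt curve
#'
#' Fits `F(T) = base + amp / (1 + exp((tm - T)/slope))` by bounded nonlinear
#' least squares. Data beyond the global fluorescence maximum are excluded
#' (post-transition aggregation decay); initialization comes from the
#' smoothed-derivative peak, with deterministic restarts on failure.
#'
#' @param curve a [melt_curve()].
#' @return Object of class `melt_fit` with elements `tm`, `slope`, `amplitude`,
#'   `baseline`, `residual_norm`, `method = "sigmoid"`, `variant`,
#'   `replicate`, `curve`, `fitted`.
#' @export
fit_melt_sigmoid <- function(curve) {
  stopifnot(inherits(curve, "melt_curve"))
  tt <- curve$temperature
  ff <- curve$fluorescence
  ## truncate at the global fluorescence maximum
  imax <- which.max(ff)
  tt <- tt[1:imax]; ff <- ff[1:imax]
  if (length(tt) < 6) stop("no-transition: curve peaks at its start")
  der <- smoothed_derivative(tt, ff)
  if (max(der$dfdt[der$valid]) <= 0)
    stop("no-transition: no rising transition in melt curve")
  ipk <- derivative_peak(der)
  tm0 <- der$t_mid[ipk]
  base0 <- min(ff)
  amp0 <- max(ff) - min(ff)
  slope0 <- max(amp0 / (4 * der$dfdt[ipk]), 0.05)
  dat <- data.frame(T = tt, F = ff)
  lower <- c(base = -Inf, amp = 1e-12, tm = min(tt), slope = 1e-3)
  upper <- c(base = Inf, amp = Inf, tm = max(tt),
             slope = (max(tt) - min(tt)))
  starts <- list(
    c(base = base0, amp = amp0, tm = tm0, slope = slope0),
    c(base = base0, amp = amp0, tm = tm0, slope = slope0 * 2),
    c(base = base0, amp = amp0, tm = tm0 + 2, slope = slope0 * 0.5),
    c(base = base0, amp = amp0, tm = tm0 - 2, slope = 1)
  )
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(F ~ base + amp / (1 + exp((tm - T) / slope)),
                        data = dat, start = as.list(st),
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("fit-failure: sigmoid fit did not converge (start tm ",
         round(tm0, 2), " C, slope ", round(slope0, 3), ")")
  cf <- stats::coef(fit)
  structure(list(
    tm = unname(cf["tm"]), slope = unname(cf["slope"]),
    amplitude = unname(cf["amp"]), baseline = unname(cf["base"]),
    residual_norm = sqrt(sum(stats::residuals(fit)^2)),
    method = "sigmoid",
    variant = attr(curve, "variant"), replicate = attr(curve, "replicate"),
    curve = data.frame(temperature = tt, fluorescence = ff),
    fitted = stats::fitted(fit)
  ), class = "melt_fit")
}

#' Melt temperature by smoothed-derivative peak
#'
#' Cross-check estimator: Tm is the temperature of the maximum of the locally
#' smoothed dF/dT, on the same truncated (pre-aggregation) window as the
#' sigmoid fit. `smooth_window = 1` is the raw finite-difference argmax.
#'
#' @param curve a [melt_curve()].
#' @param smooth_window odd moving-average width in points (default 7).
#' @return A `melt_fit` with `method = "derivative"` (slope/amplitude/baseline
#'   taken from the raw curve summaries).
#' @export
tm_by_derivative <- function(curve, smooth_window = 7) {
  stopifnot(inherits(curve, "melt_curve"))
  tt <- curve$temperature
  ff <- curve$fluorescence
  imax <- which.max(ff)
  tt <- tt[1:imax]; ff <- ff[1:imax]
  if (length(tt) < 3) stop("no-transition: curve peaks at its start")
  der <- smoothed_derivative(tt, ff, window = smooth_window)
  if (max(der$dfdt[der$valid]) <= 0)
    stop("no-transition: no rising transition in melt curve")
  ipk <- derivative_peak(der)
  structure(list(
    tm = der$t_mid[ipk], slope = NA_real_,
    amplitude = max(ff) - min(ff), baseline = min(ff),
    residual_norm = NA_real_, method = "derivative",
    variant = attr(curve, "variant"), replicate = attr(curve, "replicate"),
    curve = data.frame(temperature = tt, fluorescence = ff),
    fitted = NULL
  ), class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat("DSF melt fit (", x$method, ") for variant ", x$variant,
      ", replicate ", x$replicate, "\n", sep = "")
  cat(sprintf("  Tm = %.2f C", x$tm))
  if (x$method == "sigmoid")
    cat(sprintf("  slope = %.3f C  amplitude = %.3g  baseline = %.3g",
                x$slope, x$amplitude, x$baseline))
  cat("\n")
  invisible(x)
}

#' @export
coef.melt_fit <- function(object, ...) {
  c(tm = object$tm, slope = object$slope, amplitude = object$amplitude,
    baseline = object$baseline)
}

#' @export
predict.melt_fit <- function(object, newdata = NULL, ...) {
  if (object$method != "sigmoid")
    stop("predict() requires a sigmoid melt fit")
  tt <- if (is.null(newdata)) object$curve$temperature else newdata$temperature
  object$baseline + object$amplitude /
    (1 + exp((object$tm - tt) / object$slope))
}

#' @export
residuals.melt_fit <- function(object, ...) {
  if (is.null(object$fitted)) stop("no fitted values for this method")
  object$curve$fluorescence - object$fitted
}

#' @export
plot.melt_fit <- function(x, ...) {
  graphics::plot(x$curve$temperature, x$curve$fluorescence,
                 xlab = "Temperature (C)", ylab = "Fluorescence (a.u.)",
                 main = paste0(x$variant, ": Tm = ",
                               sprintf("%.2f", x$tm), " C"), ...)
  if (!is.null(x$fitted))
    graphics::lines(x$curve$temperature, x$fitted, col = "steelblue", lwd = 2)
  graphics::abline(v = x$tm, lty = 2)
  invisible(x)
}

#' Aggregate replicate Tm estimates for one variant
#'
#' @param estimates list of `melt_fit` objects (or numeric Tm vector), all
#'   from the same variant.
#' @param wildtype_mean mean wildtype Tm in degrees C.
#' @param variant variant id (required when `estimates` is numeric).
#' @param mutations character vector of mutations carried by the variant.
#' @param activity retained activity as a fraction of wildtype (optional).
#' @return Object of class `stability_record`: list with `variant`,
#'   `mutations`, `tm_mean`, `tm_sem` (sd/sqrt(n); 0 and flagged when n = 1),
#'   `n_replicates`, `delta_tm`, `activity`, `sem_flagged`.
#' @export
aggregate_variant <- function(estimates, wildtype_mean, variant = NULL,
                              mutations = character(), activity = NA_real_) {
  if (is.numeric(estimates)) {
    tms <- estimates
    if (is.null(variant)) stop("variant id required for numeric input")
  } else {
    stopifnot(length(estimates) >= 1)
    vars <- vapply(estimates, function(e) e$variant, character(1))
    if (length(unique(vars)) != 1)
      stop("mixed variant ids in estimates: ", paste(unique(vars),
                                                     collapse = ", "))
    if (is.null(variant)) variant <- vars[1]
    tms <- vapply(estimates, function(e) e$tm, numeric(1))
  }
  n <- length(tms)
  sem <- if (n > 1) stats::sd(tms) / sqrt(n) else 0
  structure(list(
    variant = variant, mutations = mutations,
    tm_mean = mean(tms), tm_sem = sem, n_replicates = n,
    delta_tm = mean(tms) - wildtype_mean, activity = activity,
    sem_flagged = n == 1
  ), class = "stability_record")
}

#' @export
print.stability_record <- function(x, ...) {
  cat(sprintf("%s: Tm = %.2f +/- %.3f C (n = %d), dTm = %+.2f C\n",
              x$variant, x$tm_mean, x$tm_sem, x$n_replicates, x$delta_tm))
  invisible(x)
}

## position encoded in a mutation string like "E75P"
mutation_position <- function(mut) {
  as.integer(sub("^[A-Z](\\d+)[A-Z]$", "\\1", mut))
}

#' Select mutations to combine into a stabilized variant
#'
#' Takes single-mutant stability records, keeps those with
#' `delta_tm >= delta_tm_min` and retained activity >= `activity_min`,
#' resolves conflicts at a shared position in favour of the larger delta-Tm,
#' and returns the mutation plan ordered by position.
#'
#' @param records list of `stability_record` objects (single mutants; the
#'   wildtype reference may be included and is ignored).
#' @param delta_tm_min minimum Tm shift in degrees C (default 1.0).
#' @param activity_min minimum retained activity fraction (default 0.8).
#' @return Character vector of mutations (possibly empty), ordered by
#'   position.
#' @export
select_combination <- function(records, delta_tm_min = 1.0,
                               activity_min = 0.8) {
  if (length(records) == 0) stop("empty record list")
  singles <- Filter(function(r) length(r$mutations) == 1, records)
  passing <- Filter(function(r) {
    r$delta_tm >= delta_tm_min &&
      (is.na(r$activity) || r$activity >= activity_min)
  }, singles)
  if (length(passing) == 0) return(character())
  muts <- vapply(passing, function(r) r$mutations, character(1))
  dtm <- vapply(passing, function(r) r$delta_tm, numeric(1))
  pos <- vapply(muts, mutation_position, integer(1))
  keep <- vapply(split(seq_along(muts), pos),
                 function(idx) idx[which.max(dtm[idx])], integer(1))
  sel <- muts[keep]
  sel[order(pos[keep])]
}
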