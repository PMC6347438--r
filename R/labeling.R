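# Labeling-run mass balance and kinetics.
#
# A labeling run is the dose-calibrator record of one radiolabeling
# experiment: activity added at t = 0, then measured activity in the washed
# cell fraction, the original incubation supernatant, and up to three wash
# supernatants. All mass-balance quantities are computed on activities
# decay-corrected to run start, so runs with different measurement times are
# comparable.

.compartment_levels <- c("cells", "supernatant", "wash_1", "wash_2", "wash_3",
                         "plasma")

#' Assemble a labeling run from calibrator measurements
#'
#' @param nuclide A [radionuclide()].
#' @param measurements A data.frame with columns `compartment` (one of
#'   `cells`, `supernatant`, `wash_1`..`wash_3`, `plasma`), `activity_mbq`
#'   (>= 0) and `t_min` (minutes from run start, >= 0).
#' @param initial_activity_mbq Activity added at t = 0 (MBq); used for the
#'   mass-balance check and the recovery diagnostic.
#' @param balance_tol Tolerance for the mass-balance check: the
#'   decay-corrected compartment sum may exceed `initial_activity_mbq` by at
#'   most this relative amount (default 5%, dose-calibrator accuracy scale).
#'
#' @return An object of class `"labeling_run"`.
#' @export
labeling_run <- function(nuclide, measurements, initial_activity_mbq,
                         balance_tol = 0.05) {
  stopifnot(inherits(nuclide, "radionuclide"), is.data.frame(measurements))
  req <- c("compartment", "activity_mbq", "t_min")
  if (!all(req %in% names(measurements))) {
    stop("`measurements` needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  m <- measurements[req]
  m$compartment <- as.character(m$compartment)
  bad <- setdiff(m$compartment, .compartment_levels)
  if (length(bad)) {
    stop("unknown compartment(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(m$activity_mbq < 0)) stop("activities must be >= 0", call. = FALSE)
  if (any(m$t_min < 0)) stop("measurement times must be >= 0", call. = FALSE)
  if (sum(m$compartment == "cells") != 1L) {
    stop("a labeling run needs exactly one `cells` measurement", call. = FALSE)
  }
  if (sum(m$compartment == "supernatant") > 1L) {
    stop("at most one `supernatant` measurement", call. = FALSE)
  }
  if (sum(startsWith(m$compartment, "wash_")) > 3L) {
    stop("at most three wash measurements", call. = FALSE)
  }
  if (!is.numeric(initial_activity_mbq) || initial_activity_mbq < 0) {
    stop("`initial_activity_mbq` must be >= 0", call. = FALSE)
  }
  run <- structure(
    list(nuclide = nuclide, measurements = m,
         initial_activity = as.numeric(initial_activity_mbq)),
    class = "labeling_run"
  )
  corrected <- sum(corrected_activities(run))
  if (initial_activity_mbq > 0 &&
      corrected > initial_activity_mbq * (1 + balance_tol)) {
    stop(sprintf(
      "mass balance violated: decay-corrected compartment sum %.3f MBq exceeds initial %.3f MBq by more than %.0f%%",
      corrected, initial_activity_mbq, 100 * balance_tol), call. = FALSE)
  }
  run
}

#' @export
print.labeling_run <- function(x, ...) {
  cat(sprintf("<labeling_run> %s, %.3g MBq added, %d measurements\n",
              x$nuclide$name, x$initial_activity, nrow(x$measurements)))
  print(x$measurements, row.names = FALSE)
  invisible(x)
}

#' Decay-corrected compartment activities of a run
#'
#' All measurements referred to run start (t = 0, tracer addition).
#'
#' @param run A [labeling_run()].
#' @return Named numeric vector (MBq at t = 0), one entry per measurement,
#'   named by compartment.
#' @export
corrected_activities <- function(run) {
  stopifnot(inherits(run, "labeling_run"))
  m <- run$measurements
  out <- decay_correct(m$activity_mbq, m$t_min, 0, run$nuclide)
  names(out) <- m$compartment
  out
}

#' Percent incorporation of a labeling run
#'
#' Fraction of the recovered activity found in the cell fraction, on
#' decay-corrected activities: `cells / sum(all measured compartments)`. The
#' denominator is the recovered (measured) activity, not the nominal added
#' activity; see [recovery_fraction()] for the residual diagnostic. When all
#' compartments are measured at the same time the decay correction cancels
#' and the result is time-invariant.
#'
#' @param run A [labeling_run()] with at least one non-cells compartment.
#' @return Incorporated fraction in \[0, 1\].
#' @export
percent_incorporation <- function(run) {
  stopifnot(inherits(run, "labeling_run"))
  a <- corrected_activities(run)
  if (!any(names(a) != "cells")) {
    stop("run has no non-cells compartment; incorporation undefined",
         call. = FALSE)
  }
  tot <- sum(a)
  if (tot <= 0) stop("all activities are zero; incorporation undefined",
                     call. = FALSE)
  unname(a[["cells"]] / tot)
}

#' Compartment fractions of recovered activity
#'
#' Decay-corrected activity of every measured compartment, normalised so the
#' fractions sum to exactly 1 (unlike independently rounded percentages).
#'
#' @param run A [labeling_run()].
#' @return Named numeric vector of fractions summing to 1.
#' @export
wash_fractions <- function(run) {
  stopifnot(inherits(run, "labeling_run"))
  a <- corrected_activities(run)
  tot <- sum(a)
  if (tot <= 0) stop("all activities are zero; fractions undefined",
                     call. = FALSE)
  a / tot
}

#' Recovered-activity diagnostic
#'
#' Decay-corrected compartment sum divided by the nominal added activity.
#' Values well below 1 indicate unrecovered activity (losses on plasticware,
#' unmeasured aliquots); values above 1 indicate calibrator error.
#'
#' @param run A [labeling_run()].
#' @return Recovery fraction (dimensionless).
#' @export
recovery_fraction <- function(run) {
  stopifnot(inherits(run, "labeling_run"))
  if (run$initial_activity <= 0) return(NA_real_)
  sum(corrected_activities(run)) / run$initial_activity
}

#' Fit a saturating uptake curve to incorporation timepoints
#'
#' Fits the single-exponential saturation model
#' \deqn{F(t) = f_\infty (1 - e^{-kt})}
#' to (time, incorporated fraction) data by least squares: the simplest form
#' consistent with first-order transporter-mediated (GLUT1) uptake
#' approaching a plateau. With exactly two distinct timepoints the fit is
#' exact: the ratio equation \eqn{F(t_1)/F(t_2) = (1-e^{-kt_1})/(1-e^{-kt_2})}
#' is solved for `k` by root bracketing, then \eqn{f_\infty} follows.
#'
#' @param t_min Timepoints, minutes; at least two distinct values.
#' @param fraction Incorporated fractions in \[0, 1\], same length.
#' @return An object of class `"uptake_model"`: list with `f_inf`, `k`
#'   (per minute).
#' @export
fit_uptake <- function(t_min, fraction) {
  stopifnot(length(t_min) == length(fraction), length(t_min) >= 2)
  if (any(fraction < 0 | fraction > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (length(unique(t_min)) < 2) {
    stop("uptake fit is not identifiable: all timepoints equal", call. = FALSE)
  }
  if (length(t_min) == 2L) {
    o <- order(t_min)
    t1 <- t_min[o[1]]; t2 <- t_min[o[2]]
    f1 <- fraction[o[1]]; f2 <- fraction[o[2]]
    if (f2 <= 0) stop("uptake fit needs a positive late fraction", call. = FALSE)
    r <- f1 / f2
    ratio_fn <- function(k) (1 - exp(-k * t1)) / (1 - exp(-k * t2)) - r
    # k -> 0 gives ratio t1/t2 (the linear limit); k -> Inf gives 1
    if (r <= t1 / t2 || r >= 1) {
      stop("two-point uptake ratio outside the saturating-model range",
           call. = FALSE)
    }
    k <- stats::uniroot(ratio_fn, lower = 1e-10, upper = 10,
                        tol = 1e-14)$root
    f_inf <- f2 / (1 - exp(-k * t2))
  } else {
    f0 <- max(fraction)
    k0 <- 1 / stats::median(t_min)
    fit <- minpack.lm::nlsLM(
      fraction ~ f_inf * (1 - exp(-k * t_min)),
      start = list(f_inf = min(1, f0 * 1.05 + 1e-6), k = k0),
      lower = c(f_inf = 0, k = 1e-8), upper = c(f_inf = 1.5, k = 10),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
    co <- stats::coef(fit)
    f_inf <- unname(co[["f_inf"]]); k <- unname(co[["k"]])
  }
  structure(list(f_inf = f_inf, k = k), class = "uptake_model")
}

#' @export
print.uptake_model <- function(x, ...) {
  cat(sprintf("<uptake_model> F(t) = %.4g * (1 - exp(-%.4g t))  [t in min]\n",
              x$f_inf, x$k))
  invisible(x)
}

#' Predicted incorporated fraction from an uptake model
#'
#' @param object An `"uptake_model"`.
#' @param t_min Times (minutes) at which to evaluate the curve.
#' @param ... Unused.
#' @return Predicted fractions.
#' @export
predict.uptake_model <- function(object, t_min, ...) {
  object$f_inf * (1 - exp(-object$k * t_min))
}

#' Fit a leakage time course
#'
#' Intracellular tracer release over time, fitted by default as an ordinary
#' least-squares straight line on (minutes, leaked percent) — the release is
#' slow and gradual over the observed window, so a line describes it well. A
#' first-order release variant `method = "exponential"`,
#' \eqn{L(t) = L_\infty (1 - e^{-kt})} in percent, is available for longer
#' windows where saturation matters.
#'
#' @param t_min Timepoints, minutes; at least two distinct values.
#' @param leaked_percent Leaked percent of intracellular activity.
#' @param method `"linear"` (default) or `"exponential"`.
#' @return An object of class `"leakage_model"`: list with `intercept`
#'   (percent), `slope` (percent/min), `r_squared`, `method`, `t_range`, and
#'   for the exponential variant `l_inf`/`k`.
#' @export
fit_leakage <- function(t_min, leaked_percent, method = c("linear", "exponential")) {
  method <- match.arg(method)
  stopifnot(length(t_min) == length(leaked_percent), length(t_min) >= 2)
  if (length(unique(t_min)) < 2) {
    stop("leakage fit is degenerate: all timepoints equal", call. = FALSE)
  }
  if (method == "linear") {
    fit <- stats::lm(leaked_percent ~ t_min)
    co <- stats::coef(fit)
    ss_res <- sum(stats::residuals(fit)^2)
    ss_tot <- sum((leaked_percent - mean(leaked_percent))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
    out <- list(intercept = unname(co[[1]]), slope = unname(co[[2]]),
                r_squared = r2, method = method,
                t_range = range(t_min))
  } else {
    fit <- minpack.lm::nlsLM(
      leaked_percent ~ l_inf * (1 - exp(-k * t_min)),
      start = list(l_inf = max(leaked_percent), k = 1 / stats::median(t_min)),
      lower = c(l_inf = 0, k = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
    co <- stats::coef(fit)
    ss_res <- sum(stats::residuals(fit)^2)
    ss_tot <- sum((leaked_percent - mean(leaked_percent))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
    out <- list(l_inf = unname(co[["l_inf"]]), k = unname(co[["k"]]),
                intercept = 0,
                slope = NA_real_, r_squared = r2, method = method,
                t_range = range(t_min))
  }
  structure(out, class = "leakage_model")
}

#' @export
print.leakage_model <- function(x, ...) {
  if (x$method == "linear") {
    cat(sprintf("<leakage_model> leak(t) = %.4g + %.4g t %%  (R2 = %.4f)\n",
                x$intercept, x$slope, x$r_squared))
  } else {
    cat(sprintf("<leakage_model> leak(t) = %.4g (1 - exp(-%.4g t)) %%  (R2 = %.4f)\n",
                x$l_inf, x$k, x$r_squared))
  }
  invisible(x)
}

#' Predicted leakage at a time
#'
#' Evaluates the fitted leakage model, clamped to \[0, 100\] percent. Warns
#' when extrapolating more than 30 minutes outside the fitted window.
#'
#' @param model A [fit_leakage()] result.
#' @param t_min Time, minutes.
#' @return Leaked percent in \[0, 100\].
#' @export
predict_leakage_at <- function(model, t_min) {
  stopifnot(inherits(model, "leakage_model"))
  lo <- model$t_range[1] - 30
  hi <- model$t_range[2] + 30
  if (any(t_min < lo | t_min > hi)) {
    warning(sprintf(
      "predicting leakage outside the fitted window [%g, %g] min",
      model$t_range[1], model$t_range[2]), call. = FALSE)
  }
  val <- if (model$method == "linear") {
    model$intercept + model$slope * t_min
  } else {
    model$l_inf * (1 - exp(-model$k * t_min))
  }
  pmin(100, pmax(0, val))
}

#' Predicted batch labeling yield
#'
#' Activity incorporated in a labeled-cell batch at release: added activity
#' times the incorporated fraction, decayed over the preparation time.
#'
#' @param initial_mbq Activity added at preparation start (MBq).
#' @param incorporated_fraction Incorporation fraction in \[0, 1\].
#' @param prep_time_min Total preparation time, minutes (default 65, the
#'   midpoint of a typical 60–70 min incubate-and-wash protocol).
#' @param nuclide A [radionuclide()].
#' @return Predicted yield (MBq).
#'
#' @examples
#' predict_yield(740, 0.582, 65, radionuclide("F-18", 109.77))
#'
#' @export
predict_yield <- function(initial_mbq, incorporated_fraction,
                          prep_time_min = 65, nuclide) {
  stopifnot(initial_mbq >= 0, prep_time_min >= 0,
            incorporated_fraction >= 0, incorporated_fraction <= 1)
  initial_mbq * incorporated_fraction * decay_factor(prep_time_min, nuclide)
}
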