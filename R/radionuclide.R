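#' Define a radionuclide by its physical half-life
#'
#' A radionuclide carries the two constants every decay computation needs:
#' the physical half-life \eqn{T_{1/2}} (minutes) and the decay constant
#' \eqn{\lambda = \ln 2 / T_{1/2}} (per minute).
#'
#' @param name Text label, e.g. `"F-18"`.
#' @param half_life_min Physical half-life in minutes; must be positive.
#'
#' @return An object of class `"radionuclide"`: a list with elements `name`,
#'   `half_life` (minutes) and `decay_constant` (per minute).
#'
#' @examples
#' f18 <- radionuclide("F-18", 109.77)
#' f18$decay_constant * f18$half_life  # ln(2)
#'
#' @export
radionuclide <- function(name, half_life_min) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(half_life_min) || length(half_life_min) != 1L ||
      !is.finite(half_life_min) || half_life_min <= 0) {
    stop("`half_life_min` must be a single positive finite number", call. = FALSE)
  }
  structure(
    list(
      name = name,
      half_life = as.numeric(half_life_min),
      decay_constant = log(2) / as.numeric(half_life_min)
    ),
    class = "radionuclide"
  )
}

#' @export
print.radionuclide <- function(x, ...) {
  cat(sprintf("<radionuclide> %s: T1/2 = %.4g min, lambda = %.6g /min\n",
              x$name, x$half_life, x$decay_constant))
  invisible(x)
}

#' Load the packaged radionuclide table
#'
#' Reads a `name,half_life_minutes` CSV (comment lines starting with `#`
#' carry provenance) and returns a named list of [radionuclide()] objects.
#'
#' @param path CSV path; defaults to the table shipped with the package
#'   (F-18 and Tc-99m).
#' @return Named list of `radionuclide` objects, keyed by nuclide name.
#' @export
load_nuclides <- function(path = system.file("extdata", "nuclides.csv",
                                             package = "rbcdosim")) {
  tab <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  stopifnot(all(c("name", "half_life_minutes") %in% names(tab)))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    radionuclide(tab$name[i], tab$half_life_minutes[i])
  })
  names(out) <- tab$name
  out
}

#' Look up a packaged radionuclide by name
#'
#' @param name Nuclide name as in the packaged table, e.g. `"F-18"`, `"Tc-99m"`.
#' @return A `radionuclide` object.
#' @export
get_nuclide <- function(name) {
  nucs <- load_nuclides()
  if (!name %in% names(nucs)) {
    stop(sprintf("unknown nuclide '%s'; packaged: %s",
                 name, paste(names(nucs), collapse = ", ")), call. = FALSE)
  }
  nucs[[name]]
}

#' Physical decay factor
#'
#' Fraction of activity remaining after `elapsed_min` minutes of physical
#' decay: \eqn{2^{-t/T_{1/2}}}. Strictly decreasing in elapsed time and
#' multiplicative over consecutive intervals.
#'
#' @param elapsed_min Elapsed time in minutes; vectorised; must be >= 0.
#' @param nuclide A [radionuclide()].
#' @return Numeric vector of fractions in \[0, 1\].
#'
#' @examples
#' decay_factor(109.77, radionuclide("F-18", 109.77))  # 0.5
#'
#' @export
decay_factor <- function(elapsed_min, nuclide) {
  stopifnot(inherits(nuclide, "radionuclide"))
  if (!is.numeric(elapsed_min) || any(!is.finite(elapsed_min))) {
    stop("`elapsed_min` must be finite numeric", call. = FALSE)
  }
  if (any(elapsed_min < 0)) {
    stop("`elapsed_min` must be non-negative (decay runs forward in time)",
         call. = FALSE)
  }
  2 ^ (-elapsed_min / nuclide$half_life)
}

#' Decay-correct a measured activity to a reference time
#'
#' Rescales an activity measured at `t_measured_min` back to what it was at
#' the (earlier or equal) reference time: `measured / decay_factor(t_measured
#' - t_reference)`. Decaying an activity forward and correcting it back is an
#' exact round trip.
#'
#' @param measured Measured activity (MBq, >= 0); vectorised.
#' @param t_measured_min Measurement time, minutes on the run clock.
#' @param t_reference_min Reference time, minutes on the same clock; must not
#'   be after the measurement time.
#' @param nuclide A [radionuclide()].
#' @return Activity (MBq) referred to `t_reference_min`.
#'
#' @examples
#' f18 <- radionuclide("F-18", 109.77)
#' decay_correct(0.5, 109.77, 0, f18)  # 1.0
#'
#' @export
decay_correct <- function(measured, t_measured_min, t_reference_min, nuclide) {
  if (any(measured < 0)) stop("`measured` must be non-negative", call. = FALSE)
  measured / decay_factor(t_measured_min - t_reference_min, nuclide)
}
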