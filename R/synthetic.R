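# Synthetic-data generators with known ground truth.
#
# Every input the pipeline consumes can be generated here: labeling-run
# calibrator series, leakage time courses, blood-volume tables and
# physically plausible S-value matrices. Generators are pure functions of
# their seed (RNG state is saved and restored) so noiseless round trips and
# Monte-Carlo estimator checks are exact and reproducible.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# multiplicative lognormal noise with unit mean and the given CV
.calibrator_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Ground truth for synthetic labeling runs
#'
#' @param true_incorporated_fraction Fraction of recovered activity in the
#'   cell fraction, in \[0, 1\].
#' @param wash_carryover Vector (length <= 3) of wash-supernatant fractions;
#'   together with the incorporated fraction it must sum to at most 1 — the
#'   remainder is the original incubation supernatant.
#' @param calibrator_cv Relative (scale-proportional) dose-calibrator noise;
#'   default 1%.
#' @param n_replicates Number of replicate runs.
#' @param seed RNG seed.
#' @return An object of class `"labeling_truth"`.
#' @export
labeling_truth <- function(true_incorporated_fraction,
                           wash_carryover = c(0.03, 0.02, 0.01),
                           calibrator_cv = 0.01, n_replicates = 1L,
                           seed = 1L) {
  stopifnot(true_incorporated_fraction >= 0, true_incorporated_fraction <= 1,
            all(wash_carryover >= 0), length(wash_carryover) <= 3,
            calibrator_cv >= 0, n_replicates >= 1)
  if (true_incorporated_fraction + sum(wash_carryover) > 1 + 1e-12) {
    stop("incorporated fraction + wash carry-over exceeds 1", call. = FALSE)
  }
  structure(
    list(true_incorporated_fraction = true_incorporated_fraction,
         wash_carryover = wash_carryover, calibrator_cv = calibrator_cv,
         n_replicates = as.integer(n_replicates), seed = as.integer(seed)),
    class = "labeling_truth"
  )
}

#' Generate synthetic labeling runs
#'
#' Partitions the added activity into cells / supernatant / washes according
#' to the truth fractions, applies multiplicative lognormal calibrator noise
#' with the stated CV, and (optionally) decays every compartment to its
#' measurement time. With zero noise and the default common measurement
#' time, [percent_incorporation()] recovers the true fraction exactly.
#'
#' @param truth A [labeling_truth()].
#' @param nuclide A [radionuclide()] (default packaged F-18).
#' @param initial_activity_mbq Activity added at t = 0 (default 74 MBq, a
#'   typical labeling-incubation amount).
#' @param t_measure_min Common measurement time for all compartments,
#'   minutes from run start (default 120, end of a 2-h incubation).
#' @return List of [labeling_run()] objects, length `truth$n_replicates`.
#' @export
make_labeling_run <- function(truth, nuclide = get_nuclide("F-18"),
                              initial_activity_mbq = 74,
                              t_measure_min = 120) {
  stopifnot(inherits(truth, "labeling_truth"))
  f_cells <- truth$true_incorporated_fraction
  f_wash <- truth$wash_carryover
  f_sup <- 1 - f_cells - sum(f_wash)
  comps <- c("cells", "supernatant", paste0("wash_", seq_along(f_wash)))
  fracs <- c(f_cells, max(0, f_sup), f_wash)
  .with_seed(truth$seed, {
    lapply(seq_len(truth$n_replicates), function(i) {
      noise <- .calibrator_noise(length(fracs), truth$calibrator_cv)
      measured <- initial_activity_mbq * fracs * noise *
        decay_factor(t_measure_min, nuclide)
      labeling_run(
        nuclide = nuclide,
        measurements = data.frame(
          compartment = comps,
          activity_mbq = measured,
          t_min = t_measure_min
        ),
        initial_activity_mbq = initial_activity_mbq,
        balance_tol = max(0.05, 6 * truth$calibrator_cv)
      )
    })
  })
}

#' Generate a synthetic leakage time course
#'
#' Linear truth (percent leaked vs minutes) plus multiplicative lognormal
#' noise. With `cv = 0`, [fit_leakage()] recovers the slope and intercept to
#' numerical precision.
#'
#' @param slope Percent leaked per minute.
#' @param intercept Percent leaked at t = 0.
#' @param times_min Sampling times, minutes (>= 0).
#' @param cv Relative noise on each point (0 = noiseless).
#' @param seed RNG seed.
#' @return data.frame with columns `t_min`, `leaked_percent`.
#' @export
make_leakage_series <- function(slope, intercept, times_min,
                                cv = 0.05, seed = 1L) {
  stopifnot(all(times_min >= 0), cv >= 0)
  truth <- intercept + slope * times_min
  .with_seed(seed, {
    data.frame(
      t_min = times_min,
      leaked_percent = truth * .calibrator_noise(length(times_min), cv)
    )
  })
}

#' Construct a synthetic anatomical phantom
#'
#' A stand-in anatomical model for exercising the dose engine: organ masses,
#' a mean non-penetrating (electron/positron) energy per decay, a mean
#' penetrating (photon) energy per decay, and a row-stochastic geometry
#' coupling matrix describing what fraction of a source's photon energy is
#' absorbed in each target. This phantom is synthetic — it stands in for a
#' real stylised phantom's S-value tables in tests and demonstrations, and
#' makes no anatomical claims.
#'
#' @param organ_masses_kg Named vector of organ masses (kg, > 0); the
#'   default spans 0.02–20 kg over 8 organs plus `rest_of_body` so both
#'   wall-correction and remainder logic get exercised downstream.
#' @param electron_energy Non-penetrating energy per decay, mGy·kg per
#'   MBq·h (absorbed entirely in the source organ).
#' @param photon_energy Penetrating energy per decay, mGy·kg per MBq·h,
#'   distributed over targets by the coupling matrix.
#' @param coupling Square matrix (sources x targets), rows summing to <= 1:
#'   fraction of emitted photon energy absorbed per target. Default: each
#'   source deposits in targets proportionally to target mass, scaled so
#'   self-dose dominance holds by construction.
#' @return An object of class `"synthetic_phantom"`.
#' @export
synthetic_phantom <- function(
    organ_masses_kg = c(heart_wall = 0.3, lungs = 1.0, liver = 1.8,
                        spleen = 0.15, kidneys = 0.31, red_marrow = 1.1,
                        thyroid = 0.02, urinary_bladder = 0.05,
                        rest_of_body = 20),
    electron_energy = 0.1,
    photon_energy = 0.05,
    coupling = NULL) {
  stopifnot(all(organ_masses_kg > 0), electron_energy >= 0, photon_energy >= 0)
  n <- length(organ_masses_kg)
  organs <- names(organ_masses_kg)
  if (is.null(coupling)) {
    # deposit photon energy proportionally to target mass, 50% escaping
    w <- organ_masses_kg / sum(organ_masses_kg)
    coupling <- matrix(rep(w, each = n), nrow = n, dimnames = list(organs, organs)) * 0.5
  }
  stopifnot(is.matrix(coupling), nrow(coupling) == n, ncol(coupling) == n)
  if (any(coupling < 0) || any(rowSums(coupling) > 1 + 1e-9)) {
    stop("coupling rows must be non-negative and sum to <= 1", call. = FALSE)
  }
  dimnames(coupling) <- list(organs, organs)
  structure(
    list(organ_masses_kg = organ_masses_kg, electron_energy = electron_energy,
         photon_energy = photon_energy, coupling = coupling),
    class = "synthetic_phantom"
  )
}

#' Build an S-value matrix from a synthetic phantom
#'
#' Self S-value: electron self-absorption `electron_energy / mass` plus the
#' photon self term `photon_energy * coupling[s, s] / mass`. Cross terms:
#' `photon_energy * coupling[s, t] / mass_t`. With the default
#' mass-proportional coupling, cross photon terms are constant across
#' targets while every diagonal gains the electron term, so self-dose
#' dominance holds by construction; the returned object is validated by
#' [svalue_matrix()] regardless.
#'
#' @param phantom A [synthetic_phantom()].
#' @param nuclide A [radionuclide()]; recorded in the phantom label.
#' @return An [svalue_matrix()] (targets = sources = phantom organs).
#' @export
make_smatrix <- function(phantom, nuclide = get_nuclide("F-18")) {
  stopifnot(inherits(phantom, "synthetic_phantom"))
  m <- phantom$organ_masses_kg
  organs <- names(m)
  n <- length(m)
  vals <- matrix(0, n, n, dimnames = list(organs, organs))  # target x source
  for (s in organs) {
    vals[, s] <- phantom$photon_energy * phantom$coupling[s, ] / m
    vals[s, s] <- vals[s, s] + phantom$electron_energy / m[[s]]
  }
  svalue_matrix(vals, phantom_name = sprintf("synthetic phantom (%s)",
                                             nuclide$name))
}

#' Generate a synthetic blood-volume table
#'
#' Random organ blood-volume fractions drawn from a Dirichlet-like scheme
#' (normalised gamma draws scaled to a total organ share below 1), for
#' property tests that must not depend on any transcribed reference table.
#'
#' @param organs Organ names.
#' @param total_fraction Total fraction of blood assigned to named organs
#'   (the rest goes to `rest_of_body` downstream).
#' @param seed RNG seed.
#' @return A [blood_volume_table()].
#' @export
make_blood_volume_table <- function(organs, total_fraction = 0.7, seed = 1L) {
  stopifnot(total_fraction > 0, total_fraction <= 1)
  .with_seed(seed, {
    g <- stats::rgamma(length(organs), shape = 2)
    blood_volume_table(organs, total_fraction * g / sum(g),
                       provenance = "synthetic (generated)")
  })
}
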