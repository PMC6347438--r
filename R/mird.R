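# MIRD-schema absorbed-dose engine.
#
# D(target) = sum over sources of a-tilde(source) * S(target <- source),
# with S-values (mGy per MBq*h) taken as INPUT: phantom S-value tables are
# external data (transcribed for real phantoms, generated synthetically for
# tests), never computed here. Downstream: hollow-organ wall electron
# self-dose correction, ICRP-60 effective dose, and 21 CFR 361.1
# administration limits.

#' Construct an S-value matrix
#'
#' @param values Numeric matrix, rows = target organs, columns = source
#'   regions, entries in mGy per MBq·h; all non-negative. For every organ
#'   present both as source and target, the self-dose must dominate:
#'   `S[organ, organ] >= S[other, organ]` (self-irradiation always deposits
#'   at least as much per decay as irradiation of any other target).
#' @param phantom_name Text label of the phantom the values describe.
#' @return An object of class `"svalue_matrix"`.
#' @export
svalue_matrix <- function(values, phantom_name = "unnamed phantom") {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (any(values < 0)) stop("S-values must be non-negative", call. = FALSE)
  both <- intersect(rownames(values), colnames(values))
  for (org in both) {
    if (any(values[, org] > values[org, org] + 1e-12)) {
      stop(sprintf("self-dose dominance violated for source '%s'", org),
           call. = FALSE)
    }
  }
  structure(
    list(values = values, targets = rownames(values),
         sources = colnames(values), phantom_name = phantom_name),
    class = "svalue_matrix"
  )
}

#' @export
print.svalue_matrix <- function(x, ...) {
  cat(sprintf("<svalue_matrix> %s: %d targets x %d sources [mGy/(MBq h)]\n",
              x$phantom_name, length(x$targets), length(x$sources)))
  invisible(x)
}

#' Read / write an S-value matrix CSV
#'
#' Layout: first column `target`, one further column per source region
#' (header row = source names), entries in mGy per MBq·h. `#` comment lines
#' carry provenance.
#'
#' @param path CSV path.
#' @param phantom_name Label for the loaded phantom.
#' @return [read_smatrix()] returns an `"svalue_matrix"`.
#' @export
read_smatrix <- function(path, phantom_name = basename(path)) {
  tab <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                         strip.white = TRUE)
  stopifnot(names(tab)[1] == "target")
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- tab$target
  svalue_matrix(vals, phantom_name = phantom_name)
}

#' @rdname read_smatrix
#' @param s An `"svalue_matrix"` to write.
#' @export
write_smatrix <- function(s, path) {
  stopifnot(inherits(s, "svalue_matrix"))
  df <- data.frame(target = s$targets, s$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.tia_as_vector <- function(tia) {
  if (inherits(tia, "tia_vector") || is.data.frame(tia)) {
    out <- tia$tia_h
    names(out) <- tia$region
    out
  } else {
    stopifnot(is.numeric(tia), !is.null(names(tia)))
    tia
  }
}

#' Organ absorbed doses from time-integrated activities
#'
#' The MIRD sum: for every target organ,
#' \eqn{D = \sum_s \tilde a_s \, S(\mathrm{target} \leftarrow s)}.
#' Linear in the activity coefficients and in the S-values.
#'
#' @param tia A [tia_vector()] or a named numeric vector of time-integrated
#'   activity coefficients (hours). Every region must be a source of `s`.
#' @param s An [svalue_matrix()].
#' @return Named numeric vector: absorbed dose per unit administered
#'   activity (mGy/MBq) for every target organ.
#' @export
absorbed_doses <- function(tia, s) {
  stopifnot(inherits(s, "svalue_matrix"))
  a <- .tia_as_vector(tia)
  if (any(a < 0)) stop("time-integrated activities must be >= 0", call. = FALSE)
  missing <- setdiff(names(a), s$sources)
  if (length(missing)) {
    stop("source region(s) absent from the S-value matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  full <- stats::setNames(numeric(length(s$sources)), s$sources)
  full[names(a)] <- a
  drop(s$values %*% full)
}

#' Describe a hollow organ for wall-dose correction
#'
#' @param organ Target-organ name (the wall).
#' @param wall_mass_kg Wall mass, kg (> 0).
#' @param contents_mass_kg Luminal-contents mass, kg (> 0).
#' @param delta_electron Mean non-penetrating (electron/positron) energy
#'   emitted per unit time-integrated activity, in mGy·kg per MBq·h
#'   (so that `delta_electron / mass` is an absorbed-dose S-value term).
#' @return An object of class `"hollow_organ_spec"`.
#' @export
hollow_organ_spec <- function(organ, wall_mass_kg, contents_mass_kg,
                              delta_electron) {
  stopifnot(is.character(organ), length(organ) == 1L,
            wall_mass_kg > 0, contents_mass_kg > 0, delta_electron >= 0)
  structure(
    list(organ = organ, wall_mass = wall_mass_kg,
         contents_mass = contents_mass_kg, delta_electron = delta_electron),
    class = "hollow_organ_spec"
  )
}

#' Hollow-organ wall electron self-dose correction
#'
#' Stylised phantoms place hollow-organ self-dose activity in the lumen
#' (ingested material) and credit the wall with half the contents-absorbed
#' electron dose (the surface convention):
#' \eqn{\frac{1}{2}\,\tilde a\,\Delta_e / m_{contents}}. For a blood-pool
#' agent the activity resides in the vascularised wall itself, so that term
#' is wrong; this correction replaces it with the wall self-absorbed
#' electron term \eqn{\tilde a\,\Delta_e / m_{wall}}. Photon (penetrating)
#' terms are left untouched. Only the specified organ's dose changes, and
#' the result is never negative.
#'
#' @param doses Named dose vector from [absorbed_doses()] (mGy/MBq).
#' @param tia A [tia_vector()] or named numeric vector; the organ's
#'   blood-pool activity must be assigned to its wall source region (the
#'   entry named `spec$organ`).
#' @param spec A [hollow_organ_spec()].
#' @param s Optional [svalue_matrix()]; when given, used only to check the
#'   organ is a known target.
#' @return The dose vector with the organ's electron self-dose term
#'   corrected.
#' @export
wall_correction <- function(doses, tia, spec, s = NULL) {
  stopifnot(inherits(spec, "hollow_organ_spec"))
  a <- .tia_as_vector(tia)
  if (!spec$organ %in% names(doses) ||
      (!is.null(s) && !spec$organ %in% s$targets)) {
    warning(sprintf("organ '%s' not among dose targets; no correction applied",
                    spec$organ), call. = FALSE)
    return(doses)
  }
  a_org <- if (spec$organ %in% names(a)) a[[spec$organ]] else 0
  surface_term <- 0.5 * a_org * spec$delta_electron / spec$contents_mass
  wall_term <- a_org * spec$delta_electron / spec$wall_mass
  doses[spec$organ] <- max(0, doses[[spec$organ]] - surface_term + wall_term)
  doses
}

#' ICRP-60 tissue weighting factors
#'
#' @param weights Named numeric vector of tissue weighting factors
#'   \eqn{w_T}, including an entry named `"remainder"`; must sum to 1 (to
#'   1e-9).
#' @param remainder_organs Character vector of organs whose doses form the
#'   remainder tissue.
#' @param provenance Source-document note.
#' @return An object of class `"tissue_weights"`.
#' @export
tissue_weights <- function(weights, remainder_organs, provenance = "") {
  stopifnot(is.numeric(weights), !is.null(names(weights)))
  if (any(weights < 0)) stop("tissue weights must be >= 0", call. = FALSE)
  if (!"remainder" %in% names(weights)) {
    stop("weights must include a 'remainder' entry", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop(sprintf("tissue weights sum to %.10f, not 1", sum(weights)),
         call. = FALSE)
  }
  structure(
    list(weights = weights, remainder_organs = as.character(remainder_organs),
         provenance = provenance),
    class = "tissue_weights"
  )
}

#' Load the packaged ICRP-60 tissue-weight configuration
#'
#' @param path YAML path; defaults to the packaged transcription of the
#'   ICRP Publication 60 weighting factors and remainder-organ list.
#' @return A [tissue_weights()].
#' @export
load_tissue_weights <- function(path = system.file("extdata",
                                                   "icrp60_tissue_weights.yaml",
                                                   package = "rbcdosim")) {
  y <- yaml::read_yaml(path)
  tissue_weights(unlist(y$weights), y$remainder_organs,
                 provenance = y$provenance %||% "")
}

#' Default tissue-to-organ dose aliases and surrogates
#'
#' Maps weighted-tissue names onto the organ names dose tables commonly use:
#' plural aliases (`lung` → `lungs`) and documented surrogates (`oesophagus`
#' ← thymus dose; `gonads` ← testes for the adult-male report).
#'
#' @param gonad_surrogate `"testes"` (default, adult-male report) or
#'   `"ovaries"`.
#' @return Named character vector, tissue → dose-table organ.
#' @export
default_surrogates <- function(gonad_surrogate = c("testes", "ovaries")) {
  gonad_surrogate <- match.arg(gonad_surrogate)
  c(lung = "lungs", bladder = "urinary_bladder", breast = "breasts",
    bone_surface = "bone_surfaces", oesophagus = "thymus",
    gonads = gonad_surrogate)
}

#' ICRP-60 effective dose
#'
#' \eqn{E = \sum_T w_T H_T} with the equivalent dose \eqn{H_T} numerically
#' equal to the absorbed dose (radiation weighting factor 1 for photons and
#' electrons/positrons), so mGy/MBq in gives mSv/MBq out. The remainder
#' tissue receives the unweighted mean dose of the remainder organs present
#' (a mass-weighted variant is available via `remainder_method` and
#' `organ_masses_kg`).
#'
#' @param doses Named absorbed-dose vector (mGy/MBq).
#' @param w A [tissue_weights()].
#' @param surrogates Named character vector mapping weighted tissues onto
#'   dose-table organ names; see [default_surrogates()].
#' @param remainder_method `"mean"` (default) or `"mass_weighted"`.
#' @param organ_masses_kg Named masses, required for the mass-weighted
#'   remainder.
#' @return Effective dose per unit administered activity (mSv/MBq).
#' @export
effective_dose <- function(doses, w, surrogates = default_surrogates(),
                           remainder_method = c("mean", "mass_weighted"),
                           organ_masses_kg = NULL) {
  stopifnot(inherits(w, "tissue_weights"))
  remainder_method <- match.arg(remainder_method)
  if (any(doses < 0)) stop("doses must be >= 0", call. = FALSE)
  lookup <- function(tissue) {
    cands <- c(tissue, unname(surrogates[tissue]))
    cands <- cands[!is.na(cands)]
    hit <- cands[cands %in% names(doses)]
    if (!length(hit)) {
      stop(sprintf("no dose available for weighted tissue '%s' (tried: %s)",
                   tissue, paste(cands, collapse = ", ")), call. = FALSE)
    }
    doses[[hit[1]]]
  }
  named <- setdiff(names(w$weights), "remainder")
  e <- sum(vapply(named, function(ts) w$weights[[ts]] * lookup(ts), numeric(1)))
  w_rem <- w$weights[["remainder"]]
  if (w_rem > 0) {
    present <- intersect(w$remainder_organs, names(doses))
    if (!length(present)) {
      stop("no remainder-organ doses available for the remainder tissue",
           call. = FALSE)
    }
    d_rem <- if (remainder_method == "mean") {
      mean(doses[present])
    } else {
      if (is.null(organ_masses_kg)) {
        stop("mass-weighted remainder needs `organ_masses_kg`", call. = FALSE)
      }
      m <- organ_masses_kg[present]
      if (any(is.na(m))) stop("missing masses for remainder organs", call. = FALSE)
      sum(doses[present] * m) / sum(m)
    }
    e <- e + w_rem * d_rem
  }
  unname(e)
}

#' Load the packaged 21 CFR 361.1 dose-limit configuration
#'
#' Research-use radiation dose limits in mSv: a restrictive class (whole
#' body, active blood-forming organs, lens of the eye, gonads: 30 per
#' single administration, 50 per year) and all other organs (50 single,
#' 150 annual), plus the organ names belonging to the restrictive class.
#'
#' @param path YAML path (defaults to the packaged table).
#' @return List with elements `restrictive` (`single_msv`, `annual_msv`),
#'   `other` (likewise) and `restrictive_organs`.
#' @export
load_regulatory_limits <- function(path = system.file("extdata",
                                                      "cfr361_limits.yaml",
                                                      package = "rbcdosim")) {
  yaml::read_yaml(path)
}

#' Administration limits under research-use dose limits
#'
#' For each organ, the per-administration equivalent dose is
#' `dose (mGy/MBq) * activity (MBq)` (numerically mSv with radiation
#' weighting factor 1). Every organ is checked against its class limits:
#' the restrictive class (blood-forming organs, gonads, lens, and a
#' whole-body entry when a total-body dose is supplied) at 30 mSv single /
#' 50 mSv annual, all others at 50 mSv single / 150 mSv annual. The annual
#' administration cap is the floor of the tightest `annual limit /
#' per-administration dose` ratio; the limiting organ attains it. The
#' effective dose is carried in the result for reporting; it is not treated
#' as the whole-body absorbed dose unless `use_effective_as_whole_body` is
#' set (the regulatory whole-body entry is an absorbed-dose quantity).
#'
#' @param doses Named absorbed-dose vector (mGy/MBq).
#' @param effective Effective dose coefficient (mSv/MBq), reported alongside.
#' @param activity_per_admin_mbq Administered activity per administration
#'   (MBq, > 0).
#' @param limits Regulatory limit configuration, see
#'   [load_regulatory_limits()].
#' @param use_effective_as_whole_body If `TRUE`, add a `whole_body` entry
#'   equal to the effective-dose coefficient and check it against the
#'   restrictive class.
#' @return List of class `"admin_limits"`: `limiting_organ`,
#'   `max_annual_admins`, `max_single_admin_mbq`, `single_admin_ok`,
#'   `per_admin_msv` (named vector), `effective_msv_per_admin`. With all
#'   doses zero, `limiting_organ` is `"none (no binding constraint)"` and
#'   `max_annual_admins` is `Inf`.
#' @export
admin_limits <- function(doses, effective = NA_real_, activity_per_admin_mbq,
                         limits = load_regulatory_limits(),
                         use_effective_as_whole_body = FALSE) {
  stopifnot(activity_per_admin_mbq > 0)
  if (any(doses < 0)) stop("doses must be >= 0", call. = FALSE)
  d <- doses
  if (use_effective_as_whole_body && is.finite(effective)) {
    d <- c(d, whole_body = effective)
  }
  restrictive <- names(d) %in% limits$restrictive_organs
  single_lim <- ifelse(restrictive, limits$restrictive$single_msv,
                       limits$other$single_msv)
  annual_lim <- ifelse(restrictive, limits$restrictive$annual_msv,
                       limits$other$annual_msv)
  per_admin <- d * activity_per_admin_mbq
  nonzero <- per_admin > 0
  if (!any(nonzero)) {
    return(structure(list(
      limiting_organ = "none (no binding constraint)",
      max_annual_admins = Inf, max_single_admin_mbq = Inf,
      single_admin_ok = TRUE, per_admin_msv = per_admin,
      effective_msv_per_admin = effective * activity_per_admin_mbq,
      activity_per_admin_mbq = activity_per_admin_mbq
    ), class = "admin_limits"))
  }
  admins_allowed <- annual_lim[nonzero] / per_admin[nonzero]
  i <- which.min(admins_allowed)
  max_single_mbq <- min(single_lim[nonzero] / d[nonzero])
  structure(list(
    limiting_organ = names(d)[nonzero][i],
    max_annual_admins = floor(min(admins_allowed)),
    max_single_admin_mbq = max_single_mbq,
    single_admin_ok = all(per_admin[nonzero] <= single_lim[nonzero] + 1e-9),
    per_admin_msv = per_admin,
    effective_msv_per_admin = effective * activity_per_admin_mbq,
    activity_per_admin_mbq = activity_per_admin_mbq
  ), class = "admin_limits")
}

#' @export
print.admin_limits <- function(x, ...) {
  cat(sprintf(
    "<admin_limits> %.0f MBq/admin: limiting organ %s, max %s administrations/year\n",
    x$activity_per_admin_mbq, x$limiting_organ,
    format(x$max_annual_admins)))
  if (!x$single_admin_ok) cat("  WARNING: single-administration limit exceeded\n")
  invisible(x)
}

#' Total effective dose over an administration
#'
#' @param coefficient_msv_per_mbq Effective dose per unit activity (mSv/MBq).
#' @param activity_mbq Administered activity (MBq); vectorised (e.g. a
#'   planned low–high range).
#' @param digits Reporting precision in decimal places (default 1).
#' @return Effective dose (mSv), rounded to `digits` decimals for reporting.
#' @export
total_effective_dose <- function(coefficient_msv_per_mbq, activity_mbq,
                                 digits = 1) {
  stopifnot(all(coefficient_msv_per_mbq >= 0), all(activity_mbq >= 0))
  round(coefficient_msv_per_mbq * activity_mbq, digits)
}

#' Bundle a dosimetry result into a report
#'
#' @param organ_doses Named absorbed-dose vector (mGy/MBq).
#' @param effective_msv_per_mbq Effective dose coefficient (mSv/MBq).
#' @param scenario_label Free-text scenario name.
#' @param limits An [admin_limits()] result, or `NULL`.
#' @return An object of class `"dose_report"`.
#' @export
dose_report <- function(organ_doses, effective_msv_per_mbq = NA_real_,
                        scenario_label = "", limits = NULL) {
  if (any(organ_doses < 0)) stop("doses must be >= 0", call. = FALSE)
  structure(
    list(organ_doses = organ_doses,
         effective_msv_per_mbq = effective_msv_per_mbq,
         scenario_label = scenario_label, limits = limits),
    class = "dose_report"
  )
}

#' @export
print.dose_report <- function(x, ...) {
  cat(sprintf("<dose_report> %s: %d organs", x$scenario_label,
              length(x$organ_doses)))
  if (is.finite(x$effective_msv_per_mbq)) {
    cat(sprintf(", effective dose %.3g mSv/MBq", x$effective_msv_per_mbq))
  }
  cat("\n  (equivalent dose = absorbed dose numerically; w_R = 1 for photons/positrons)\n")
  if (!is.null(x$limits)) print(x$limits)
  invisible(x)
}

#' Compare organ-dose reports between agents or scenarios
#'
#' Restricts all reports to their common organ set, then tabulates per-organ
#' doses, the ratio of every report to the first (the reference), and ranks
#' organs by the dose difference between the second report and the
#' reference. Pure presentation over already-computed reports.
#'
#' @param reports Named list (length >= 2) of [dose_report()] objects or
#'   named dose vectors.
#' @return A data.frame with one row per common organ: `organ`, one dose
#'   column per report, `ratio_<name>` columns relative to the first
#'   report, and `dose_diff` (second minus first), sorted by decreasing
#'   absolute difference.
#' @export
compare_agents <- function(reports) {
  stopifnot(is.list(reports), length(reports) >= 2)
  if (is.null(names(reports)) || any(names(reports) == "")) {
    names(reports) <- paste0("report_", seq_along(reports))
  }
  vecs <- lapply(reports, function(r) {
    if (inherits(r, "dose_report")) r$organ_doses else r
  })
  common <- Reduce(intersect, lapply(vecs, names))
  if (!length(common)) stop("reports share no organs", call. = FALSE)
  out <- data.frame(organ = common)
  for (nm in names(vecs)) out[[nm]] <- unname(vecs[[nm]][common])
  ref <- out[[names(vecs)[1]]]
  for (nm in names(vecs)[-1]) {
    out[[paste0("ratio_", nm)]] <- out[[nm]] / ref
  }
  out$dose_diff <- out[[names(vecs)[2]]] - ref
  out[order(-abs(out$dose_diff)), , drop = FALSE]
}
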