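# File dialects: labeling-run CSVs with YAML sidecars, reference dose
# tables and coefficient tables. All time columns are minutes from run
# start / injection (`t_min`); no clock-time strings enter the math layer.

#' Read a labeling run from CSV + YAML sidecar
#'
#' The CSV carries `compartment,activity_mbq,t_min`; the sidecar YAML
#' (same path with `.yaml` extension unless given) carries `nuclide` and
#' `initial_activity_mbq`.
#'
#' @param csv_path Measurement CSV path.
#' @param sidecar_path YAML sidecar path; defaults to the CSV path with the
#'   extension replaced by `.yaml`.
#' @param nuclides Named list of available nuclides, see [load_nuclides()].
#' @return A [labeling_run()].
#' @export
read_labeling_run <- function(csv_path, sidecar_path = NULL,
                              nuclides = load_nuclides()) {
  if (is.null(sidecar_path)) {
    sidecar_path <- sub("\\.csv$", ".yaml", csv_path)
  }
  meta <- yaml::read_yaml(sidecar_path)
  if (!meta$nuclide %in% names(nuclides)) {
    stop(sprintf("sidecar names unknown nuclide '%s'", meta$nuclide),
         call. = FALSE)
  }
  tab <- utils::read.csv(csv_path, comment.char = "#", strip.white = TRUE)
  labeling_run(nuclide = nuclides[[meta$nuclide]], measurements = tab,
               initial_activity_mbq = meta$initial_activity_mbq)
}

#' Write a labeling run to CSV + YAML sidecar
#'
#' @param run A [labeling_run()].
#' @param csv_path Destination CSV path; the sidecar is written next to it.
#' @return The CSV path, invisibly.
#' @export
write_labeling_run <- function(run, csv_path) {
  stopifnot(inherits(run, "labeling_run"))
  utils::write.csv(run$measurements, csv_path, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(
    list(nuclide = run$nuclide$name,
         initial_activity_mbq = run$initial_activity),
    sub("\\.csv$", ".yaml", csv_path)
  )
  invisible(csv_path)
}

#' Load the packaged reference organ-dose table
#'
#' Published adult-male organ absorbed doses for the FDG-labeled erythrocyte
#' blood-pool agent (mGy/MBq) under the two biodistribution scenarios:
#' `no_leakage` (full retention, physical decay only) and `free_25`
#' (25% urinary excretion of free tracer). These are reference values used
#' as input for effective-dose, limit and comparison arithmetic — the
#' package's own dose engine does not produce them.
#'
#' @param path CSV path (defaults to the packaged table).
#' @return data.frame with columns `organ`, `no_leakage`, `free_25`.
#' @export
load_reference_doses <- function(path = system.file("extdata",
                                                    "organ_doses_fdg_rbc.csv",
                                                    package = "rbcdosim")) {
  utils::read.csv(path, comment.char = "#", strip.white = TRUE)
}

#' Reference dose column as a named vector
#'
#' @param scenario `"no_leakage"` or `"free_25"`.
#' @param table Output of [load_reference_doses()].
#' @return Named numeric vector organ -> mGy/MBq.
#' @export
reference_dose_vector <- function(scenario = c("no_leakage", "free_25"),
                                  table = load_reference_doses()) {
  scenario <- match.arg(scenario)
  stats::setNames(table[[scenario]], table$organ)
}

#' Load packaged effective-dose coefficients
#'
#' Published adult effective-dose coefficients (mSv/MBq) for the labeled-
#' erythrocyte agent and its comparators.
#'
#' @param path CSV path (defaults to the packaged table).
#' @return Named numeric vector agent -> mSv/MBq.
#' @export
load_effective_coefficients <- function(path = system.file(
  "extdata", "effective_dose_coefficients.csv", package = "rbcdosim")) {
  tab <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  stats::setNames(tab$msv_per_mbq, tab$agent)
}
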