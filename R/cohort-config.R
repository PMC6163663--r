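#' Configuration for a synthetic TMA cohort
#'
#' Describes the design of a simulated tissue-microarray cohort: matched
#' high-risk (HR) / low-risk (LR) patient pairs, several tumour cores per
#' patient, and a three-class intensity model (bright background,
#' hematoxylin-only tissue, DAB-positive tissue) on the 8-bit scale.
#'
#' Per-core DAB-positive area fractions are drawn hierarchically on the
#' logit scale: a patient-level normal deviation (`patient_sd`) around the
#' group mean fraction, then a core-level deviation (`core_sd`) around the
#' patient value, mapped back through the inverse logit so fractions stay
#' in \[0, 1\].
#'
#' @param n_pairs Number of matched HR/LR patient pairs (default 41, i.e.
#'   82 patients).
#' @param cores_per_patient Tumour cores sampled per patient (default 4).
#' @param image_side Side of the square core image in pixels.
#' @param core_diameter Diameter of the inscribed tissue disc in pixels;
#'   must not exceed `image_side`.
#' @param background_mean,background_sd Mean and sd of background pixel
#'   intensity (0-255; bright, unstained glass).
#' @param tissue_mean,tissue_sd Intensity of hematoxylin-only tissue;
#'   darker than background.
#' @param dab_mean,dab_sd Intensity of DAB-positive tissue; darker still.
#' @param dab_fraction_hr,dab_fraction_lr Group means of the per-core
#'   DAB-positive area fraction, in \[0, 1\].
#' @param patient_sd,core_sd Between-patient and within-patient standard
#'   deviations of the DAB fraction, on the logit scale.
#' @param seed Integer seed; the whole cohort is deterministic given the
#'   config.
#'
#' @return A validated list of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_pairs = 2, cores_per_patient = 2,
#'                      image_side = 64, core_diameter = 56, seed = 1)
cohort_config <- function(n_pairs = 41,
                          cores_per_patient = 4,
                          image_side = 256,
                          core_diameter = 230,
                          background_mean = 250, background_sd = 3,
                          tissue_mean = 150, tissue_sd = 10,
                          dab_mean = 60, dab_sd = 10,
                          dab_fraction_hr = 0.30,
                          dab_fraction_lr = 0.15,
                          patient_sd = 0.6,
                          core_sd = 0.4,
                          seed = 1L) {
  cfg <- structure(list(
    n_pairs = as.integer(n_pairs),
    cores_per_patient = as.integer(cores_per_patient),
    image_side = as.integer(image_side),
    core_diameter = as.integer(core_diameter),
    background_mean = background_mean, background_sd = background_sd,
    tissue_mean = tissue_mean, tissue_sd = tissue_sd,
    dab_mean = dab_mean, dab_sd = dab_sd,
    dab_fraction_hr = dab_fraction_hr,
    dab_fraction_lr = dab_fraction_lr,
    patient_sd = patient_sd,
    core_sd = core_sd,
    seed = as.integer(seed)
  ), class = "cohort_config")
  validate_cohort_config(cfg)
}

#' Validate a cohort configuration
#'
#' Checks the invariants of [cohort_config()]; errors name the offending
#' field.
#'
#' @param cfg A `cohort_config` object.
#' @return `cfg`, invisibly unchanged, if valid.
#' @export
validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  fail <- function(field, msg) {
    stop(sprintf("invalid cohort config: field '%s' %s", field, msg),
         call. = FALSE)
  }
  if (is.na(cfg$n_pairs) || cfg$n_pairs < 1L) {
    fail("n_pairs", "must be >= 1")
  }
  if (is.na(cfg$cores_per_patient) || cfg$cores_per_patient < 1L) {
    fail("cores_per_patient", "must be >= 1")
  }
  if (cfg$core_diameter > cfg$image_side) {
    fail("core_diameter", "must not exceed image_side")
  }
  if (cfg$core_diameter < 1L) fail("core_diameter", "must be >= 1")
  if (!(cfg$background_mean > cfg$tissue_mean)) {
    fail("tissue_mean", "must be darker (smaller) than background_mean")
  }
  if (!(cfg$tissue_mean > cfg$dab_mean)) {
    fail("dab_mean", "must be darker (smaller) than tissue_mean")
  }
  for (f in c("dab_fraction_hr", "dab_fraction_lr")) {
    v <- cfg[[f]]
    if (is.na(v) || v < 0 || v > 1) fail(f, "must lie in [0, 1]")
  }
  for (f in c("background_sd", "tissue_sd", "dab_sd",
              "patient_sd", "core_sd")) {
    if (cfg[[f]] < 0) fail(f, "must be non-negative")
  }
  if (is.na(cfg$seed)) fail("seed", "must be a finite integer")
  invisible(cfg)
}
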