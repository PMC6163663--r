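# Shared fixtures and independent oracles. Oracles are deliberately
# naive (loops, full enumeration) and never share code with the
# implementation paths they check.

# the worked three-class intensity map: 6000 px background (250),
# 3000 px tissue (150), 1000 px DAB (60)
three_class_map <- function() {
  matrix(c(rep(250, 6000), rep(150, 3000), rep(60, 1000)), 100, 100)
}

# small noise-free cohort with exactly separable intensity classes
noise_free_config <- function(n_pairs = 3, cores_per_patient = 2,
                              image_side = 48, core_diameter = 40,
                              dab_fraction_hr = 0.4, dab_fraction_lr = 0.1,
                              seed = 11) {
  cohort_config(
    n_pairs = n_pairs, cores_per_patient = cores_per_patient,
    image_side = image_side, core_diameter = core_diameter,
    background_sd = 0, tissue_sd = 0, dab_sd = 0,
    dab_fraction_hr = dab_fraction_hr, dab_fraction_lr = dab_fraction_lr,
    patient_sd = 0, core_sd = 0, seed = seed
  )
}

# naive per-pixel double loop for the two-threshold measurement
naive_measure <- function(intensity, t_tissue, t_signal) {
  amt_t <- 0L; amt_s <- 0L
  for (i in seq_len(nrow(intensity))) {
    for (j in seq_len(ncol(intensity))) {
      v <- intensity[i, j]
      if (v < t_tissue) amt_t <- amt_t + 1L
      if (v < t_signal) amt_s <- amt_s + 1L
    }
  }
  list(amt_t = amt_t, amt_s = amt_s)
}

# pairwise-counting U for group x (favourable pairs + half ties)
naive_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

# exact two-sided p by full enumeration of label assignments, doubling
# the smaller tail of the pairwise-count U distribution
enumerate_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  u_obs <- naive_u(x, y)
  sets <- utils::combn(length(pool), n1)
  u_all <- apply(sets, 2, function(idx) naive_u(pool[idx], pool[-idx]))
  eps <- 1e-9
  min(1, 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps)))
}

# trapezoidal area under the empirical ROC in (1 - sp, se) space
trapezoid_area <- function(points) {
  fpr <- rev(1 - points$sp)   # ascending
  tpr <- rev(points$se)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# a quantification-like tibble from raw scores, for stats-level tests
quant_from_scores <- function(hr, lr) {
  tibble::tibble(
    core_id = sprintf("C%04d", seq_len(length(hr) + length(lr))),
    patient_id = sprintf("P%04d", seq_len(length(hr) + length(lr))),
    pair_id = NA_character_,
    group = rep(c("HR", "LR"), c(length(hr), length(lr))),
    amt_t = 1000L,
    amt_s = NA_integer_,
    ratio = c(hr, lr),
    valid = TRUE
  )
}

rscript_bin <- function() file.path(R.home("bin"), "Rscript")

cli_script <- function() {
  system.file("cli", "tma_pipeline.R", package = "tmaquant")
}

run_cli <- function(args) {
  out <- suppressWarnings(
    system2(rscript_bin(), c(cli_script(), args),
            stdout = TRUE, stderr = TRUE)
  )
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}
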