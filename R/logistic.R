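# Logistic combination of markers. The fit is ordinary binomial
# maximum likelihood (IRLS, as implemented by stats::glm), with a
# quasi-separation guard: runaway coefficients indicate the likelihood
# has no interior maximum, so the model is reported as not converged
# and the coefficients are withheld.

#' Fit a logistic combination of one or more markers
#'
#' @param markers A numeric matrix or data frame, cores x markers
#'   (expression ratios; no missing values — invalid cores are excluded
#'   upstream).
#' @param labels Group labels; `positive` is coded 1.
#' @param positive Positive-class label (default "HR").
#' @param max_iter IRLS iteration cap (default 50).
#' @param epsilon Convergence tolerance on the relative log-likelihood
#'   change (default 1e-8).
#' @param beta_bound Quasi-separation guard: if any |coefficient|
#'   exceeds this bound (default 20, in log-odds per unit ratio) the fit
#'   is flagged `converged = FALSE` and coefficients are withheld.
#' @return A `logistic_model`: `beta0`, `betas` (named, NULL unless
#'   converged), `converged`, `explanation`, `log_lik`,
#'   `accuracy_at_half` (share of cores whose fitted probability rounds
#'   to their label), `fitted` and `a_combined` (an [auc()] estimate on
#'   the fitted probabilities).
#' @export
fit_logistic <- function(markers, labels, positive = "HR",
                         max_iter = 50, epsilon = 1e-8, beta_bound = 20) {
  x <- as.matrix(markers)
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("marker", seq_len(ncol(x)))
  }
  if (anyNA(x)) stop("marker matrix contains missing values", call. = FALSE)
  y <- as.numeric(as.character(labels) == positive)
  if (all(y == 1) || all(y == 0)) {
    stop("both classes must be present", call. = FALSE)
  }
  dat <- data.frame(.y = y, x, check.names = FALSE)
  fit <- suppressWarnings(stats::glm(
    .y ~ ., data = dat, family = stats::binomial(),
    control = stats::glm.control(epsilon = epsilon, maxit = max_iter)
  ))
  cf <- stats::coef(fit)
  separated <- any(!is.finite(cf)) || max(abs(cf)) > beta_bound
  converged <- fit$converged && !separated
  p_hat <- as.numeric(stats::fitted(fit))
  lab_chr <- ifelse(y == 1, positive, paste0("not_", positive))
  structure(list(
    beta0 = if (converged) unname(cf[1]) else NA_real_,
    betas = if (converged) cf[-1] else NULL,
    converged = converged,
    explanation = if (converged) NA_character_ else if (separated) {
      sprintf("quasi-separation detected: max |beta| exceeds %g", beta_bound)
    } else "IRLS did not converge within the iteration cap",
    log_lik = as.numeric(stats::logLik(fit)),
    accuracy_at_half = mean((p_hat >= 0.5) == (y == 1)),
    fitted = p_hat,
    a_combined = auc(p_hat, lab_chr, positive = positive)
  ), class = "logistic_model")
}
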