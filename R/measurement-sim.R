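#' Variance-components simulator for agreement tables
#'
#' Draws a complete subjects-by-raters measurement table from the two-way
#' random-effects model underlying the intraclass correlation,
#' `y_ij = mu + b_i + o_j + e_ij`, with independent Normal subject, rater
#' and residual effects. The implied true single-measure agreement ICC is
#' `sigma_subject^2 / (sigma_subject^2 + sigma_observer^2 + sigma_error^2)`.
#'
#' @param mu grand mean, in measurement units (fractal-dimension units for
#'   the retinal application).
#' @param sigma_subject,sigma_observer,sigma_error standard deviations of
#'   the subject, rater and residual effects (all `>= 0`).
#' @param n_subjects,n_raters table dimensions; both at least 2.
#' @param seed integer RNG seed.
#' @return `variance_components_params()`: a parameter list with the implied
#'   `true_icc`; `simulate_measurement_table()`: a long-format data frame
#'   with columns `participant_id`, `rater_id`, `value`.
#' @export
variance_components_params <- function(mu = 1.69, sigma_subject = 0.03,
                                       sigma_observer = 0, sigma_error = 0.01,
                                       n_subjects = 43L, n_raters = 2L,
                                       seed = 1L) {
  if (sigma_subject < 0 || sigma_observer < 0 || sigma_error < 0)
    stop_config("all sigmas must be >= 0")
  if (n_subjects < 2L) stop_config("n_subjects must be at least 2")
  if (n_raters < 2L) stop_config("n_raters must be at least 2")
  tot <- sigma_subject^2 + sigma_observer^2 + sigma_error^2
  structure(list(mu = mu, sigma_subject = sigma_subject,
                 sigma_observer = sigma_observer, sigma_error = sigma_error,
                 n_subjects = as.integer(n_subjects),
                 n_raters = as.integer(n_raters), seed = as.integer(seed),
                 true_icc = if (tot > 0) sigma_subject^2 / tot else NA_real_),
            class = "variance_components_params")
}

#' @rdname variance_components_params
#' @param params a [variance_components_params()] object.
#' @export
simulate_measurement_table <- function(params = variance_components_params()) {
  if (!inherits(params, "variance_components_params"))
    params <- do.call(variance_components_params, params)
  n <- params$n_subjects; k <- params$n_raters
  with_seed(params$seed, {
    b <- rnorm(n, 0, params$sigma_subject)
    o <- rnorm(k, 0, params$sigma_observer)
    e <- matrix(rnorm(n * k, 0, params$sigma_error), n, k)
    y <- params$mu + outer(b, rep(1, k)) + outer(rep(1, n), o) + e
    data.frame(participant_id = rep(sprintf("S%03d", seq_len(n)), times = k),
               rater_id = rep(sprintf("R%d", seq_len(k)), each = n),
               value = as.vector(y), stringsAsFactors = FALSE)
  })
}
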