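#' Replicate simulation for calibration and parameter recovery
#'
#' Repeatedly builds a fresh design for one experiment, simulates observers
#' under a scenario, fits the capture-time mixed model and extracts the
#' quantities used to calibrate the statistical pipeline:
#' \itemize{
#'   \item the headline among-participant interference contrast
#'     (solid-B search then test of type A, versus solid-A search then test
#'     of type A; in experiment C this is distractive-to-disruptive
#'     switching against disruptive-only),
#'   \item the likelihood-ratio test for the slide-by-phase-treatment
#'     interaction,
#'   \item the within-participant training-to-search contrasts for both
#'     solid search conditions,
#'   \item the fitted signs of the three position-quadratic coefficients.
#' }
#' Fits use the model without the inversion factor: polarity inversion never
#' enters the generative model, and in experiments pairing disruptive prey
#' (which have no inverted variant) with an invertible type the flag is
#' structurally confounded with prey type.
#' The contrast is computed from the model retained by the interaction LRT
#' (the simplification rule restricted to the one tested term).
#'
#' @param scenario `"paperlike"` or `"null"`.
#' @param n_reps number of replicates.
#' @param seed integer seed; replicate seeds derive from it.
#' @param experiment experiment label (default `"C"`, the
#'   disruptive/distractive pairing carrying the injected interference).
#' @param n_per_arm participants per arm (default 20, the study size).
#' @param alpha significance level for the recorded rejections.
#' @return Data frame with one row per replicate: `headline_estimate`,
#'   `headline_t`, `headline_p`, `headline_reject`, `lrt_chisq`, `lrt_p`,
#'   `lrt_reject`, `train_to_searchA_estimate`, `train_to_searchA_p`,
#'   `train_to_searchB_estimate`, `train_to_searchB_p`, `gamma1_sign`,
#'   `gamma2_sign`, `gamma3_sign`.
#' @export
calibration_replicates <- function(scenario = c("paperlike", "null"),
                                   n_reps = 100L, seed = 1L,
                                   experiment = "C", n_per_arm = 20L,
                                   alpha = 0.05) {
  scenario <- match.arg(scenario)
  params <- default_params(scenario)
  spec_full <- model_spec(inverted = FALSE, slide_phase_interaction = TRUE)
  spec_red <- model_spec(inverted = FALSE, slide_phase_interaction = FALSE)
  headline <- data.frame(label = "headline", level_a = "testB-A",
                         level_b = "testA-A",
                         comparison_class = "among_participant")
  train <- data.frame(label = c("train_to_searchA", "train_to_searchB"),
                      level_a = c("searchA", "searchB"),
                      level_b = "learning",
                      comparison_class = "within_participant")
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    design <- build_experiment(experiment, n_per_arm,
                               derive_seed(seed, "design", r))
    trials <- simulate_trials(design, params,
                              derive_seed(seed, "simulate", r),
                              validate = FALSE)
    tab <- prepare_trials(trials)
    fit_full <- fit_model(tab, spec_full, "ML")
    fit_red <- fit_model(tab, spec_red, "ML")
    res <- lrt(fit_red, fit_full, "slide_in_phase:phase_treatment")
    fit_use <- if (res$p > alpha) fit_red else fit_full
    hc <- planned_contrasts(fit_use, headline)
    tc <- planned_contrasts(fit_use, train)
    co <- fit_full$coefficients
    gsign <- function(term) sign(co$estimate[co$term == term])
    out[[r]] <- data.frame(
      headline_estimate = hc$estimate, headline_t = hc$t,
      headline_p = hc$p, headline_reject = hc$p < alpha,
      lrt_chisq = res$chisq, lrt_p = res$p, lrt_reject = res$p < alpha,
      train_to_searchA_estimate = tc$estimate[1],
      train_to_searchA_p = tc$p[1],
      train_to_searchB_estimate = tc$estimate[2],
      train_to_searchB_p = tc$p[2],
      gamma1_sign = gsign("I(xs^2)"), gamma2_sign = gsign("I(ys^2)"),
      gamma3_sign = gsign("xs:ys"))
  }
  do.call(rbind, out)
}
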