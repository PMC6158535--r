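test_that("trial preparation applies the timeout policy and unit conventions", {
  trials <- small_trial_table("B", n_per_arm = 2, seed = 42)
  fake <- trials[1:100, ]
  fake$timed_out <- FALSE
  fake$timed_out[1:3] <- TRUE
  fake$capture_time_ms[1:3] <- NA_integer_
  fake$capture_time_ms[4] <- 1000L
  tab <- prepare_trials(fake)
  expect_equal(nrow(tab), 97)
  expect_equal(tab$log_time[tab$capture_time_ms == 1000][1], 0)
  expect_true(all(abs(tab$xs) <= 1 & abs(tab$ys) <= 1))
  expect_true(all(tab$slide_in_phase >= 1 & tab$slide_in_phase <= 32))
  expect_true(all(tab$slide_in_phase[tab$phase != "learning"] <= 16))
  ceil <- prepare_trials(fake, "ceiling")
  expect_equal(nrow(ceil), 100)
  expect_equal(ceil$log_time[1:3], rep(log(30), 3))
  allcens <- fake
  allcens$timed_out <- TRUE
  expect_error(prepare_trials(allcens), "censored")
})

test_that("the degenerate fixed-effects model matches a normal-equations oracle", {
  trials <- small_trial_table("B", n_per_arm = 2, seed = 42,
                              params = zero_params(resid_sd = 0.4,
                                                   gamma = c(0.2, 0.2, 0.1)))
  tab <- prepare_trials(trials)
  spec <- model_spec(inverted = FALSE, slide_phase_interaction = FALSE,
                     random_effects = character(0))
  fit <- fit_model(tab, spec)
  X <- model.matrix(~ xs + I(xs^2) + ys + I(ys^2) + xs:ys + slide_in_phase +
                      phase_treatment, tab)
  beta_ols <- solve(crossprod(X), crossprod(X, tab$log_time))
  expect_equal(fit$coefficients$estimate,
               unname(beta_ols[fit$coefficients$term, 1]), tolerance = 1e-6)
})

test_that("doubling capture times shifts only the intercept by log 2", {
  trials <- small_trial_table("B", n_per_arm = 2, seed = 42)
  tab1 <- prepare_trials(trials)
  doubled <- trials
  doubled$capture_time_ms <- doubled$capture_time_ms * 2L
  tab2 <- prepare_trials(doubled)
  spec <- model_spec(random_effects = character(0))
  f1 <- fit_model(tab1, spec)
  f2 <- fit_model(tab2, spec)
  shift <- f2$coefficients$estimate - f1$coefficients$estimate
  names(shift) <- f1$coefficients$term
  expect_equal(shift[["(Intercept)"]], log(2), tolerance = 1e-8)
  expect_true(all(abs(shift[names(shift) != "(Intercept)"]) < 1e-8))
})

test_that("structurally aliased inversion terms are reported or rejected", {
  # experiment A pairs BM with non-invertible disruptive prey, so some
  # inverted-by-phase cells are empty and the full model is rank deficient
  trials <- small_trial_table("A", n_per_arm = 2, seed = 31)
  tab <- prepare_trials(trials)
  fit <- fit_model(tab, model_spec())
  expect_gt(length(fit$aliased), 0)
  expect_true(all(grepl("inverted", fit$aliased)))
  expect_error(fit_model(tab, model_spec(), on_alias = "error"),
               "rank deficient")
})

test_that("likelihood-ratio tests equal direct log-likelihood arithmetic", {
  trials <- small_trial_table("B", n_per_arm = 2, seed = 42)
  full_tab <- prepare_trials(trials)
  tab <- full_tab[round(seq(1, nrow(full_tab), length.out = 50)), ]
  tab$phase_treatment <- droplevels(tab$phase_treatment)
  spec_full <- model_spec(inverted = FALSE, slide_phase_interaction = FALSE,
                          random_effects = "participant_id")
  spec_red <- model_spec(inverted = FALSE, xy_interaction = FALSE,
                         slide_phase_interaction = FALSE,
                         random_effects = "participant_id")
  f_full <- fit_model(tab, spec_full, "ML")
  f_red <- fit_model(tab, spec_red, "ML")
  res <- lrt(f_red, f_full, "xs:ys")
  expect_equal(res$chisq,
               max(0, 2 * (as.numeric(logLik(f_full$model)) -
                             as.numeric(logLik(f_red$model)))),
               tolerance = 1e-10)
  expect_equal(res$df, 1)
  expect_equal(res$p, pchisq(res$chisq, 1, lower.tail = FALSE))
  # identical models: zero statistic, p = 1
  same <- lrt(f_full, f_full, "none")
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)
  # guards: REML fits and row mismatches are rejected
  f_reml <- fit_model(tab, spec_full, "REML")
  expect_error(lrt(f_red, f_reml), "ML")
  f_fewer <- fit_model(tab[1:40, ], spec_red, "ML")
  expect_error(lrt(f_fewer, f_full), "different rows")
})

test_that("model simplification records exactly three ordered tests and honest drops", {
  # strong xy interaction and no inversion effect: experiment B keeps the
  # inversion flag orthogonal to prey type, so it should be dropped while
  # the coordinate interaction is retained
  trials <- small_trial_table("B", n_per_arm = 6, seed = 77,
                              params = zero_params(resid_sd = 0.4,
                                                   gamma = c(0.15, 0.15, 0.3),
                                                   tau_p = 0.2))
  tab <- prepare_trials(trials)
  sim <- simplify_model(tab)
  expect_length(sim$lrts, 3)
  expect_equal(vapply(sim$lrts, `[[`, "", "term"),
               c("slide_in_phase:phase_treatment", "xs:ys", "inverted"))
  expect_true("inverted" %in% sim$dropped)
  expect_false("xs:ys" %in% sim$dropped)
  expect_true("slide_in_phase:phase_treatment" %in% sim$dropped)
  expect_s3_class(sim$final, "fit_result")
  expect_false(sim$final$spec$inverted)
})

test_that("planned contrasts satisfy their identities and match emmeans", {
  trials <- small_trial_table("B", n_per_arm = 4, seed = 13)
  tab <- prepare_trials(trials)
  fit <- fit_model(tab, model_spec(inverted = FALSE,
                                   slide_phase_interaction = FALSE))
  cat_df <- contrast_catalogue("B")
  res <- planned_contrasts(fit, cat_df)
  expect_equal(nrow(res), 18)
  expect_equal(res$t, res$estimate / res$se, tolerance = 1e-10)
  expect_setequal(unique(res$comparison_class),
                  c("within_participant", "among_participant"))
  # identity contrast: a level against itself
  self_cat <- data.frame(label = "self", level_a = "searchA",
                         level_b = "searchA", comparison_class = "within_participant")
  self <- planned_contrasts(fit, self_cat)
  expect_equal(self$estimate, 0)
  expect_equal(self$t, 0)
  # unknown level
  bad <- data.frame(label = "bad", level_a = "searchZ", level_b = "learning",
                    comparison_class = "within_participant")
  expect_error(planned_contrasts(fit, bad), "unknown")
  # independent route: emmeans adjusted means on the same fitted model
  emm <- emmeans::emmeans(fit$model, ~phase_treatment, data = tab,
                          at = list(xs = 0, ys = 0, slide_in_phase = 8.5),
                          lmer.df = "asymptotic")
  emm_df <- as.data.frame(emm)
  for (i in c(1, 4, 10, 15)) {
    ea <- emm_df$emmean[emm_df$phase_treatment == res$level_a[i]]
    eb <- emm_df$emmean[emm_df$phase_treatment == res$level_b[i]]
    expect_equal(res$estimate[i], ea - eb, tolerance = 1e-6)
  }
})

test_that("the per-experiment report carries the full pipeline output", {
  trials <- small_trial_table("C", n_per_arm = 2, seed = 12)
  rep <- analyze_experiment(trials)
  expect_s3_class(rep, "analysis_report")
  expect_equal(rep$experiment, "C")
  expect_equal(nrow(rep$lrt_table), 3)
  expect_equal(nrow(rep$contrasts), 18)
  expect_true(all(c("participant", "background", "residual") %in%
                    names(rep$varcomp)))
  expect_equal(rep$n_modelled, sum(!trials$timed_out))
  expect_output(print(rep), "planned contrasts")
})
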