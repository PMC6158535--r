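#' Prepare trial records for modelling
#'
#' Builds the modelling table: the response is the natural log of capture
#' time in seconds; screen coordinates are standardized to [-1, 1] about the
#' canvas centre (raw pixels would condition the quadratic design badly);
#' slide number is re-expressed within phase; phase treatment is attached as
#' a 10-level factor. Timed-out encounters are excluded under the default
#' policy, or set to the log of the 30 s ceiling under `"ceiling"`.
#'
#' @param trials a `trial_table` from [simulate_trials()] or [read_trials()].
#' @param timeout_policy `"exclude"` or `"ceiling"`.
#' @return Data frame with columns `log_time`, `xs`, `ys`,
#'   `slide_in_phase`, `phase_treatment` (factor), `inverted`,
#'   `participant_id`, `background_id` and the original design columns.
#' @export
prepare_trials <- function(trials, timeout_policy = c("exclude", "ceiling")) {
  timeout_policy <- match.arg(timeout_policy)
  d <- as.data.frame(trials)
  if (timeout_policy == "exclude") {
    d <- d[!d$timed_out, , drop = FALSE]
    if (!nrow(d)) stop_invalid("all rows are censored; nothing to model")
    d$log_time <- log(d$capture_time_ms / 1000)
  } else {
    d$log_time <- ifelse(d$timed_out, log(TIMEOUT_S),
                         log(d$capture_time_ms / 1000))
  }
  st <- standardize_coords(d$x, d$y)
  d$xs <- st$x
  d$ys <- st$y
  d$slide_in_phase <- slide_within_phase(d$slide_index)
  d$phase_treatment <- factor(d$phase_treatment,
                              levels = PHASE_TREATMENT_LEVELS)
  d$phase_treatment <- droplevels(d$phase_treatment)
  d$participant_id <- factor(d$participant_id)
  d$background_id <- factor(d$background_id)
  d
}

#' Specify the capture-time mixed model
#'
#' The full model regresses log capture time on a quadratic in the
#' standardized X and Y screen coordinates with their interaction, the
#' polarity-inversion flag, slide number within phase, the 10-level phase
#' treatment, and all two-way interactions among inverted, slide and phase
#' treatment, with random intercepts for participant and background image.
#' Components can be switched off to express the reduced models used in
#' likelihood-ratio simplification.
#'
#' @param inverted include the inversion flag (and its interactions).
#' @param xy_interaction include the X-by-Y coordinate interaction.
#' @param slide_phase_interaction include slide-by-phase-treatment.
#' @param inverted_interactions include inverted-by-slide and
#'   inverted-by-phase-treatment (ignored when `inverted = FALSE`).
#' @param random_effects character vector of random-intercept grouping
#'   columns (possibly empty, giving an ordinary linear model).
#' @return A list of class `model_spec` with a `formula` element.
#' @export
model_spec <- function(inverted = TRUE, xy_interaction = TRUE,
                       slide_phase_interaction = TRUE,
                       inverted_interactions = inverted,
                       random_effects = c("participant_id", "background_id")) {
  fixed <- c("xs", "I(xs^2)", "ys", "I(ys^2)",
             if (xy_interaction) "xs:ys",
             "slide_in_phase", "phase_treatment",
             if (inverted) "inverted",
             if (inverted && inverted_interactions)
               c("inverted:slide_in_phase", "inverted:phase_treatment"),
             if (slide_phase_interaction) "slide_in_phase:phase_treatment")
  rand <- if (length(random_effects))
    sprintf("(1 | %s)", random_effects) else character(0)
  f <- stats::as.formula(paste("log_time ~",
                               paste(c(fixed, rand), collapse = " + ")),
                         env = globalenv())
  structure(list(formula = f, fixed_terms = fixed,
                 random_effects = random_effects,
                 inverted = inverted, xy_interaction = xy_interaction,
                 slide_phase_interaction = slide_phase_interaction,
                 inverted_interactions = inverted && inverted_interactions),
            class = "model_spec")
}

#' Fit the capture-time model
#'
#' Fits the linear mixed model of a [model_spec()] by maximum likelihood
#' (default; keeps likelihood-ratio tests between fixed-effect structures
#' valid) or REML. With no random effects the model is fitted by ordinary
#' least squares. Structurally aliased fixed-effect columns (e.g. inversion
#' contrasts inside phase-treatment cells where only non-invertible prey
#' occur) are dropped and recorded by default; `on_alias = "error"` raises
#' an error naming them instead.
#'
#' @param table output of [prepare_trials()].
#' @param spec a [model_spec()].
#' @param criterion `"ML"` or `"REML"`.
#' @param on_alias `"drop"` or `"error"`.
#' @return A `fit_result`: list with `model` (lmerMod or lm), `coefficients`
#'   (data frame: term, estimate, se, t), `varcomp` (named vector:
#'   participant, background, residual SDs), `logLik`, `n`, `converged`,
#'   `criterion`, `aliased` (character), `spec`.
#' @export
fit_model <- function(table, spec = model_spec(),
                      criterion = c("ML", "REML"),
                      on_alias = c("drop", "error")) {
  criterion <- match.arg(criterion)
  on_alias <- match.arg(on_alias)
  if (!nrow(table)) stop_invalid("empty modelling table")
  fixed_formula <- stats::as.formula(
    paste("log_time ~", paste(spec$fixed_terms, collapse = " + ")),
    env = globalenv())
  X <- stats::model.matrix(fixed_formula, table)
  qrX <- qr(X)
  aliased <- if (qrX$rank < ncol(X))
    colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]] else character(0)
  if (length(aliased) && on_alias == "error")
    stop_invalid("fixed-effect design is rank deficient; aliased terms: %s",
                 paste(aliased, collapse = ", "))
  if (length(spec$random_effects)) {
    fit <- suppressMessages(lme4::lmer(
      spec$formula, data = table, REML = (criterion == "REML"),
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore")))
    beta <- lme4::fixef(fit)
    se <- sqrt(Matrix::diag(stats::vcov(fit)))
    vc <- as.data.frame(lme4::VarCorr(fit))
    sd_of <- function(g) {
      hit <- vc$sdcor[vc$grp == g]
      if (length(hit)) hit[1] else NA_real_
    }
    varcomp <- c(participant = sd_of("participant_id"),
                 background = sd_of("background_id"),
                 residual = sd_of("Residual"))
    conv <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0 &&
      fit@optinfo$conv$opt == 0
    n <- stats::nobs(fit)
  } else {
    fit <- stats::lm(spec$formula, data = table)
    sm <- summary(fit)
    keep <- !is.na(stats::coef(fit))
    beta <- stats::coef(fit)[keep]
    se <- sm$coefficients[, "Std. Error"]
    varcomp <- c(participant = NA_real_, background = NA_real_,
                 residual = sm$sigma)
    conv <- TRUE
    n <- stats::nobs(fit)
  }
  structure(list(model = fit,
                 coefficients = data.frame(term = names(beta),
                                           estimate = unname(beta),
                                           se = unname(se),
                                           t = unname(beta) / unname(se),
                                           stringsAsFactors = FALSE),
                 varcomp = varcomp,
                 logLik = as.numeric(stats::logLik(fit)),
                 n = n, converged = conv, criterion = criterion,
                 aliased = aliased, spec = spec),
            class = "fit_result")
}

#' Likelihood-ratio test between nested fits
#'
#' Twice the log-likelihood difference between a full and a nested model,
#' referred to a chi-square with degrees of freedom equal to the difference
#' in estimated fixed-effect coefficients. Both fits must be by ML on the
#' same rows.
#'
#' @param nested,full `fit_result`s; the nested model's fixed terms must be
#'   a subset of the full model's.
#' @param term label for the tested term(s).
#' @return An `lrt_result`: list with `term`, `chisq`, `df`, `p`.
#' @export
lrt <- function(nested, full, term = "term") {
  if (nested$criterion != "ML" || full$criterion != "ML")
    stop_invalid("LRT requires ML fits (got %s vs %s)",
                 nested$criterion, full$criterion)
  if (nested$n != full$n)
    stop_invalid("LRT fits use different rows (%d vs %d)", nested$n, full$n)
  df <- nrow(full$coefficients) - nrow(nested$coefficients)
  if (df < 0) stop_invalid("`nested` has more coefficients than `full`")
  chisq <- max(0, 2 * (full$logLik - nested$logLik))
  p <- if (df == 0) 1 else stats::pchisq(chisq, df, lower.tail = FALSE)
  structure(list(term = term, chisq = chisq, df = max(df, 1L), p = p),
            class = "lrt_result")
}

#' Likelihood-ratio model simplification
#'
#' Tests, in order, the redundancy of (1) the slide-by-phase-treatment
#' interaction, (2) the X-by-Y coordinate interaction, and (3) the inversion
#' factor (with its interactions). A term is dropped when its LRT p exceeds
#' `alpha`; every test is recorded and the final model refitted.
#'
#' @param table output of [prepare_trials()].
#' @param full_spec the full [model_spec()].
#' @param alpha retention threshold (default 0.05).
#' @return List with `final` (`fit_result`), `lrts` (list of 3
#'   `lrt_result`), `dropped` (character).
#' @export
simplify_model <- function(table, full_spec = model_spec(), alpha = 0.05) {
  respec <- function(spec, ...) {
    args <- utils::modifyList(
      list(inverted = spec$inverted, xy_interaction = spec$xy_interaction,
           slide_phase_interaction = spec$slide_phase_interaction,
           inverted_interactions = spec$inverted_interactions,
           random_effects = spec$random_effects),
      list(...))
    do.call(model_spec, args)
  }
  current <- full_spec
  fit_cur <- fit_model(table, current, "ML")
  lrts <- vector("list", 3)
  dropped <- character(0)

  step <- function(reduced_spec, label) {
    fit_red <- fit_model(table, reduced_spec, "ML")
    res <- lrt(fit_red, fit_cur, label)
    list(fit = fit_red, res = res)
  }
  # 1. slide x phase-treatment interaction
  s1 <- step(respec(current, slide_phase_interaction = FALSE),
             "slide_in_phase:phase_treatment")
  lrts[[1]] <- s1$res
  if (s1$res$p > alpha) {
    current <- respec(current, slide_phase_interaction = FALSE)
    fit_cur <- s1$fit
    dropped <- c(dropped, "slide_in_phase:phase_treatment")
  }
  # 2. X x Y coordinate interaction
  s2 <- step(respec(current, xy_interaction = FALSE), "xs:ys")
  lrts[[2]] <- s2$res
  if (s2$res$p > alpha) {
    current <- respec(current, xy_interaction = FALSE)
    fit_cur <- s2$fit
    dropped <- c(dropped, "xs:ys")
  }
  # 3. the inversion factor and its interactions
  s3 <- step(respec(current, inverted = FALSE,
                    inverted_interactions = FALSE), "inverted")
  lrts[[3]] <- s3$res
  if (s3$res$p > alpha) {
    current <- respec(current, inverted = FALSE,
                      inverted_interactions = FALSE)
    fit_cur <- s3$fit
    dropped <- c(dropped, "inverted")
  }
  list(final = fit_cur, lrts = lrts, dropped = dropped)
}

#' The planned phase-treatment contrast catalogue
#'
#' Mirrors the structure of the study's planned-comparison table. The
#' within-participant block compares phases an individual passes through:
#' training (learning) against each search-image condition, and each
#' search-image condition against its two test phases. The among-participant
#' block compares conditions experienced by different participants: the three
#' search-condition pairs and, within each test-phase prey type, the three
#' pairs of search histories.
#'
#' @param experiment `"A"`, `"B"` or `"C"`; used only to substitute the
#'   experiment's camouflage-type names into human-readable labels.
#' @return Data frame with `label`, `level_a`, `level_b`,
#'   `comparison_class`.
#' @export
contrast_catalogue <- function(experiment = c("A", "B", "C")) {
  experiment <- match.arg(experiment)
  ty <- experiment_types(experiment)
  within <- rbind(
    c("searchA", "learning"), c("searchAB", "learning"),
    c("searchB", "learning"),
    c("testA-A", "searchA"), c("testA-B", "searchA"),
    c("testAB-A", "searchAB"), c("testAB-B", "searchAB"),
    c("testB-A", "searchB"), c("testB-B", "searchB"))
  among <- rbind(
    c("searchA", "searchAB"), c("searchB", "searchAB"),
    c("searchA", "searchB"),
    c("testB-A", "testA-A"), c("testAB-A", "testA-A"),
    c("testB-A", "testAB-A"),
    c("testA-B", "testB-B"), c("testAB-B", "testB-B"),
    c("testA-B", "testAB-B"))
  cat_df <- data.frame(
    level_a = c(within[, 1], among[, 1]),
    level_b = c(within[, 2], among[, 2]),
    comparison_class = rep(c("within_participant", "among_participant"),
                           c(nrow(within), nrow(among))),
    stringsAsFactors = FALSE)
  pretty <- function(lv) {
    lv <- sub("^searchA$", sprintf("search[%s]", ty[["A"]]), lv)
    lv <- sub("^searchB$", sprintf("search[%s]", ty[["B"]]), lv)
    lv <- sub("^searchAB$", sprintf("search[%s/%s]", ty[["A"]], ty[["B"]]), lv)
    lv <- sub("^testA-", sprintf("%s->", ty[["A"]]), lv)
    lv <- sub("^testB-", sprintf("%s->", ty[["B"]]), lv)
    lv <- sub("^testAB-", sprintf("%s/%s->", ty[["A"]], ty[["B"]]), lv)
    lv <- sub("->A$", paste0("->", ty[["A"]]), lv)
    sub("->B$", paste0("->", ty[["B"]]), lv)
  }
  cat_df$label <- paste(pretty(cat_df$level_a), "vs", pretty(cat_df$level_b))
  cat_df[, c("label", "level_a", "level_b", "comparison_class")]
}

# Model-matrix row for a phase-treatment level at reference covariate values
# (screen centre, non-inverted, slide at the phase midpoint).
level_row <- function(fit, level, slide_ref) {
  mf <- stats::model.frame(fit$model)
  pt <- mf$phase_treatment
  nd <- data.frame(xs = 0, ys = 0, slide_in_phase = slide_ref,
                   inverted = FALSE,
                   phase_treatment = factor(level, levels = levels(pt)))
  fixed_formula <- stats::as.formula(
    paste("~", paste(fit$spec$fixed_terms, collapse = " + ")),
    env = globalenv())
  X <- stats::model.matrix(fixed_formula, nd)
  X[1, fit$coefficients$term, drop = TRUE]
}

#' Planned comparisons between phase-treatment levels
#'
#' Estimates, for each catalogue entry, the difference between the adjusted
#' means of two phase-treatment levels (other fixed effects held at reference
#' values: screen centre, non-inverted, slide number at the phase midpoint),
#' with standard error from the fixed-effect covariance, t = estimate / se,
#' and a two-sided p-value. Inference uses the normal approximation by
#' default; supply finite `df` for a t reference (e.g. a Satterthwaite-style
#' correction computed elsewhere).
#'
#' @param fit a `fit_result` (typically the simplified model).
#' @param catalogue a [contrast_catalogue()] (or compatible data frame).
#' @param slide_ref reference slide-within-phase (default 8.5, the midpoint
#'   of a 16-slide phase).
#' @param df degrees of freedom for the reference distribution
#'   (`Inf` = normal approximation).
#' @return Data frame of `contrast_result`s: `label`, `level_a`, `level_b`,
#'   `comparison_class`, `estimate`, `se`, `t`, `p`.
#' @export
planned_contrasts <- function(fit, catalogue, slide_ref = 8.5, df = Inf) {
  if (!fit$converged) warning("contrasts computed on a non-converged fit")
  pt_levels <- levels(stats::model.frame(fit$model)$phase_treatment)
  bad <- setdiff(unique(c(catalogue$level_a, catalogue$level_b)), pt_levels)
  if (length(bad))
    stop_invalid("catalogue references unknown phase-treatment level(s): %s",
                 paste(bad, collapse = ", "))
  V <- as.matrix(stats::vcov(fit$model))
  beta <- fit$coefficients$estimate
  out <- catalogue
  out$estimate <- out$se <- out$t <- out$p <- NA_real_
  for (i in seq_len(nrow(catalogue))) {
    cvec <- level_row(fit, catalogue$level_a[i], slide_ref) -
      level_row(fit, catalogue$level_b[i], slide_ref)
    est <- sum(cvec * beta)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tval <- if (se > 0) est / se else 0
    out$estimate[i] <- est
    out$se[i] <- se
    out$t[i] <- tval
    out$p[i] <- if (is.finite(df)) 2 * stats::pt(-abs(tval), df)
                else 2 * stats::pnorm(-abs(tval))
  }
  out
}

#' Run the full statistical pipeline for one experiment
#'
#' Prepares trials, fits and simplifies the mixed model, and computes the
#' planned contrasts, returning a machine-readable report.
#'
#' @param trials a `trial_table` for a single experiment.
#' @param experiment `"A"`, `"B"` or `"C"` (defaults to the table's own
#'   label).
#' @param timeout_policy passed to [prepare_trials()].
#' @param full_spec the full [model_spec()].
#' @return List of class `analysis_report`: `experiment`, `n_modelled`,
#'   `lrt_table`, `coefficients`, `varcomp`, `contrasts`, `dropped`.
#' @export
analyze_experiment <- function(trials, experiment = NULL,
                               timeout_policy = "exclude",
                               full_spec = model_spec()) {
  experiment <- experiment %||% unique(trials$experiment)
  if (length(experiment) != 1)
    stop_invalid("trials span multiple experiments; analyse them separately")
  tab <- prepare_trials(trials, timeout_policy)
  sim <- simplify_model(tab, full_spec)
  contrasts <- planned_contrasts(sim$final, contrast_catalogue(experiment))
  structure(list(
    experiment = experiment,
    n_modelled = sim$final$n,
    lrt_table = do.call(rbind, lapply(sim$lrts, function(l)
      data.frame(term = l$term, chisq = l$chisq, df = l$df, p = l$p,
                 stringsAsFactors = FALSE))),
    coefficients = sim$final$coefficients,
    varcomp = sim$final$varcomp,
    contrasts = contrasts,
    dropped = sim$dropped), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report experiment %s> %d modelled rows\n",
              x$experiment, x$n_modelled))
  cat("LRT simplification:\n")
  print(x$lrt_table, row.names = FALSE, digits = 3)
  cat(sprintf("dropped: %s\n",
              if (length(x$dropped)) paste(x$dropped, collapse = ", ")
              else "(none)"))
  cat("planned contrasts:\n")
  print(x$contrasts[, c("label", "comparison_class", "estimate", "se",
                        "t", "p")], row.names = FALSE, digits = 3)
  invisible(x)
}
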