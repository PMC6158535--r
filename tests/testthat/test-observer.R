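centre_encounter <- function(type = "BM", slide = 1L) {
  list(prey_type = type, slide_index = slide, x = 959.5, y = 539.5)
}

test_that("the generative mean reduces to its components in closed form", {
  p0 <- zero_params()
  # all effects zero at the centre: exactly the baseline
  expect_equal(expected_log_time(p0, centre_encounter()), log(5))
  # run-length increments below the cap subtract exactly sigma[type]
  ps <- zero_params(sigma = c(BM = 0.05, D_RUP = 0, D_RAC = 0.1))
  e <- centre_encounter("D_RAC")
  for (r in 1:7) {
    expect_equal(expected_log_time(ps, e, run_length = r + 1) -
                   expected_log_time(ps, e, run_length = r), -0.1)
  }
  # at the cap the gain saturates
  expect_equal(expected_log_time(ps, e, run_length = ps$r_max + 5),
               expected_log_time(ps, e, run_length = ps$r_max + 1))
  # corner minus centre equals gamma1 + gamma2 + gamma3 at standardized (1, 1)
  pg <- zero_params(gamma = c(0.2, 0.1, 0.05))
  corner <- list(prey_type = "BM", slide_index = 1L, x = 1919, y = 1079)
  expect_equal(expected_log_time(pg, corner) -
                 expected_log_time(pg, centre_encounter()),
               0.2 + 0.1 + 0.05)
  # learning slope acts on slide-within-phase
  pt <- zero_params(theta = -0.02)
  expect_equal(expected_log_time(pt, centre_encounter(slide = 33L)),
               log(5))
  expect_equal(expected_log_time(pt, centre_encounter(slide = 40L)),
               log(5) - 0.02 * 7)
})

test_that("switch penalties decay geometrically and need a previous type", {
  pi_switch <- matrix(0, 3, 3, dimnames = list(PREY_TYPES, PREY_TYPES))
  pi_switch["D_RAC", "D_RUP"] <- 0.4
  pp <- zero_params(pi_switch = pi_switch, decay = 0.5)
  e <- centre_encounter("D_RUP")
  expect_equal(expected_log_time(pp, e, prev_type = NA_character_), log(5))
  expect_equal(expected_log_time(pp, e, post_switch_lag = 0,
                                 prev_type = "D_RAC"), log(5) + 0.4)
  expect_equal(expected_log_time(pp, e, post_switch_lag = 2,
                                 prev_type = "D_RAC"), log(5) + 0.4 * 0.25)
  expect_equal(expected_log_time(pp, e, post_switch_lag = 1,
                                 prev_type = "BM"), log(5))
})

test_that("noise-free simulation equals the scalar generative mean row by row", {
  design <- build_experiment("C", n_per_arm = 1, seed = 8)
  pi_switch <- matrix(0.1, 3, 3, dimnames = list(PREY_TYPES, PREY_TYPES))
  params <- observer_params(mu = c(BM = 0, D_RUP = 0.3, D_RAC = -0.1),
                            theta = -0.01,
                            sigma = c(BM = 0.02, D_RUP = 0, D_RAC = 0.04),
                            pi_switch = pi_switch, gamma = c(0.1, 0.1, 0.05),
                            tau_p = 0, tau_b = 0, resid_sd = 0)
  trials <- simulate_trials(design, params, seed = 1)
  # independent scalar recomputation with explicit run-history bookkeeping
  for (pid in unique(trials$participant_id)) {
    tp <- trials[trials$participant_id == pid, ]
    prev <- NA_character_; run <- 0L
    for (k in seq_len(nrow(tp))) {
      if (k > 1 && tp$prey_type[k] != tp$prey_type[k - 1]) {
        prev <- tp$prey_type[k - 1]; run <- 1L
      } else run <- run + 1L
      mu_k <- expected_log_time(params, tp[k, ], run_length = run,
                                post_switch_lag = run - 1L,
                                prev_type = prev)
      expect_equal(tp$capture_time_ms[k],
                   max(1L, as.integer(round(exp(mu_k) * 1000))))
      expect_equal(tp$run_length[k], run)
    }
  }
})

test_that("simulated capture times respect censoring conservation and the 30 s bound", {
  trials <- small_trial_table("C", n_per_arm = 2, seed = 12)
  expect_equal(sum(trials$timed_out) + sum(!trials$timed_out), nrow(trials))
  expect_true(all(is.na(trials$capture_time_ms[trials$timed_out])))
  expect_true(all(trials$capture_time_ms[!trials$timed_out] <= 30000))
  expect_true(all(trials$capture_time_ms[!trials$timed_out] >= 1))
  # determinism
  design <- build_experiment("A", n_per_arm = 1, seed = 3)
  t1 <- simulate_trials(design, default_params("paperlike"), seed = 5)
  t2 <- simulate_trials(design, default_params("paperlike"), seed = 5)
  expect_identical(t1$capture_time_ms, t2$capture_time_ms)
})

test_that("log capture times centre on the baseline in a pure-noise simulation", {
  design <- build_experiment("B", n_per_arm = 27, seed = 6)
  params <- zero_params(resid_sd = 0.3)
  trials <- simulate_trials(design, params, seed = 2, validate = FALSE)
  n <- sum(!trials$timed_out)
  expect_gt(n, 10000)
  m <- mean(log(trials$capture_time_ms[!trials$timed_out] / 1000))
  expect_lt(abs(m - log(5)), 3 * 0.3 / sqrt(n))
})

test_that("without injected phase structure per-type mean log times are phase-invariant", {
  design <- build_experiment("C", n_per_arm = 10, seed = 9)
  params <- zero_params(mu = c(BM = 0, D_RUP = 0.3, D_RAC = 0),
                        resid_sd = 0.3)
  trials <- simulate_trials(design, params, seed = 4, validate = FALSE)
  ok <- !trials$timed_out
  lt <- log(trials$capture_time_ms[ok] / 1000)
  grp <- interaction(trials$prey_type[ok], trials$phase[ok])
  means <- tapply(lt, grp, mean)
  ns <- tapply(lt, grp, length)
  for (ty in unique(trials$prey_type)) {
    cells <- grep(paste0("^", ty, "\\."), names(means), value = TRUE)
    for (a in cells) for (b in cells) {
      se <- 0.3 * sqrt(1 / ns[[a]] + 1 / ns[[b]])
      expect_lt(abs(means[[a]] - means[[b]]), 4 * se)
    }
  }
})

test_that("scenario presets encode the intended effect structure", {
  pl <- default_params("paperlike")
  expect_equal(pl$sigma[["D_RUP"]], 0)
  expect_gt(pl$sigma[["D_RAC"]], pl$sigma[["BM"]])
  expect_gt(pl$pi_switch["D_RAC", "D_RUP"], pl$pi_switch["D_RUP", "D_RAC"])
  expect_gte(pl$pi_switch["D_RUP", "D_RAC"], 0)
  nl <- default_params("null")
  expect_true(all(nl$sigma == 0))
  expect_true(all(nl$pi_switch == 0))
  expect_equal(nl$timeout_s, 30)
  expect_error(default_params("other"))
})
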