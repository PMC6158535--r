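#' Construct observer-simulation parameters
#'
#' Generative parameters for censored capture-time simulation on the
#' log-seconds scale. The expected log capture time of an encounter is
#' \deqn{\beta_0 + \mu_{type} + \theta (s - 1) - \sigma_{type}
#'   \min(r - 1, r_{max}) + \pi_{prev,type} \, \delta^{\ell}
#'   + \gamma_1 \tilde x^2 + \gamma_2 \tilde y^2 + \gamma_3 \tilde x \tilde y
#'   + u_p + v_b}
#' where s is the slide number within phase, r the consecutive same-type run
#' length, \eqn{\ell} the number of encounters since the last type switch,
#' and \eqn{\tilde x, \tilde y} the screen coordinates standardized to
#' [-1, 1] about the canvas centre. Latent times are log-normal and censored
#' at the 30 s timeout.
#'
#' @param beta0 baseline log-seconds.
#' @param mu named per-type detectability offsets (log-s) for BM, D_RUP,
#'   D_RAC.
#' @param theta within-phase learning slope (log-s per slide, <= 0).
#' @param sigma named per-type search-image gain (log-s per consecutive
#'   same-type encounter, >= 0).
#' @param r_max cap on the search-image run-length effect.
#' @param pi_switch 3 x 3 switch-penalty matrix (log-s), entry [from, to]
#'   applied after a type switch.
#' @param decay geometric decay of the switch penalty per post-switch
#'   encounter, in [0, 1).
#' @param gamma length-3 position coefficients: x^2, y^2, x*y terms on
#'   standardized coordinates.
#' @param tau_p,tau_b participant and background random-intercept SDs
#'   (log-s).
#' @param resid_sd residual SD (log-s).
#' @param timeout_s censoring bound in seconds (30).
#' @return A list of class `observer_params`.
#' @export
observer_params <- function(beta0 = log(5),
                            mu = c(BM = 0, D_RUP = 0.3, D_RAC = 0),
                            theta = -0.01,
                            sigma = c(BM = 0.02, D_RUP = 0, D_RAC = 0.04),
                            r_max = 8L,
                            pi_switch = matrix(0, 3, 3,
                              dimnames = list(PREY_TYPES, PREY_TYPES)),
                            decay = 0.9,
                            gamma = c(0.15, 0.15, 0.08),
                            tau_p = 0.25, tau_b = 0.08,
                            resid_sd = 0.5,
                            timeout_s = TIMEOUT_S) {
  stopifnot(setequal(names(mu), PREY_TYPES), setequal(names(sigma), PREY_TYPES),
            all(sigma >= 0), resid_sd >= 0, tau_p >= 0, tau_b >= 0,
            decay >= 0, decay < 1, identical(dim(pi_switch), c(3L, 3L)),
            length(gamma) == 3, timeout_s > 0)
  structure(list(beta0 = beta0, mu = mu[PREY_TYPES], theta = theta,
                 sigma = sigma[PREY_TYPES], r_max = as.integer(r_max),
                 pi_switch = pi_switch, decay = decay, gamma = gamma,
                 tau_p = tau_p, tau_b = tau_b, resid_sd = resid_sd,
                 timeout_s = timeout_s),
            class = "observer_params")
}

#' Default observer scenarios
#'
#' `"paperlike"` encodes the qualitative findings the analysis should
#' recover: disruptive prey yield no search-image gain (`sigma["D_RUP"] = 0`)
#' while distractive prey yield the largest, and switching from a distractive
#' search image to disruptive prey carries a positive interference penalty
#' (`pi_switch["D_RAC", "D_RUP"] > 0`). `"null"` zeroes every search-image
#' gain and switch penalty, leaving only type baselines, within-phase
#' learning, position effects and random intercepts — the reference
#' distribution for calibration of test size.
#'
#' @param scenario `"paperlike"` or `"null"`.
#' @return An `observer_params`.
#' @export
default_params <- function(scenario = c("paperlike", "null")) {
  scenario <- match.arg(scenario)
  pi_switch <- matrix(0, 3, 3, dimnames = list(PREY_TYPES, PREY_TYPES))
  if (scenario == "paperlike") {
    pi_switch["D_RAC", "D_RUP"] <- 0.6
    observer_params(pi_switch = pi_switch)
  } else {
    observer_params(sigma = c(BM = 0, D_RUP = 0, D_RAC = 0),
                    pi_switch = pi_switch)
  }
}

#' Standardize screen coordinates to [-1, 1]
#' @param x,y 0-based pixel coordinates.
#' @param canvas `c(width, height)`.
#' @return List with `x`, `y` standardized about the canvas centre.
#' @export
standardize_coords <- function(x, y, canvas = c(CANVAS_WIDTH, CANVAS_HEIGHT)) {
  hx <- (canvas[1] - 1) / 2; hy <- (canvas[2] - 1) / 2
  list(x = (x - hx) / hx, y = (y - hy) / hy)
}

# Slide number within phase from the absolute slide index (1-32 / 1-16 /
# 1-16).
slide_within_phase <- function(slide_index) {
  ifelse(slide_index <= 32, slide_index,
         ifelse(slide_index <= 48, slide_index - 32L, slide_index - 48L))
}

#' Expected log capture time of one encounter
#'
#' Evaluates the generative mean (see [observer_params()]) for a single
#' encounter given its run-length history and random-intercept draws.
#'
#' @param params an `observer_params`.
#' @param encounter a list or one-row data frame with `prey_type`,
#'   `slide_index`, `x`, `y`.
#' @param run_length consecutive same-type encounters ending here (>= 1).
#' @param post_switch_lag encounters since the most recent type switch
#'   (0 on the first post-switch encounter); ignored when `prev_type` is NA.
#' @param u_p,v_b participant and background random intercepts (log-s).
#' @param prev_type the prey type seen before the most recent switch, or NA
#'   during the first run.
#' @return Expected log capture time in log-seconds.
#' @export
expected_log_time <- function(params, encounter, run_length = 1L,
                              post_switch_lag = 0L, u_p = 0, v_b = 0,
                              prev_type = NA_character_) {
  type <- encounter$prey_type
  s <- slide_within_phase(encounter$slide_index)
  st <- standardize_coords(encounter$x, encounter$y)
  lp <- params$beta0 + params$mu[[type]] +
    params$theta * (s - 1) -
    params$sigma[[type]] * pmin(run_length - 1, params$r_max) +
    params$gamma[1] * st$x^2 + params$gamma[2] * st$y^2 +
    params$gamma[3] * st$x * st$y + u_p + v_b
  if (!is.na(prev_type) && prev_type != type) {
    lag <- pmin(post_switch_lag, 16)
    lp <- lp + params$pi_switch[prev_type, type] * params$decay^lag
  }
  unname(lp)
}

# Run-length bookkeeping for one participant's ordered prey sequence:
# run_length (resets to 1 on a switch), post_switch_lag (0-based within the
# current run) and prev_type (type before the most recent switch, NA for the
# first run).
run_history <- function(prey) {
  n <- length(prey)
  run_length <- integer(n); lag <- integer(n); prev <- rep(NA_character_, n)
  cur_prev <- NA_character_; r <- 0L
  for (i in seq_len(n)) {
    if (i > 1 && prey[i] != prey[i - 1]) {
      cur_prev <- prey[i - 1]; r <- 1L
    } else r <- r + 1L
    run_length[i] <- r
    lag[i] <- r - 1L
    prev[i] <- cur_prev
  }
  list(run_length = run_length, post_switch_lag = lag, prev_type = prev)
}

#' Simulate censored capture times over a design
#'
#' Draws participant and background random intercepts, evaluates the
#' generative mean per encounter with the participant's own run-length
#' history, adds log-normal residual noise, and censors latent times at the
#' timeout. Deterministic for a fixed seed.
#'
#' @param design a `design_table` (validated before simulation).
#' @param params an `observer_params`.
#' @param seed integer seed.
#' @param validate run [validate_design()] first (disable for speed in tight
#'   replicate loops over already-validated designs).
#' @return A `trial_table` data frame: all design columns plus `run_length`,
#'   `capture_time_ms` (integer ms, NA when timed out) and `timed_out`.
#' @export
simulate_trials <- function(design, params = default_params("paperlike"),
                            seed = 1L, validate = TRUE) {
  if (validate) validate_design(design)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  pids <- sort(unique(design$participant_id))
  bids <- sort(unique(design$background_id))
  u <- stats::setNames(stats::rnorm(length(pids), 0, params$tau_p), pids)
  v <- stats::setNames(stats::rnorm(length(bids), 0, params$tau_b), bids)
  design <- design[order(design$participant_id, design$slide_index), ]
  n <- nrow(design)
  run_length <- integer(n)
  lag <- integer(n)
  prev <- rep(NA_character_, n)
  for (pid in pids) {
    idx <- which(design$participant_id == pid)
    hist <- run_history(design$prey_type[idx])
    run_length[idx] <- hist$run_length
    lag[idx] <- hist$post_switch_lag
    prev[idx] <- hist$prev_type
  }
  # vectorized evaluation of the generative mean (scalar reference:
  # expected_log_time)
  st <- standardize_coords(design$x, design$y)
  pi_term <- numeric(n)
  has_prev <- !is.na(prev)
  pi_term[has_prev] <-
    params$pi_switch[cbind(prev[has_prev], design$prey_type[has_prev])] *
    params$decay^pmin(lag[has_prev], 16)
  lp <- params$beta0 + unname(params$mu[design$prey_type]) +
    params$theta * (slide_within_phase(design$slide_index) - 1) -
    unname(params$sigma[design$prey_type]) * pmin(run_length - 1, params$r_max) +
    pi_term +
    params$gamma[1] * st$x^2 + params$gamma[2] * st$y^2 +
    params$gamma[3] * st$x * st$y +
    unname(u[design$participant_id]) + unname(v[design$background_id])
  latent_s <- exp(lp + stats::rnorm(n, 0, params$resid_sd))
  timed_out <- latent_s > params$timeout_s
  ms <- pmax(1L, as.integer(round(latent_s * 1000)))
  ms[timed_out] <- NA_integer_
  out <- design
  out$run_length <- run_length
  out$capture_time_ms <- ms
  out$timed_out <- timed_out
  class(out) <- c("trial_table", "data.frame")
  out
}
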