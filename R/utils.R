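#' Derive a stage seed from a master seed
#'
#' Per-stage seeds are derived deterministically from the master seed and a
#' sequence of string labels, so that pipeline stages can be re-run in
#' isolation with reproducible randomness. The hash is a simple polynomial
#' rolling hash kept below 2^31 so it is always a valid R integer seed.
#'
#' @param master integer master seed.
#' @param ... character labels identifying the stage (e.g. "design", "A").
#' @return A single integer seed in [0, 2^31 - 1].
#' @export
derive_seed <- function(master, ...) {
  labels <- paste(c(as.character(as.integer(master)), ...), collapse = "/")
  codes <- utf8ToInt(labels)
  h <- 0
  m <- 2147483647 # 2^31 - 1
  for (k in codes) h <- (h * 131 + k) %% m
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

#' @keywords internal
assert_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x))
    stop_invalid("`%s` must be a single integer >= %d", name, min)
  invisible(as.integer(x))
}

# Canvas and target-box constants shared across modules (monitor resolution
# and prey bounding box of the touch-screen task).
CANVAS_WIDTH <- 1920L
CANVAS_HEIGHT <- 1080L
TARGET_WIDTH <- 126L
TARGET_HEIGHT <- 64L
TIMEOUT_S <- 30

#' Prey type labels
#'
#' The three camouflage strategies: background matching (\code{"BM"}),
#' disruptive (\code{"D_RUP"}) and distractive (\code{"D_RAC"}).
#' @export
PREY_TYPES <- c("BM", "D_RUP", "D_RAC")

#' Phase-treatment factor levels
#'
#' The 10-level factor encoding experimental phase and arm: the shared
#' learning phase, the three search-image conditions (solid first type A,
#' interspersed AB, solid second type B) and the six search-to-test paths.
#' @export
PHASE_TREATMENT_LEVELS <- c(
  "learning",
  "searchA", "searchAB", "searchB",
  "testA-A", "testA-B", "testAB-A", "testAB-B", "testB-A", "testB-B"
)
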