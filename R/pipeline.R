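#' Pipeline configuration
#'
#' Bundles the design constants of the serial-detection task with the
#' knobs of the synthetic pipeline. Defaults equal the study's printed
#' design: 1920 x 1080 canvas, 126 x 64 prey, 30 s timeout, 20 participants
#' per arm, 32/16/16 phase lengths.
#'
#' @param canvas `c(width, height)` in px.
#' @param target_box `c(width, height)` in px.
#' @param timeout_s censoring bound (s).
#' @param n_per_arm participants per treatment arm.
#' @param phase_lengths `c(learning, search, test)` slide counts.
#' @param pool_size number of backgrounds in the pool.
#' @param scenario observer scenario (`"paperlike"` or `"null"`).
#' @param master_seed integer master seed; all stage seeds derive from it.
#' @param stimulus a [stimulus_config()].
#' @param bark a [bark_config()].
#' @param sweep_per_treatment prey targets generated per treatment in the
#'   pipeline's stimulus spot-check sweep.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(canvas = c(CANVAS_WIDTH, CANVAS_HEIGHT),
                            target_box = c(TARGET_WIDTH, TARGET_HEIGHT),
                            timeout_s = TIMEOUT_S,
                            n_per_arm = 20L,
                            phase_lengths = c(32L, 16L, 16L),
                            pool_size = 8L,
                            scenario = "paperlike",
                            master_seed = 1L,
                            stimulus = stimulus_config(),
                            bark = bark_config(),
                            sweep_per_treatment = 6L) {
  stopifnot(all(canvas > 0), all(target_box > 0), timeout_s > 0,
            n_per_arm >= 1, identical(length(phase_lengths), 3L),
            pool_size >= 1, scenario %in% c("paperlike", "null"))
  structure(as.list(environment()), class = "pipeline_config")
}

TRIAL_COLUMNS <- c("experiment", "participant_id", "arm", "search_condition",
                   "test_type", "slide_index", "phase", "phase_treatment",
                   "prey_type", "inverted", "x", "y", "background_id",
                   "run_length", "capture_time_ms", "timed_out")

#' Write / read trial records
#'
#' Trial tables round-trip losslessly through CSV, including timeout flags
#' and integer millisecond capture times (NA for timed-out encounters).
#' Reading validates the column dictionary and errors naming any missing or
#' unexpected columns.
#'
#' @param trials a `trial_table`.
#' @param path CSV path.
#' @return `write_trials` returns `path` invisibly; `read_trials` returns a
#'   `trial_table`.
#' @export
write_trials <- function(trials, path) {
  missing_cols <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing_cols))
    stop_invalid("trial table is missing column(s): %s",
                 paste(missing_cols, collapse = ", "))
  utils::write.csv(as.data.frame(trials)[, TRIAL_COLUMNS], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(TRIAL_COLUMNS, names(d))
  extra_cols <- setdiff(names(d), TRIAL_COLUMNS)
  if (length(missing_cols) || length(extra_cols))
    stop_invalid("trial table schema mismatch; missing: [%s], unexpected: [%s]",
                 paste(missing_cols, collapse = ", "),
                 paste(extra_cols, collapse = ", "))
  d$inverted <- as.logical(d$inverted)
  d$timed_out <- as.logical(d$timed_out)
  d$capture_time_ms <- as.integer(d$capture_time_ms)
  class(d) <- c("trial_table", "data.frame")
  d
}

#' Write / read a design table
#' @param design a `design_table`.
#' @param path CSV path.
#' @return `write_design` returns `path` invisibly; `read_design` a
#'   `design_table`.
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$inverted <- as.logical(d$inverted)
  class(d) <- c("design_table", "data.frame")
  d
}

#' Serialize an analysis report to JSON
#' @param report an `analysis_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Run the full synthetic experiment end to end
#'
#' Orchestrates every stage: background pool, stimulus spot-check sweep,
#' designs for experiments A, B and C, observer simulation, and the
#' per-experiment statistical analysis. Every stage's seed is derived
#' deterministically from the master seed, so two runs with the same
#' configuration produce identical (hash-equal) outputs. A manifest listing
#' every written file with its MD5 content hash is written alongside the
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param write_backgrounds also write the background PNGs (off by default;
#'   they are large and reproducible from the seed).
#' @return List with `designs`, `trials`, `reports` (per experiment),
#'   `sweep` (stimulus spot-check summary), `manifest` (data frame), and
#'   `pool_ids`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run"),
                         write_backgrounds = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_fail <- function(stage, e)
    stop_invalid("pipeline stage '%s' (master seed %d) failed: %s",
                 stage, config$master_seed, conditionMessage(e))
  files <- character(0)
  put <- function(p) { files <<- c(files, p); p }

  pool <- tryCatch(
    make_background_pool(config$pool_size, derive_seed(config$master_seed,
                                                       "backgrounds"),
                         config$canvas[1], config$canvas[2], config$bark),
    error = function(e) stage_fail("backgrounds", e))
  pool_manifest <- data.frame(id = names(pool), source = "synthetic-bark",
                              seed = vapply(seq_along(pool), function(i)
                                derive_seed(derive_seed(config$master_seed,
                                                        "backgrounds"),
                                            "background", i), 0L))
  utils::write.csv(pool_manifest, put(file.path(out_dir, "backgrounds.csv")),
                   row.names = FALSE)
  if (write_backgrounds)
    for (bg in pool)
      write_background(bg, put(file.path(out_dir,
                                         paste0(bg$id, ".png"))))

  sweep <- tryCatch(
    stimulus_sweep(pool, n_per_treatment = config$sweep_per_treatment,
                   seed = derive_seed(config$master_seed, "sweep"),
                   config = config$stimulus),
    error = function(e) stage_fail("stimuli", e))
  utils::write.csv(sweep, put(file.path(out_dir, "stimulus_sweep.csv")),
                   row.names = FALSE)

  designs <- list(); trials <- list(); reports <- list()
  for (ex in c("A", "B", "C")) {
    designs[[ex]] <- tryCatch(
      build_experiment(ex, config$n_per_arm,
                       derive_seed(config$master_seed, "design", ex),
                       names(pool)),
      error = function(e) stage_fail(paste0("design-", ex), e))
    write_design(designs[[ex]],
                 put(file.path(out_dir, sprintf("design_%s.csv", ex))))
    trials[[ex]] <- tryCatch(
      simulate_trials(designs[[ex]], default_params(config$scenario),
                      derive_seed(config$master_seed, "simulate", ex)),
      error = function(e) stage_fail(paste0("simulate-", ex), e))
    write_trials(trials[[ex]],
                 put(file.path(out_dir, sprintf("trials_%s.csv", ex))))
    reports[[ex]] <- tryCatch(
      analyze_experiment(trials[[ex]], ex),
      error = function(e) stage_fail(paste0("analysis-", ex), e))
    write_report(reports[[ex]],
                 put(file.path(out_dir, sprintf("report_%s.json", ex))))
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         rows = vapply(files, function(f) {
                           if (grepl("\\.csv$", f))
                             length(readLines(f)) - 1L else NA_integer_
                         }, 0L),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  list(designs = designs, trials = trials, reports = reports, sweep = sweep,
       manifest = manifest, pool_ids = names(pool), out_dir = out_dir)
}

#' Generate and re-verify a sweep of prey targets
#'
#' Generates `n_per_treatment` targets of each camouflage treatment over the
#' pool (round-robin) and re-verifies each against its treatment constraint
#' with [verify_target()].
#'
#' @param pool a background pool.
#' @param n_per_treatment targets per treatment.
#' @param seed integer seed.
#' @param config a [stimulus_config()].
#' @param keep_targets also return the target objects (memory-heavy for
#'   large sweeps).
#' @return Data frame with `treatment`, `seed`, `background_id`,
#'   `edge_intersections`, `n_components`, `spot_area`, `spot_fill`,
#'   `verified`; targets in `attr(, "targets")` when requested.
#' @export
stimulus_sweep <- function(pool, n_per_treatment = 500L, seed = 0L,
                           config = stimulus_config(), keep_targets = FALSE) {
  mask <- triangle_mask(ring_width = config$ring_width)
  rows <- list(); targets <- list()
  k <- 0L
  for (tr in PREY_TYPES) {
    for (i in seq_len(n_per_treatment)) {
      k <- k + 1L
      bg <- pool[[(k - 1L) %% length(pool) + 1L]]
      tseed <- derive_seed(seed, "target", tr, i)
      tg <- make_target(bg, tr, inverted = FALSE, seed = tseed, mask = mask,
                        config = config)
      rows[[k]] <- data.frame(
        treatment = tr, seed = tseed, background_id = bg$id,
        edge_intersections = tg$edge_intersection_count,
        n_components = length(tg$components),
        spot_area = if (is.null(tg$spot)) NA_integer_ else tg$spot$area,
        spot_fill = if (is.null(tg$spot)) NA_integer_ else tg$spot$fill,
        verified = verify_target(tg, config),
        stringsAsFactors = FALSE)
      if (keep_targets) targets[[k]] <- tg
    }
  }
  out <- do.call(rbind, rows)
  if (keep_targets) attr(out, "targets") <- targets
  out
}
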