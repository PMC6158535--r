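#' Camouflage pairing of each experiment
#'
#' Experiment A compares background matching with disruptive prey, B compares
#' background matching with distractive, and C disruptive with distractive.
#' Within an experiment the two types are labelled A (first) and B (second).
#'
#' @param experiment `"A"`, `"B"` or `"C"`.
#' @return Named character vector `c(A = <type>, B = <type>)`.
#' @export
experiment_types <- function(experiment = c("A", "B", "C")) {
  switch(match.arg(experiment),
         A = c(A = "BM", B = "D_RUP"),
         B = c(A = "BM", B = "D_RAC"),
         C = c(A = "D_RUP", B = "D_RAC"))
}

# Feasibility of completing a two-type sequence with `a` of type 1 and `b` of
# type 2 left, given the running tail (last type, current run length), under a
# maximum run length. Memoized exhaustive recursion; the state space is tiny.
runs_feasible <- function(a, b, last, run, max_run, memo = new.env(parent = emptyenv())) {
  if (a == 0 && b == 0) return(TRUE)
  key <- paste(a, b, last, run)
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  ok <- FALSE
  if (a > 0 && !(last == 1L && run >= max_run))
    ok <- runs_feasible(a - 1L, b, 1L, if (last == 1L) run + 1L else 1L,
                        max_run, memo)
  if (!ok && b > 0 && !(last == 2L && run >= max_run))
    ok <- runs_feasible(a, b - 1L, 2L, if (last == 2L) run + 1L else 1L,
                        max_run, memo)
  memo[[key]] <- ok
  ok
}

# Constrained pseudorandom interleaving of two prey types: n_each of both,
# no run of identical types longer than max_run. Sequential sampling with a
# feasibility look-ahead, so construction cannot dead-end.
interleave_types <- function(type1, type2, n_each, max_run = 2, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  memo <- new.env(parent = emptyenv())
  a <- as.integer(n_each); b <- as.integer(n_each)
  last <- 0L; run <- 0L
  out <- character(2 * n_each)
  for (i in seq_along(out)) {
    cand <- integer(0)
    if (a > 0 && !(last == 1L && run >= max_run) &&
        runs_feasible(a - 1L, b, 1L, if (last == 1L) run + 1L else 1L,
                      max_run, memo)) cand <- c(cand, 1L)
    if (b > 0 && !(last == 2L && run >= max_run) &&
        runs_feasible(a, b - 1L, 2L, if (last == 2L) run + 1L else 1L,
                      max_run, memo)) cand <- c(cand, 2L)
    pick <- if (length(cand) == 1) cand else cand[sample.int(length(cand), 1)]
    run <- if (pick == last) run + 1L else 1L
    last <- pick
    if (pick == 1L) a <- a - 1L else b <- b - 1L
    out[i] <- if (pick == 1L) type1 else type2
  }
  out
}

#' Pseudorandom training-phase sequence
#'
#' The 32-slide training (learning) phase presents both prey types in a
#' pseudorandom order with no more than two consecutive encounters of the
#' same type, balanced 16/16 so prior experience of both types is equal.
#'
#' @param type_first,type_second the two prey-type labels.
#' @param seed integer seed.
#' @param n_slides total length (default 32).
#' @param max_run maximum run of identical types (default 2).
#' @return Character vector of prey types, length `n_slides`.
#' @export
training_sequence <- function(type_first, type_second, seed = 1L,
                              n_slides = 32L, max_run = 2L) {
  stopifnot(type_first != type_second, n_slides %% 2 == 0)
  interleave_types(type_first, type_second, n_slides / 2, max_run, seed)
}

#' Search-image-phase sequence
#'
#' The 16-slide search-image phase is either a solid run of one camouflage
#' type (allowing a search image to form) or, for the control condition, a
#' continued pseudorandom mix of both types.
#'
#' @param condition `"solid_first"`, `"interspersed"` or `"solid_second"`.
#' @param type_first,type_second the two prey-type labels.
#' @param seed integer seed (used only for the interspersed condition).
#' @param n_slides phase length (default 16).
#' @param max_run maximum run for the interspersed mix.
#' @return Character vector of prey types, length `n_slides`.
#' @export
phase_sequence <- function(condition = c("solid_first", "interspersed",
                                         "solid_second"),
                           type_first, type_second, seed = 1L,
                           n_slides = 16L, max_run = 2L) {
  condition <- match.arg(condition)
  switch(condition,
         solid_first = rep(type_first, n_slides),
         solid_second = rep(type_second, n_slides),
         interspersed = interleave_types(type_first, type_second,
                                         n_slides / 2, max_run, seed))
}

#' Allocate participants to the six treatment arms
#'
#' Each experiment crosses three search-image conditions (solid run of type
#' A, interspersed control, solid run of type B) with two test-phase types,
#' giving six arms; `n_per_arm` participants are allocated to each.
#'
#' @param experiment `"A"`, `"B"` or `"C"`.
#' @param n_per_arm participants per arm (the study used 20, i.e. 120 per
#'   experiment).
#' @param seed integer seed fixing the (shuffled) allocation order.
#' @return Data frame with `participant_id`, `experiment`,
#'   `search_condition`, `test_type` (`"first"`/`"second"`), `arm` label.
#' @export
allocate_arms <- function(experiment = c("A", "B", "C"), n_per_arm = 20L,
                          seed = 1L) {
  experiment <- match.arg(experiment)
  assert_scalar_count(n_per_arm, "n_per_arm")
  arms <- expand.grid(search_condition = c("solid_first", "interspersed",
                                           "solid_second"),
                      test_type = c("first", "second"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  alloc <- arms[rep(seq_len(nrow(arms)), each = n_per_arm), ]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "alloc", experiment))
  alloc <- alloc[sample.int(nrow(alloc)), ]
  alloc$experiment <- experiment
  alloc$arm <- paste0(substr(alloc$search_condition, 1, 5), "_",
                      alloc$test_type)
  alloc$participant_id <- sprintf("%s%03d", experiment, seq_len(nrow(alloc)))
  rownames(alloc) <- NULL
  alloc[, c("participant_id", "experiment", "search_condition", "test_type",
            "arm")]
}

#' Draw a uniform on-canvas target placement
#'
#' Samples target-centre coordinates uniformly over all placements that keep
#' the target box fully on the canvas. Coordinates are 0-based pixels, origin
#' top-left, x rightward, y downward.
#'
#' @param seed integer seed.
#' @param n number of placements to draw.
#' @param canvas `c(width, height)` in px.
#' @param target_box `c(width, height)` of the target bounding box.
#' @return Data frame with integer columns `x`, `y`.
#' @export
place_target <- function(seed = 1L, n = 1L,
                         canvas = c(CANVAS_WIDTH, CANVAS_HEIGHT),
                         target_box = c(TARGET_WIDTH, TARGET_HEIGHT)) {
  w <- as.integer(target_box[1]); h <- as.integer(target_box[2])
  cw <- as.integer(canvas[1]); ch <- as.integer(canvas[2])
  if (w > cw || h > ch) stop_invalid("target box larger than canvas")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  # centre convention: box columns span [x - w/2, x + w/2 - 1]
  xmin <- w %/% 2L; xmax <- cw - 1L - (w - w %/% 2L)
  ymin <- h %/% 2L; ymax <- ch - 1L - (h - h %/% 2L)
  data.frame(x = xmin + sample.int(xmax - xmin + 1L, n, replace = TRUE) - 1L,
             y = ymin + sample.int(ymax - ymin + 1L, n, replace = TRUE) - 1L)
}

# Phase-treatment level for each slide of a participant's arm.
phase_treatment_levels_for <- function(search_condition, test_type) {
  search_lab <- switch(search_condition, solid_first = "searchA",
                       interspersed = "searchAB", solid_second = "searchB")
  test_lab <- paste0("test", sub("^search", "", search_lab), "-",
                     if (test_type == "first") "A" else "B")
  c(rep("learning", 32), rep(search_lab, 16), rep(test_lab, 16))
}

#' Build a full experimental design
#'
#' Assembles the complete per-participant trial list for one pairwise
#' experiment: 32 training slides (pseudorandom 16/16 mix, max run 2), a
#' 16-slide search-image phase per the arm's condition, and a 16-slide solid
#' test run of the arm's test type. Placement is uniform on-canvas; polarity
#' inversion alternates within eligible prey types; backgrounds are assigned
#' round-robin over the pool with a random per-participant offset.
#'
#' @param experiment `"A"`, `"B"` or `"C"`.
#' @param n_per_arm participants per arm (default 20).
#' @param seed integer master seed for the design.
#' @param background_ids character vector of background ids (a pool's names),
#'   or a pool from [make_background_pool()].
#' @param invert_eligible prey types with light-on-dark / dark-on-light
#'   variants.
#' @return A `design_table` data frame, one row per encounter, with columns
#'   `experiment`, `participant_id`, `arm`, `search_condition`, `test_type`,
#'   `slide_index`, `phase`, `phase_treatment`, `prey_type`, `inverted`,
#'   `x`, `y`, `background_id`.
#' @export
build_experiment <- function(experiment = c("A", "B", "C"), n_per_arm = 20L,
                             seed = 1L, background_ids = sprintf("bg%02d", 1:8),
                             invert_eligible = c("BM", "D_RAC")) {
  experiment <- match.arg(experiment)
  if (is.list(background_ids))
    background_ids <- vapply(background_ids, `[[`, "", "id")
  if (!length(background_ids)) stop_invalid("background pool is empty")
  types <- experiment_types(experiment)
  alloc <- allocate_arms(experiment, n_per_arm, seed)
  npool <- length(background_ids)
  rows <- vector("list", nrow(alloc))
  for (i in seq_len(nrow(alloc))) {
    p <- alloc[i, ]
    pseed <- derive_seed(seed, "participant", p$participant_id)
    prey <- c(
      training_sequence(types[["A"]], types[["B"]],
                        derive_seed(pseed, "train")),
      phase_sequence(p$search_condition, types[["A"]], types[["B"]],
                     derive_seed(pseed, "search")),
      rep(types[[if (p$test_type == "first") "A" else "B"]], 16)
    )
    pos <- place_target(derive_seed(pseed, "place"), n = 64)
    old <- .Random.seed_save()
    set.seed(derive_seed(pseed, "misc"))
    inverted <- rep(FALSE, 64)
    for (ty in intersect(unique(prey), invert_eligible)) {
      idx <- which(prey == ty)
      start <- sample.int(2, 1) - 1L
      inverted[idx] <- ((seq_along(idx) + start) %% 2L) == 1L
    }
    offset <- sample.int(npool, 1) - 1L
    .Random.seed_restore(old)
    bg <- background_ids[((seq_len(64) - 1L + offset) %% npool) + 1L]
    rows[[i]] <- data.frame(
      experiment = experiment, participant_id = p$participant_id,
      arm = p$arm, search_condition = p$search_condition,
      test_type = p$test_type, slide_index = 1:64,
      phase = c(rep("learning", 32), rep("search", 16), rep("test", 16)),
      phase_treatment = phase_treatment_levels_for(p$search_condition,
                                                   p$test_type),
      prey_type = prey, inverted = inverted,
      x = pos$x, y = pos$y, background_id = bg,
      stringsAsFactors = FALSE)
  }
  design <- do.call(rbind, rows)
  design <- design[order(design$participant_id, design$slide_index), ]
  rownames(design) <- NULL
  attr(design, "seed") <- as.integer(seed)
  class(design) <- c("design_table", "data.frame")
  design
}

#' Validate a design table's structural invariants
#'
#' Checks phase blocking (slides 1-32 learning, 33-48 search, 49-64 test),
#' training balance and run constraint, solid/interspersed search-phase
#' composition, solid test runs, on-canvas placement, and phase-treatment
#' consistency. Errors on the first violation.
#'
#' @param design a `design_table`.
#' @param max_run maximum run length for pseudorandom mixes.
#' @return `TRUE` invisibly, or an error.
#' @export
validate_design <- function(design, max_run = 2L) {
  need <- c("participant_id", "slide_index", "phase", "phase_treatment",
            "prey_type", "inverted", "x", "y", "background_id")
  missing_cols <- setdiff(need, names(design))
  if (length(missing_cols))
    stop_invalid("design is missing columns: %s",
                 paste(missing_cols, collapse = ", "))
  max_run_of <- function(v) max(rle(v)$lengths)
  for (pid in unique(design$participant_id)) {
    d <- design[design$participant_id == pid, ]
    d <- d[order(d$slide_index), ]
    if (nrow(d) != 64 || !identical(d$slide_index, 1:64))
      stop_invalid("participant %s does not have slides 1-64", pid)
    if (!identical(d$phase, c(rep("learning", 32), rep("search", 16),
                              rep("test", 16))))
      stop_invalid("participant %s has mis-blocked phases", pid)
    train <- d$prey_type[1:32]
    if (length(unique(train)) != 2 || any(table(train) != 16))
      stop_invalid("participant %s training phase is not balanced 16/16", pid)
    if (max_run_of(train) > max_run)
      stop_invalid("participant %s training run exceeds %d", pid, max_run)
    search <- d$prey_type[33:48]
    ptr <- unique(d$phase_treatment[33:48])
    if (length(ptr) != 1) stop_invalid("mixed search treatment for %s", pid)
    if (ptr == "searchAB") {
      if (any(table(search) != 8) || max_run_of(search) > max_run)
        stop_invalid("participant %s interspersed search phase invalid", pid)
    } else if (length(unique(search)) != 1) {
      stop_invalid("participant %s solid search run is not solid", pid)
    }
    if (length(unique(d$prey_type[49:64])) != 1)
      stop_invalid("participant %s test run is not solid", pid)
  }
  w <- TARGET_WIDTH; h <- TARGET_HEIGHT
  if (any(design$x - w %/% 2 < 0 | design$x + (w - w %/% 2) > CANVAS_WIDTH |
          design$y - h %/% 2 < 0 | design$y + (h - h %/% 2) > CANVAS_HEIGHT))
    stop_invalid("some placements fall outside the canvas")
  if (!all(design$phase_treatment %in% PHASE_TREATMENT_LEVELS))
    stop_invalid("unknown phase-treatment levels present")
  invisible(TRUE)
}
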