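# Shared fixtures and independent oracles. Everything is generated in code;
# expensive objects are cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Small backgrounds for stimulus unit tests (patch sampling only needs the
# image to exceed the 126 x 64 mask).
small_pool <- function() {
  cached("small_pool",
         make_background_pool(3, seed = 7, width = 512, height = 384))
}

# Full canvas-sized pool for design/render tests.
canvas_pool <- function() {
  cached("canvas_pool", make_background_pool(2, seed = 3))
}

const_background <- function(value = 128L, width = 512L, height = 384L) {
  structure(list(id = sprintf("const%d", value),
                 pixels = matrix(as.integer(value), height, width),
                 width = as.integer(width), height = as.integer(height)),
            class = "background_image")
}

# Wrap a texture matrix as a prey patch for segmentation tests.
as_patch <- function(values, mask, threshold) {
  values[!mask$inside] <- NA_integer_
  structure(list(values = values, mask = mask, threshold = threshold,
                 origin = c(x = 0, y = 0), background_id = "fixture"),
            class = "prey_patch")
}

# Independent connected-component oracle: queue-based flood fill with
# 8-connectivity over a logical matrix. Returns a list of pixel-index sets.
flood_fill_components <- function(bin) {
  nr <- nrow(bin); nc <- ncol(bin)
  seen <- matrix(FALSE, nr, nc)
  comps <- list()
  for (start in which(bin)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      members <- c(members, p)
      r <- (p - 1) %% nr + 1; cc <- (p - 1) %/% nr + 1
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; ccc <- cc + dc
        if (rr >= 1 && rr <= nr && ccc >= 1 && ccc <= nc) {
          q <- (ccc - 1) * nr + rr
          if (bin[q] && !seen[q]) {
            seen[q] <- TRUE
            queue <- c(queue, q)
          }
        }
      }
    }
    comps[[length(comps) + 1]] <- sort(members)
  }
  comps
}

# Independent triangle rasterizer: point-in-triangle by half-plane tests
# against the three vertices (apex top-centre, base corners bottom).
triangle_oracle_area <- function(width, height) {
  ax <- (width + 1) / 2; ay <- 0
  bx <- 0.5; by <- height
  cx <- width + 0.5; cy <- height
  side <- function(px, py, x1, y1, x2, y2)
    (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
  count <- 0L
  for (i in seq_len(height)) for (j in seq_len(width)) {
    s1 <- side(j, i, ax, ay, bx, by)
    s2 <- side(j, i, bx, by, cx, cy)
    s3 <- side(j, i, cx, cy, ax, ay)
    if ((s1 >= 0 && s2 >= 0 && s3 >= 0) || (s1 <= 0 && s2 <= 0 && s3 <= 0))
      count <- count + 1L
  }
  count
}

# Zero-effect observer parameters (optionally overridden) for noise-free and
# invariance tests.
zero_params <- function(...) {
  args <- list(beta0 = log(5),
               mu = c(BM = 0, D_RUP = 0, D_RAC = 0), theta = 0,
               sigma = c(BM = 0, D_RUP = 0, D_RAC = 0),
               gamma = c(0, 0, 0), tau_p = 0, tau_b = 0, resid_sd = 0)
  do.call(observer_params, utils::modifyList(args, list(...)))
}

# Small simulated modelling table for analysis unit tests.
small_trial_table <- function(experiment = "B", n_per_arm = 2, seed = 42,
                              params = default_params("paperlike")) {
  key <- paste("trials", experiment, n_per_arm, seed)
  cached(key, {
    design <- build_experiment(experiment, n_per_arm,
                               derive_seed(seed, "design"))
    simulate_trials(design, params, derive_seed(seed, "sim"),
                    validate = FALSE)
  })
}
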