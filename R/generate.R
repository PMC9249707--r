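#' Generate one synthetic CLE frame
#'
#' `generate_benign_frame()` draws a honeycomb-epithelium frame (regular
#' jittered hexagonal tessellation, bright intercellular borders, dark
#' interiors, spatially flat regional field). `generate_scc_frame()` draws a
#' carcinoma frame: disorganized tessellation, smudged borders, bright
#' fluorescein-leakage blobs and a random low-frequency regional intensity
#' plane. Both are mapped to 16-bit gray values by the class calibration
#' (see [frame_calibration()]) so that the expected pooled corner-ROI mean
#' and expected mean across-ROI SD equal the class presets in `cfg`.
#'
#' Frames consume R's global random stream; call `set.seed()` (or wrap in
#' `withr::with_seed()`) for reproducibility. [generate_study()] manages
#' per-sequence substreams itself.
#'
#' @param cfg A [generator_config()].
#' @param cal Optional calibration as returned by [frame_calibration()];
#'   supplying one overrides the automatic calibration (used e.g. to probe
#'   the raw texture mechanics at a fixed intensity mapping).
#' @return An integer matrix `cfg$frame_px` square, gray values in
#'   `[0, 65535]`.
#' @export
#' @examples
#' cfg <- generator_config(frame_px = 120L, pixel_size_um = 2)
#' set.seed(1)
#' fr <- generate_benign_frame(cfg)
#' dim(fr)
generate_benign_frame <- function(cfg, cal = NULL) {
  validate_generator_config(cfg)
  if (is.null(cal)) cal <- frame_calibration(cfg, "benign")
  calibrate_frame(synth_texture(texture_params(cfg, "benign")), cal)
}

#' @rdname generate_benign_frame
#' @export
generate_scc_frame <- function(cfg, cal = NULL) {
  validate_generator_config(cfg)
  if (is.null(cal)) cal <- frame_calibration(cfg, "scc")
  calibrate_frame(synth_texture(texture_params(cfg, "scc")), cal)
}

#' Render a sequence through the fluorescein wash-in ramp
#'
#' Takes fully flooded template frames (post wash-in appearance) and renders
#' the frame at each acquisition time `t` as
#' `baseline + noise + r(t) * template`, where `r(t)` is the saturating ramp
#' of [kinetics_ramp()] (0 before `onset_s`, 0.9 at `adequate_s`). Template
#' frames are first scaled so their pooled corner-ROI mean equals
#' `k$plateau`; the rendered trace therefore rises from `baseline` to about
#' `baseline + plateau`. Templates are recycled if the time range needs more
#' frames than supplied.
#'
#' @param template A list of gray-value frames, or a `cle_frame_sequence`.
#' @param k A [kinetics_params()] object.
#' @param t0_s Acquisition time of the first output frame, seconds (time 0 is
#'   the fluorescein injection).
#' @param n_frames Number of output frames.
#' @param fps Frame rate of the output sequence, Hz.
#' @param noise_sd SD of the additive baseline noise, gray values.
#' @return A [frame_sequence()] spanning `t0_s` to `t0_s + n_frames/fps`.
#' @export
apply_kinetics <- function(template, k, t0_s = 0, n_frames = NULL, fps = NULL,
                           noise_sd = 4) {
  stopifnot(inherits(k, "cle_kinetics_params"))
  if (t0_s < 0) stop("t0_s must be >= 0", call. = FALSE)
  if (inherits(template, "cle_frame_sequence")) {
    if (is.null(fps)) fps <- template$fps
    frames <- template$frames
  } else {
    frames <- template
  }
  if (is.null(fps)) fps <- 12
  if (is.null(n_frames)) n_frames <- length(frames)
  n <- nrow(frames[[1]])

  # scale templates so the pooled corner-ROI mean is the plateau amplitude
  side <- roi_side_px(45, 1)
  side <- min(side, n %/% 2L)
  lo <- 1:side
  hi <- (n - side + 1L):n
  pooled <- mean(vapply(frames, function(f) {
    mean(c(mean(f[lo, lo]), mean(f[lo, hi]), mean(f[hi, lo]), mean(f[hi, hi])))
  }, numeric(1)))
  scale <- if (pooled > 0) k$plateau / pooled else 0

  t_s <- t0_s + (seq_len(n_frames) - 1L) / fps
  r <- kinetics_ramp(t_s, k)
  out <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    tpl <- frames[[((i - 1L) %% length(frames)) + 1L]]
    g <- round(k$baseline + rnorm(length(tpl), 0, noise_sd) +
                 r[i] * scale * as.numeric(tpl))
    g[g < 0] <- 0
    g[g > .GRAY_MAX] <- .GRAY_MAX
    storage.mode(g) <- "integer"
    dim(g) <- dim(tpl)
    out[[i]] <- g
  }
  frame_sequence(out, pixel_size_um = 1, fps = fps, label = "unknown",
                 sequence_id = "kinetic_render")
}

#' Composite an acquisition artifact into a frame
#'
#' Implements the CLE artifact taxonomy used for robustness checks: probe
#' contamination with `blood` (large dark occluding blotch) or `dirt`
#' (several small dark blobs), a `saliva` film (hazy low-contrast veil), an
#' air `bubble` (dark disc with a bright rim), `motion` (whole-frame
#' directional smear with a brightness gain, as probe slippage stretches
#' cells and integrates the moving scene),
#' `contact_loss` (the whole frame collapses to baseline noise), and
#' `tangent` probe position (a strong monotone intensity gradient across the
#' frame, so the four corner ROIs differ systematically).
#'
#' All artifacts except `tangent` (with explicit `gradient`) and
#' `contact_loss` consume the global random stream.
#'
#' @param frame Gray-value matrix.
#' @param kind One of `"blood"`, `"saliva"`, `"bubble"`, `"motion"`,
#'   `"contact_loss"`, `"dirt"`, `"tangent"`.
#' @param strength Scalar multiplier on the artifact's default severity.
#' @param gradient For `tangent`: gray-value amplitude of the linear ramp at
#'   the frame's half-width (default `0.6 * mean(frame)`).
#' @param angle For `tangent`: ramp direction in radians (default random).
#' @param baseline Gray value of the bare-probe background used by
#'   `contact_loss`.
#' @return The modified frame, clamped to `[0, 65535]`.
#' @export
apply_artifact <- function(frame, kind, strength = 1, gradient = NULL,
                           angle = NULL, baseline = 25) {
  kinds <- c("blood", "saliva", "bubble", "motion", "contact_loss",
             "dirt", "tangent")
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% kinds))
    stop("unknown artifact kind; expected one of: ",
         paste(kinds, collapse = ", "), call. = FALSE)
  n <- nrow(frame)
  m <- ncol(frame)
  v <- as.numeric(frame)
  y <- rep.int(0:(n - 1L), m)
  x <- rep(0:(m - 1L), each = n)

  soft_blob <- function(v, cx, cy, r, depth) {
    mask <- exp(-(((x - cx)^2 + (y - cy)^2) / r^2)^2)
    v * (1 - depth * mask)
  }

  v <- switch(kind,
    blood = soft_blob(v, runif(1, 0.2 * m, 0.8 * m), runif(1, 0.2 * n, 0.8 * n),
                      runif(1, 0.35, 0.55) * n, min(0.95 * strength, 1)),
    dirt = {
      for (k in seq_len(3 + rpois(1, 2))) {
        v <- soft_blob(v, runif(1, 0, m - 1), runif(1, 0, n - 1),
                       runif(1, 8, 20), min(0.85 * strength, 1))
      }
      v
    },
    saliva = {
      w <- min(0.65 * strength, 1)
      (1 - w) * v + w * mean(v)
    },
    bubble = {
      cx <- runif(1, 0.3 * m, 0.7 * m)
      cy <- runif(1, 0.3 * n, 0.7 * n)
      r <- runif(1, 0.2, 0.35) * n
      rad <- sqrt((x - cx)^2 + (y - cy)^2)
      rim_val <- as.numeric(quantile(v, 0.995))
      v[rad < r] <- v[rad < r] * 0.08
      v[rad >= r & rad < r + 4] <- rim_val
      v
    },
    motion = {
      # whole-frame slippage: directional running-average smear plus the
      # brightness pile-up of integrating the moving scene
      shift <- sample(4:8, 1L)
      gain <- 1 + strength * runif(1, 0.35, 0.7)
      fr <- matrix(v, n, m)
      acc <- fr * 0
      for (s in 0:(shift - 1L)) {
        cols <- pmax(seq_len(m) - s, 1L)
        acc <- acc + fr[, cols, drop = FALSE]
      }
      as.numeric((acc / shift) * gain)
    },
    contact_loss = rnorm(n * m, baseline, 0.2 * baseline),
    tangent = {
      if (is.null(gradient)) gradient <- 0.6 * strength * mean(v)
      if (is.null(angle)) angle <- runif(1, 0, 2 * pi)
      ctr_x <- (m - 1) / 2
      ctr_y <- (n - 1) / 2
      v + gradient * (cos(angle) * (x - ctr_x) + sin(angle) * (y - ctr_y)) / ctr_x
    }
  )
  g <- round(v)
  g[g < 0] <- 0
  g[g > .GRAY_MAX] <- .GRAY_MAX
  storage.mode(g) <- "integer"
  dim(g) <- c(n, m)
  g
}

# draw one labeled sequence from its own substream
generate_sequence <- function(cfg, label, index, cal) {
  seq_seed <- derive_seed(cfg$seed, 1000L + index)
  p <- texture_params(cfg, label)
  kinds <- names(cfg$artifact_probs)
  frames <- NULL
  applied <- character(0)
  withr::with_seed(seq_seed, {
    frames <- lapply(seq_len(cfg$frames_per_sequence), function(i) {
      calibrate_frame(synth_texture(p), cal)
    })
    hit <- kinds[runif(length(kinds)) < cfg$artifact_probs]
    for (kind in hit) {
      run_len <- min(sample(3:8, 1L), cfg$frames_per_sequence)
      start <- sample.int(cfg$frames_per_sequence - run_len + 1L, 1L)
      for (i in start:(start + run_len - 1L)) {
        frames[[i]] <- apply_artifact(frames[[i]], kind)
      }
      applied <- c(applied, kind)
    }
  })
  frame_sequence(frames,
                 pixel_size_um = cfg$pixel_size_um,
                 fps = cfg$fps,
                 label = label,
                 sequence_id = sprintf("seq%03d_%s", index, label),
                 artifacts_applied = applied)
}

#' Generate a full synthetic CLE study
#'
#' Draws `cfg$n_benign` benign and `cfg$n_scc` SCC sequences of
#' `cfg$frames_per_sequence` frames each (defaults: 27 + 33 sequences of 60
#' frames = 3600 frames). Each sequence is generated from its own substream
#' derived from `cfg$seed` by sequence counter, so output is deterministic
#' and adding sequences never perturbs earlier ones.
#'
#' For the default study this holds ~830 MB of frames; prefer
#' [run_study()] (which generates, analyzes and discards sequences one at a
#' time) or the `callback` argument for large designs.
#'
#' @param cfg A [generator_config()].
#' @param callback Optional `function(seq)` invoked on each sequence as it is
#'   generated; when supplied, frames are not accumulated and the return
#'   value is the list of callback results.
#' @return A list of [frame_sequence()] objects (benign first), or the
#'   callback results.
#' @export
generate_study <- function(cfg, callback = NULL) {
  validate_generator_config(cfg)
  labels <- c(rep("benign", cfg$n_benign), rep("scc", cfg$n_scc))
  cals <- list(benign = if (cfg$n_benign > 0) frame_calibration(cfg, "benign"),
               scc = if (cfg$n_scc > 0) frame_calibration(cfg, "scc"))
  out <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    s <- generate_sequence(cfg, labels[i], i, cals[[labels[i]]])
    out[[i]] <- if (is.null(callback)) s else callback(s)
  }
  out
}

#' Simulate rater calls for labeled sequences
#'
#' Each rater calls each item independently: an SCC item is called
#' inhomogeneous with probability `sensitivity`, a benign item with
#' probability `1 - specificity`.
#'
#' @param labels Character vector of per-item truth (`"benign"`/`"scc"`).
#' @param profiles List of [rater_profile()]s.
#' @return A [rating_matrix()] (items x raters, 0 = homogeneous,
#'   1 = inhomogeneous) with the truth attached.
#' @export
#' @examples
#' set.seed(1)
#' rm <- simulate_raters(c("benign", "scc"), observer_rater_profiles()[1:2])
#' dim(rm$calls)
simulate_raters <- function(labels, profiles) {
  if (length(labels) < 1L) stop("at least one item is required", call. = FALSE)
  if (length(profiles) < 1L) stop("at least one rater profile is required",
                                  call. = FALSE)
  if (!all(labels %in% c("benign", "scc")))
    stop("labels must be 'benign' or 'scc'", call. = FALSE)
  calls <- vapply(profiles, function(pr) {
    stopifnot(inherits(pr, "cle_rater_profile"))
    p_inhom <- ifelse(labels == "scc", pr$sensitivity, 1 - pr$specificity)
    rbinom(length(labels), 1L, p_inhom)
  }, integer(length(labels)))
  calls <- matrix(calls, nrow = length(labels))
  colnames(calls) <- paste0("rater", seq_along(profiles))
  rating_matrix(calls, labels)
}
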