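# Normalized stochastic CLE textures.
#
# Frames are synthesized on a dimensionless "texture" scale (border peak ~1)
# and only later mapped to gray values by a per-class affine transform
# (frame_calibration). The benign texture is a jittered hexagonal Voronoi
# tessellation: bright intercellular border bands of width border_width_um,
# dim interiors, per-cell brightness variation. The SCC texture disorganizes
# the lattice (large jitter, wider smudged borders, brighter interiors), adds
# bright fluorescein-leakage blobs, and a low-frequency regional intensity
# plane that drives corner-to-corner divergence.

# texture parameter sets; fixed constants of the presets, not user dials
texture_params <- function(cfg, class) {
  d <- cfg$cell_diameter_um / cfg$pixel_size_um
  bw <- cfg$border_width_um / cfg$pixel_size_um
  if (class == "benign") {
    list(frame_px = cfg$frame_px, d = d, bw = bw,
         jitter_frac = 0.08, bright_sdlog = 0.7, interior_frac = 0.12,
         noise_sd = 0.03, leakage_density = 0, regional_amp = 0)
  } else {
    list(frame_px = cfg$frame_px, d = d, bw = 1.4 * bw,
         jitter_frac = 0.38, bright_sdlog = 0.7, interior_frac = 0.25,
         noise_sd = 0.03, leakage_density = cfg$leakage_patch_density,
         regional_amp = cfg$regional_amp)
  }
}

# cached 0-based pixel-centre vectors (x = column, y = row, column-major)
.grid_cache <- new.env(parent = emptyenv())
pixel_grid <- function(n) {
  key <- as.character(n)
  g <- .grid_cache[[key]]
  if (is.null(g)) {
    g <- list(x = rep(0:(n - 1L), each = n), y = rep.int(0:(n - 1L), n))
    .grid_cache[[key]] <- g
  }
  g
}

# one normalized frame; consumes the current RNG stream
synth_texture <- function(p) {
  n <- p$frame_px
  d <- p$d
  h <- d * sqrt(3) / 2

  # jittered hexagonal lattice of cell centres, with margin
  imin <- -3L; imax <- as.integer(ceiling(n / d)) + 3L
  jmin <- -3L; jmax <- as.integer(ceiling(n / h)) + 3L
  nsite <- (imax - imin + 1L) * (jmax - jmin + 1L)
  jit <- p$jitter_frac * d
  sx <- rnorm(nsite, 0, jit)
  sy <- rnorm(nsite, 0, jit)
  sv <- rlnorm(nsite, meanlog = -p$bright_sdlog^2 / 2, sdlog = p$bright_sdlog)

  g <- pixel_grid(n)
  x <- g$x
  y <- g$y
  nn <- nearest_two_sites(n, d, h, imin, imax, jmin, jmax, sx, sy, sv)

  # border band: pixels near the Voronoi edge between the two closest cells
  border <- (sqrt(nn$d2) - sqrt(nn$d1)) <= p$bw
  tex <- nn$v1 * (p$interior_frac + (1 - p$interior_frac) * border)

  # fluorescein leakage blobs (SCC)
  if (p$leakage_density > 0) {
    npatch <- rpois(1, p$leakage_density)
    for (k in seq_len(npatch)) {
      cx <- runif(1, 0, n - 1)
      cy <- runif(1, 0, n - 1)
      r <- runif(1, 6, 16)
      amp <- runif(1, 0.6, 1.5)
      tex <- tex + amp * exp(-((x - cx)^2 + (y - cy)^2) / (2 * (r / 2)^2))
    }
  }

  # low-frequency regional intensity plane (SCC)
  if (p$regional_amp > 0) {
    theta <- runif(1, 0, 2 * pi)
    u <- runif(1, 0.5, 1.5)
    ctr <- (n - 1) / 2
    tex <- tex + p$regional_amp * u *
      ((cos(theta) * (x - ctr) + sin(theta) * (y - ctr)) / ctr)
  }

  tex <- tex + rnorm(n * n, 0, p$noise_sd)
  tex[tex < 0] <- 0
  matrix(tex, n, n)
}

# environment-level cache for per-class calibrations
.cal_cache <- new.env(parent = emptyenv())

#' Affine intensity calibration of the synthetic textures
#'
#' The generator synthesizes frames on a normalized texture scale and maps
#' them to 16-bit gray values as `gain * texture + offset`. This function
#' solves the two constants per class so that the *expected* pooled
#' corner-ROI mean and the *expected* mean across-ROI sample SD equal the
#' class presets (`benign_mean`/`benign_spread` or `scc_mean`/`scc_spread`):
#' the normalized texture's first two corner-ROI moments (`m0`, `d0`) are
#' estimated from `cfg$calibration_frames` Monte-Carlo frames drawn from a
#' dedicated substream of `cfg$seed`, and then
#' `gain = spread_target / d0`, `offset = mean_target - gain * m0`.
#'
#' The Monte-Carlo standard errors of the two achieved expectations are
#' returned (`mean_se`, `spread_se`); they quantify how far the realized
#' expectation can sit from the preset and are part of any honest tolerance
#' for recovery checks. Calibrations are cached per configuration within a
#' session. A spread target of 0 switches the texture off (`gain = 0`): the
#' frame is the constant `mean` target.
#'
#' @param cfg A [generator_config()].
#' @param class `"benign"` or `"scc"`.
#' @return A list with `gain`, `offset`, `m0`, `d0`, `mean_se`, `spread_se`,
#'   `n_frames`.
#' @export
frame_calibration <- function(cfg, class = c("benign", "scc")) {
  class <- match.arg(class)
  validate_generator_config(cfg)
  target_mean <- if (class == "benign") cfg$benign_mean else cfg$scc_mean
  target_spread <- if (class == "benign") cfg$benign_spread else cfg$scc_spread

  if (target_spread == 0) {
    return(list(gain = 0, offset = target_mean, m0 = NA_real_, d0 = NA_real_,
                mean_se = 0, spread_se = 0, n_frames = 0L))
  }

  p <- texture_params(cfg, class)
  key <- paste(class, cfg$seed, cfg$calibration_frames, target_mean,
               target_spread,
               paste(unlist(p), collapse = "_"), sep = "|")
  if (!is.null(.cal_cache[[key]])) return(.cal_cache[[key]])

  n <- cfg$frame_px
  side <- roi_side_px(45, cfg$pixel_size_um)
  lo <- 1:side
  hi <- (n - side + 1L):n
  cal_seed <- derive_seed(cfg$seed, if (class == "benign") 101L else 202L)
  nf <- cfg$calibration_frames
  m_f <- numeric(nf)
  s_f <- numeric(nf)
  withr::with_seed(cal_seed, {
    for (f in seq_len(nf)) {
      tex <- synth_texture(p)
      mu <- c(mean(tex[lo, lo]), mean(tex[lo, hi]),
              mean(tex[hi, lo]), mean(tex[hi, hi]))
      m_f[f] <- mean(mu)
      s_f[f] <- sd(mu)
    }
  })
  m0 <- mean(m_f)
  d0 <- mean(s_f)
  gain <- target_spread / d0
  offset <- target_mean - gain * m0
  if (offset < 0)
    stop("spread target ", target_spread, " is not attainable at mean ",
         target_mean, " with the ", class, " texture contrast", call. = FALSE)
  cal <- list(gain = gain, offset = offset, m0 = m0, d0 = d0,
              mean_se = gain * sd(m_f) / sqrt(nf),
              spread_se = gain * sd(s_f) / sqrt(nf),
              n_frames = nf)
  .cal_cache[[key]] <- cal
  cal
}

# normalized texture -> integer gray-value frame
calibrate_frame <- function(tex, cal) {
  g <- round(cal$gain * tex + cal$offset)
  g[g < 0] <- 0
  g[g > .GRAY_MAX] <- .GRAY_MAX
  storage.mode(g) <- "integer"
  g
}
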