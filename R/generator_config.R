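#' Synthetic CLE study configuration
#'
#' Bundles every knob of the synthetic CLE generator. The defaults encode the
#' study design this package emulates: a GastroFlex/Cellvizio probe with a
#' 240 um field of view at 1 um resolution, sequences of 60 frames over 5 s
#' (12 Hz), 27 benign and 33 SCC sequences, and class presets calibrated so
#' that the pooled corner-ROI mean gray value and the mean across-ROI standard
#' deviation match the published class statistics (benign 232.1 / 39.1, SCC
#' 467.3 / 101.5, on the 16-bit Cellvizio gray-value scale).
#'
#' Texture parameters (cell diameter, border width, jitter, brightness
#' dispersion) are not reported by any CLE study; the defaults are plausible
#' values for squamous epithelium at this magnification (cells ~20 um,
#' intercellular borders ~3 um) and are fixed parts of the preset, not tuning
#' dials: the affine intensity calibration (see [frame_calibration()]) hits
#' the intensity targets for any reasonable texture geometry.
#'
#' @param frame_px Side of the square frame in pixels.
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @param frames_per_sequence Frames per sequence.
#' @param fps Frame rate in Hz (60 frames over 5 s gives 12 Hz).
#' @param n_benign,n_scc Number of benign / SCC sequences in a study.
#' @param benign_mean,scc_mean Target pooled corner-ROI mean gray value per
#'   class.
#' @param benign_spread,scc_spread Target mean across-ROI sample SD per class.
#' @param cell_diameter_um Epithelial cell diameter in micrometres.
#' @param border_width_um Width of the bright intercellular border band.
#' @param leakage_patch_density Expected number of bright fluorescein-leakage
#'   blobs per SCC frame (Poisson mean).
#' @param regional_amp Amplitude of the low-frequency regional intensity field
#'   of SCC frames (normalized texture units; benign frames have none).
#' @param artifact_probs Named probabilities, per sequence, that an artifact of
#'   each kind is composited into a run of frames. All zero by default: the
#'   emulated study used manually selected, representative, artifact-free
#'   sequences, and the intensity presets describe those selected sequences.
#' @param kinetics A [kinetics_params()] object used when sequences are
#'   rendered with the fluorescein wash-in ramp.
#' @param calibration_frames Monte-Carlo sample size used to calibrate the
#'   per-class affine intensity transform.
#' @param seed Integer seed; the study generator derives one substream per
#'   sequence from it so that adding sequences never perturbs earlier ones.
#'
#' @return An object of class `cle_generator_config` (a validated list).
#' @seealso [generate_study()], [frame_calibration()]
#' @export
#' @examples
#' cfg <- generator_config(n_benign = 2, n_scc = 2, frames_per_sequence = 4)
#' cfg$frame_px
generator_config <- function(frame_px = 240L,
                             pixel_size_um = 1.0,
                             frames_per_sequence = 60L,
                             fps = 12.0,
                             n_benign = 27L,
                             n_scc = 33L,
                             benign_mean = 232.1,
                             scc_mean = 467.3,
                             benign_spread = 39.1,
                             scc_spread = 101.5,
                             cell_diameter_um = 20,
                             border_width_um = 3,
                             leakage_patch_density = 6,
                             regional_amp = 0.5,
                             artifact_probs = NULL,
                             kinetics = kinetics_params(),
                             calibration_frames = 1500L,
                             seed = 1L) {
  kinds <- c("blood", "saliva", "bubble", "motion", "contact_loss",
             "dirt", "tangent")
  if (is.null(artifact_probs)) {
    artifact_probs <- stats::setNames(rep(0, length(kinds)), kinds)
  }
  cfg <- structure(list(
    frame_px = as.integer(frame_px),
    pixel_size_um = pixel_size_um,
    frames_per_sequence = as.integer(frames_per_sequence),
    fps = fps,
    n_benign = as.integer(n_benign),
    n_scc = as.integer(n_scc),
    benign_mean = benign_mean,
    scc_mean = scc_mean,
    benign_spread = benign_spread,
    scc_spread = scc_spread,
    cell_diameter_um = cell_diameter_um,
    border_width_um = border_width_um,
    leakage_patch_density = leakage_patch_density,
    regional_amp = regional_amp,
    artifact_probs = artifact_probs,
    kinetics = kinetics,
    calibration_frames = as.integer(calibration_frames),
    seed = as.integer(seed)
  ), class = "cle_generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "cle_generator_config"))
  with(cfg, {
    if (frame_px < 1L || pixel_size_um <= 0)
      stop("invalid frame geometry: frame_px >= 1 and pixel_size_um > 0 required",
           call. = FALSE)
    roi_px <- roi_side_px(45, pixel_size_um)
    if (frame_px < 2L * roi_px)
      stop("frame_px must be at least twice the ROI side (", roi_px,
           " px) so all four corner ROIs fit", call. = FALSE)
    if (frames_per_sequence < 1L || n_benign < 0L || n_scc < 0L)
      stop("frames_per_sequence >= 1 and sequence counts >= 0 required",
           call. = FALSE)
    if (n_benign + n_scc < 1L)
      stop("at least one sequence is required", call. = FALSE)
    targets <- c(benign_mean, scc_mean, benign_spread, scc_spread)
    if (any(!is.finite(targets)) || any(targets < 0) ||
        any(c(benign_mean, scc_mean) > .GRAY_MAX))
      stop("intensity targets must lie in [0, 65535]", call. = FALSE)
    if (any(artifact_probs < 0 | artifact_probs > 1))
      stop("artifact probabilities must lie in [0, 1]", call. = FALSE)
    if (fps <= 0) stop("fps must be positive", call. = FALSE)
    if (cell_diameter_um <= 0 || border_width_um <= 0)
      stop("texture geometry must be positive", call. = FALSE)
    if (calibration_frames < 2L)
      stop("calibration_frames must be >= 2", call. = FALSE)
  })
  invisible(cfg)
}

#' Fluorescein wash-in kinetics parameters
#'
#' Describes the intensity rise after intravenous fluorescein: the signal sits
#' at a dark baseline until dye arrives in the imaged mucosa (`onset_s`), then
#' rises along a monotone saturating ramp that reaches 90% of the plateau at
#' `adequate_s`, the time from which image quality is adequate for reading.
#' Defaults follow the published kinetic graph: initial enhancement 208 s and
#' adequate quality 224 s after injection.
#'
#' The ramp is \eqn{r(t) = 1 - \exp(-((t - onset)/\tau)^q)} for
#' \eqn{t \ge onset} (0 before), with \eqn{\tau} solved so that
#' \eqn{r(adequate) = 0.9} exactly; `rise_shape` is the exponent \eqn{q}.
#'
#' @param baseline Gray value before dye arrival.
#' @param onset_s Time of initial fluorescein enhancement, seconds.
#' @param adequate_s Time at which the ramp reaches 90% of plateau, seconds.
#' @param plateau Gray-value amplitude of the fully flooded texture (the
#'   pooled corner-ROI mean the rendered sequence converges to, on top of the
#'   baseline).
#' @param rise_shape Ramp exponent \eqn{q > 0}; 1 gives an exponential
#'   saturation.
#'
#' @return An object of class `cle_kinetics_params`.
#' @export
#' @examples
#' k <- kinetics_params()
#' kinetics_ramp(c(208, 224, 300), k)  # 0, 0.9, ~1
kinetics_params <- function(baseline = 25,
                            onset_s = 208,
                            adequate_s = 224,
                            plateau = 232.1,
                            rise_shape = 1) {
  k <- structure(list(baseline = baseline, onset_s = onset_s,
                      adequate_s = adequate_s, plateau = plateau,
                      rise_shape = rise_shape),
                 class = "cle_kinetics_params")
  if (!(onset_s < adequate_s))
    stop("kinetics require onset_s < adequate_s", call. = FALSE)
  if (!(baseline < plateau))
    stop("kinetics require baseline < plateau", call. = FALSE)
  if (rise_shape <= 0) stop("rise_shape must be positive", call. = FALSE)
  k
}

#' Evaluate the wash-in ramp
#'
#' Closed-form saturating ramp used by [apply_kinetics()]: 0 before onset,
#' \eqn{1 - \exp(-((t-onset)/\tau)^q)} after, with \eqn{\tau} fixed by
#' \eqn{r(adequate_s) = 0.9}.
#'
#' @param t_s Times in seconds (vectorized).
#' @param k A [kinetics_params()] object.
#' @return Ramp values in `[0, 1)`.
#' @export
kinetics_ramp <- function(t_s, k) {
  stopifnot(inherits(k, "cle_kinetics_params"))
  tau <- (k$adequate_s - k$onset_s) / (-log(0.1))^(1 / k$rise_shape)
  u <- pmax(t_s - k$onset_s, 0)
  ifelse(t_s < k$onset_s, 0, 1 - exp(-(u / tau)^k$rise_shape))
}

#' Simulated rater operating profile
#'
#' A rater is modeled as a pair of Bernoulli probabilities: `sensitivity` is
#' the probability an SCC sequence is called inhomogeneous, `specificity` the
#' probability a benign sequence is called homogeneous.
#'
#' @param sensitivity,specificity Probabilities in `[0, 1]`.
#' @return An object of class `cle_rater_profile`.
#' @seealso [simulate_raters()], [cle_observer_counts()]
#' @export
rater_profile <- function(sensitivity, specificity) {
  if (any(c(sensitivity, specificity) < 0) || any(c(sensitivity, specificity) > 1))
    stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  structure(list(sensitivity = sensitivity, specificity = specificity),
            class = "cle_rater_profile")
}

#' Per-rater counts of the laryngeal CLE observer study
#'
#' Inhomogeneity call counts of the seven blinded raters who read the 60 CLE
#' sequences (27 benign, 33 SCC) of the observer study this package emulates:
#' for each rater, how many of the 27 benign and how many of the 33 SCC
#' sequences were called inhomogeneous. These printed counts are the input
#' from which all observer-study statistics (Table-style metrics, pooled
#' sensitivity 189/231 and specificity 163/189, Wilson intervals) are
#' recomputed, and they define the default [rater_profile()]s used by the
#' Fleiss-kappa plausibility simulation.
#'
#' @return A data.frame with columns `rater`, `n_benign`, `benign_inhom`,
#'   `n_scc`, `scc_inhom`.
#' @export
#' @examples
#' counts <- cle_observer_counts()
#' sum(counts$scc_inhom)     # 189 of 231 SCC readings called inhomogeneous
#' sum(counts$benign_inhom)  # 26 of 189 benign readings
cle_observer_counts <- function() {
  data.frame(
    rater = paste0("rater", 1:7),
    n_benign = 27L,
    benign_inhom = c(1L, 13L, 6L, 1L, 4L, 1L, 0L),
    n_scc = 33L,
    scc_inhom = c(15L, 32L, 26L, 30L, 28L, 28L, 30L)
  )
}

#' @rdname cle_observer_counts
#' @return `observer_rater_profiles()`: a list of seven [rater_profile()]s
#'   with sensitivities `scc_inhom/n_scc` and specificities
#'   `1 - benign_inhom/n_benign`.
#' @export
observer_rater_profiles <- function() {
  counts <- cle_observer_counts()
  lapply(seq_len(nrow(counts)), function(i) {
    rater_profile(sensitivity = counts$scc_inhom[i] / counts$n_scc[i],
                  specificity = 1 - counts$benign_inhom[i] / counts$n_benign[i])
  })
}

# nearest-integer ROI side in px, half rounded away from zero, minimum 1
roi_side_px <- function(roi_side_um, pixel_size_um) {
  max(1L, as.integer(floor(roi_side_um / pixel_size_um + 0.5)))
}

# deterministic per-purpose substream seeds below 2^31
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 16807) %% 2147483647)
}
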