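#' Run the full synthetic CLE study end-to-end
#'
#' Orchestrates generate -> analyze -> classify -> observer statistics as one
#' reproducible run. Sequences are generated one at a time from per-sequence
#' substreams of `cfg$seed`, analyzed (corner-ROI statistics, homogeneity
#' call) and then discarded, so memory stays at one sequence regardless of
#' study size. Optionally writes every sequence as TIFF + sidecar with a CSV
#' manifest, simulates rater calls and computes the observer-study table.
#'
#' @param cfg A [generator_config()].
#' @param roi_side_um ROI side, micrometres.
#' @param threshold Spread cutoff for [classify()] (gray values), or
#'   `"youden"` to fit the Youden-optimal cutoff on the study itself.
#' @param profiles Optional list of [rater_profile()]s; when given, rater
#'   calls are simulated and the per-rater table and Fleiss kappa computed.
#' @param out_dir Optional directory: when given, per-sequence results,
#'   group summary and (if raters are simulated) ratings and rater table are
#'   written there as CSV/JSON.
#' @param write_tiffs Also write every sequence as multi-page TIFF + JSON
#'   sidecar under `out_dir` with a `manifest.csv` (only with `out_dir`).
#' @return An object of class `cle_study_report`: list with
#'   \describe{
#'     \item{results}{per-sequence data.frame: `sequence_id`, `label`,
#'       `n_frames`, `mean_intensity`, `mean_spread`, `call`, `n_qc_flags`.}
#'     \item{group}{per-class pooled statistics (pooled ROI mean, pooled mean
#'       spread, their SEs over sequences, frame counts).}
#'     \item{separation}{Welch t-test on per-sequence mean spreads,
#'       benign vs SCC.}
#'     \item{threshold, confusion, accuracy}{the cutoff used, the 2x2 of
#'       calls vs truth, and [diagnostic_metrics()] of the automated call.}
#'     \item{ratings, rater_table, kappa}{observer simulation output (NULL
#'       without `profiles`).}
#'     \item{seed}{the seed used.}
#'   }
#' @export
#' @examples
#' \donttest{
#' cfg <- generator_config(n_benign = 2, n_scc = 2, frames_per_sequence = 3,
#'                         calibration_frames = 50, seed = 7)
#' rep <- run_study(cfg)
#' rep$results$call
#' }
run_study <- function(cfg, roi_side_um = 45, threshold = 70.3,
                      profiles = NULL, out_dir = NULL, write_tiffs = FALSE) {
  validate_generator_config(cfg)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  if (write_tiffs && is.null(out_dir))
    stop("write_tiffs requires out_dir", call. = FALSE)

  rois <- corner_rois(cfg$frame_px, cfg$pixel_size_um, roi_side_um)
  manifest <- list()
  per_seq <- generate_study(cfg, callback = function(s) {
    if (write_tiffs) {
      tiff_path <- file.path(out_dir, paste0(s$sequence_id, ".tiff"))
      write_sequence(s, tiff_path)
      manifest[[length(manifest) + 1L]] <<- data.frame(
        sequence_id = s$sequence_id, path = basename(tiff_path),
        label = s$label)
    }
    st <- sequence_stats(s, rois)
    data.frame(sequence_id = st$sequence_id, label = st$label,
               n_frames = st$n_frames,
               mean_intensity = st$mean_intensity,
               mean_spread = st$mean_spread,
               n_qc_flags = length(st$qc_flags))
  })
  results <- do.call(rbind, per_seq)

  if (identical(threshold, "youden")) {
    threshold <- fit_threshold(results$mean_spread, results$label)$threshold
  }
  results$call <- classify(results$mean_spread, threshold)
  results <- results[, c("sequence_id", "label", "n_frames",
                         "mean_intensity", "mean_spread", "call",
                         "n_qc_flags")]

  group <- do.call(rbind, lapply(split(results, results$label), function(g) {
    data.frame(label = g$label[1],
               n_sequences = nrow(g),
               n_frames = sum(g$n_frames),
               pooled_mean_intensity = mean(g$mean_intensity),
               pooled_mean_spread = mean(g$mean_spread),
               se_mean_intensity = sd(g$mean_intensity) / sqrt(nrow(g)),
               se_mean_spread = sd(g$mean_spread) / sqrt(nrow(g)))
  }))
  rownames(group) <- NULL

  separation <- NULL
  confusion <- NULL
  accuracy <- NULL
  both <- all(c("benign", "scc") %in% results$label)
  if (both && sum(results$label == "benign") >= 2 &&
      sum(results$label == "scc") >= 2) {
    separation <- welch_t_test(
      results$mean_spread[results$label == "scc"],
      results$mean_spread[results$label == "benign"])
  }
  if (both) {
    tp <- sum(results$label == "scc" & results$call == "inhomogeneous")
    fn <- sum(results$label == "scc" & results$call == "homogeneous")
    fp <- sum(results$label == "benign" & results$call == "inhomogeneous")
    tn <- sum(results$label == "benign" & results$call == "homogeneous")
    confusion <- matrix(c(tp, fp, fn, tn), 2L,
                        dimnames = list(truth = c("scc", "benign"),
                                        call = c("inhomogeneous",
                                                 "homogeneous")))
    accuracy <- diagnostic_metrics(tp, fn, fp, tn)
  }

  ratings <- NULL
  rtable <- NULL
  kappa <- NULL
  if (!is.null(profiles)) {
    ratings <- withr::with_seed(derive_seed(cfg$seed, 777L),
                                simulate_raters(results$label, profiles))
    rtable <- rater_table(ratings)
    kappa <- fleiss_kappa(ratings)
  }

  report <- structure(list(results = results, group = group,
                           separation = separation, threshold = threshold,
                           confusion = confusion, accuracy = accuracy,
                           ratings = ratings, rater_table = rtable,
                           kappa = kappa, seed = cfg$seed, cfg = cfg),
                      class = "cle_study_report")

  if (!is.null(out_dir)) {
    write.csv(results, file.path(out_dir, "sequence_results.csv"),
              row.names = FALSE)
    write.csv(group, file.path(out_dir, "group_summary.csv"),
              row.names = FALSE)
    if (write_tiffs)
      write_manifest(do.call(rbind, manifest),
                     file.path(out_dir, "manifest.csv"))
    if (!is.null(rtable))
      write.csv(rtable, file.path(out_dir, "rater_table.csv"),
                row.names = FALSE)
    stats_json <- list(
      seed = cfg$seed,
      threshold = threshold,
      separation = separation,
      kappa = if (!is.null(kappa)) list(kappa = kappa$kappa,
                                        band = kappa$band),
      accuracy = if (!is.null(accuracy)) as.list(accuracy$display))
    jsonlite::write_json(stats_json, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  report
}

#' @export
print.cle_study_report <- function(x, ...) {
  cat(sprintf("<cle_study_report> %d sequences (%d frames), seed %d\n",
              nrow(x$results), sum(x$results$n_frames), x$seed))
  for (i in seq_len(nrow(x$group))) {
    g <- x$group[i, ]
    cat(sprintf(
      "  %-6s: %2d sequences / %4d frames | pooled ROI mean %.1f | mean spread %.2f\n",
      g$label, g$n_sequences, g$n_frames, g$pooled_mean_intensity,
      g$pooled_mean_spread))
  }
  if (!is.null(x$separation))
    cat(sprintf("  spread separation (Welch): t = %.2f, p = %.3g\n",
                x$separation$t, x$separation$p))
  if (!is.null(x$accuracy)) {
    cat(sprintf("  automated call at threshold %.1f: ", x$threshold))
    print(x$accuracy)
  }
  if (!is.null(x$kappa))
    cat(sprintf("  simulated raters: Fleiss kappa %.3f (%s)\n",
                x$kappa$kappa, x$kappa$band))
  invisible(x)
}
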