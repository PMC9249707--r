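# Sequence and manifest I/O: multi-page 16-bit grayscale TIFF, JSON sidecar,
# CSV manifests. Pixel coordinates are 0-based row-major and rectangles are
# half-open; metadata travels in the sidecar (not TIFF tags) so it stays
# transparent and diff-able.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a frame sequence as multi-page TIFF plus JSON sidecar
#'
#' Frames are written losslessly as uncompressed 16-bit grayscale pages;
#' metadata (`sequence_id`, `label`, `pixel_size_um`, `fps`,
#' `artifacts_applied`) goes to a sidecar `<path-without-ext>.json`.
#'
#' @param seq A [frame_sequence()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path) {
  validate_frame_sequence(seq)
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop("cannot write sequence: directory does not exist: ", dir,
         call. = FALSE)
  pages <- lapply(seq$frames, function(f) f / .GRAY_MAX)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  meta <- list(sequence_id = seq$sequence_id,
               label = seq$label,
               pixel_size_um = seq$pixel_size_um,
               fps = seq$fps,
               artifacts_applied = as.character(seq$artifacts_applied))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a frame sequence from multi-page TIFF plus JSON sidecar
#'
#' Pages must be single-channel grayscale and share one shape. Metadata is
#' taken from the sidecar; if the sidecar is missing, documented defaults are
#' used (`pixel_size_um = 1`, `fps = 12`, `label = "unknown"`) with a
#' warning.
#'
#' @param path TIFF path.
#' @param sidecar Sidecar JSON path; defaults to `<path-without-ext>.json`.
#' @return A [frame_sequence()].
#' @export
read_sequence <- function(path, sidecar = sidecar_path(path)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- vector("list", length(pages))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] != 1L)
        stop("page ", i, " is not single-channel grayscale (",
             dim(p)[3], " channels)", call. = FALSE)
      p <- p[, , 1]
    }
    storage.mode(p) <- "integer"
    frames[[i]] <- p
  }
  shapes <- vapply(frames, function(f) paste(dim(f), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1L) {
    bad <- which(shapes != shapes[1])[1]
    stop("mixed frame shapes in ", path, ": page ", bad, " is ", shapes[bad],
         " but page 1 is ", shapes[1], call. = FALSE)
  }
  meta <- list(pixel_size_um = 1.0, fps = 12.0, label = "unknown",
               sequence_id = tools::file_path_sans_ext(basename(path)),
               artifacts_applied = character(0))
  if (file.exists(sidecar)) {
    got <- tryCatch(jsonlite::fromJSON(sidecar),
                    error = function(e) stop("unreadable sidecar ", sidecar,
                                             ": ", conditionMessage(e),
                                             call. = FALSE))
    for (field in intersect(names(meta), names(got))) meta[[field]] <- got[[field]]
  } else {
    warning("no sidecar for ", path, "; using default metadata", call. = FALSE)
  }
  frame_sequence(frames,
                 pixel_size_um = meta$pixel_size_um,
                 fps = meta$fps,
                 label = meta$label,
                 sequence_id = meta$sequence_id,
                 source_path = path,
                 artifacts_applied = as.character(meta$artifacts_applied))
}

#' Study manifest I/O
#'
#' A study manifest is a CSV with columns `sequence_id`, `path`, `label`
#' listing the sequences of a study. `load_manifest()` validates it
#' (unique ids, known labels, existing files; relative paths are resolved
#' against the manifest's directory); `write_manifest()` writes one.
#'
#' @param path Manifest CSV path.
#' @param check_paths Verify that every referenced TIFF exists (default
#'   TRUE).
#' @return A data.frame of class `cle_study_manifest`.
#' @export
load_manifest <- function(path, check_paths = TRUE) {
  m <- read.csv(path, colClasses = "character")
  need <- c("sequence_id", "path", "label")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(m) == 0L) {
    warning("manifest ", path, " lists no sequences", call. = FALSE)
  }
  dup <- unique(m$sequence_id[duplicated(m$sequence_id)])
  if (length(dup))
    stop("duplicate sequence_id in manifest: ", paste(dup, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(m$label), c("benign", "scc", "unknown"))
  if (length(bad))
    stop("unknown label in manifest: ", paste(bad, collapse = ", "),
         call. = FALSE)
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  if (check_paths && nrow(m)) {
    missing <- m$path[!file.exists(m$path)]
    if (length(missing))
      stop("manifest refers to missing files: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  class(m) <- c("cle_study_manifest", "data.frame")
  m
}

#' @rdname load_manifest
#' @param manifest Data.frame with columns `sequence_id`, `path`, `label`.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest[, c("sequence_id", "path", "label")], path,
            row.names = FALSE)
  invisible(path)
}
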