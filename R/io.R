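#' @include AllClasses.R
NULL

#' Read and write calibrated movies as multi-frame TIFF
#'
#' Movies are stored as grayscale 16-bit multi-frame TIFF (one channel,
#' ImageJ-compatible), counts scaled into the 16-bit range on disk. The
#' acquisition calibration travels in a JSON sidecar
#' (`<movie>.json`: `frame_rate`, `pixel_size`, optional `efs_onset` /
#' `efs_duration`), written by `writeMovie()` and read back by
#' `readMovie()`; explicit `frameRate`/`pixelSize` arguments override the
#' sidecar.
#'
#' @param movie a [CalciumMovie()].
#' @param path TIFF file path.
#' @param efs optional [EFSProtocol()] recorded in the sidecar.
#' @param frameRate,pixelSize calibration overrides when no sidecar exists.
#' @return `writeMovie()` returns `path` invisibly; `readMovie()` a
#'   [CalciumMovie()].
#' @examples
#' mv <- CalciumMovie(array(100, c(4, 4, 3)), 33, 0.5)
#' p <- file.path(tempdir(), "mv.tif")
#' writeMovie(mv, p)
#' nFrames(readMovie(p))
#' @export
writeMovie <- function(movie, path, efs = NULL) {
  A <- movie@intensity
  frames <- lapply(seq_len(dim(A)[3]), function(f) A[, , f] / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L,
                  compression = "none", reduce = TRUE)
  meta <- list(frame_rate = movie@frameRate, pixel_size = movie@pixelSize)
  if (!is.null(efs)) {
    meta$efs_onset <- efs@onset
    meta$efs_duration <- efs@trainDuration
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeMovie
#' @export
readMovie <- function(path, frameRate = NULL, pixelSize = NULL) {
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(frameRate)) frameRate <- meta$frame_rate
    if (is.null(pixelSize)) pixelSize <- meta$pixel_size
  }
  if (is.null(frameRate) || is.null(pixelSize))
    stop("frameRate/pixelSize must come from the sidecar or be supplied")
  frames <- tiff::readTIFF(path, all = TRUE)
  A <- array(0, c(dim(frames[[1]])[1:2], length(frames)))
  for (f in seq_along(frames)) {
    m <- frames[[f]]
    if (length(dim(m)) == 3L) m <- m[, , 1]
    A[, , f] <- round(m * 65535)
  }
  CalciumMovie(A, frameRate = frameRate, pixelSize = pixelSize)
}

#' Read and write whole-cell ROIs as JSON
#'
#' A [CellROI()] is serialized as JSON with `polygon` and `centerline`
#' arrays of `[x, y]` pairs in 0-based pixel coordinates, plus
#' `pixel_size`.
#'
#' @param roi a [CellROI()].
#' @param path JSON file path.
#' @return `writeROI()` returns `path` invisibly; `readROI()` a
#'   [CellROI()].
#' @export
writeROI <- function(roi, path) {
  jsonlite::write_json(
    list(pixel_size = roi@pixelSize,
         polygon = unname(apply(roi@polygon, 1L, c, simplify = FALSE)),
         centerline = unname(apply(roi@centerline, 1L, c,
                                   simplify = FALSE))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeROI
#' @export
readROI <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  asXY <- function(v) {
    m <- if (is.list(v)) do.call(rbind, v) else as.matrix(v)
    colnames(m) <- c("x", "y")
    m
  }
  CellROI(asXY(j$polygon), asXY(j$centerline), pixelSize = j$pixel_size)
}

#' Write the ground-truth ledger of a simulated recording
#'
#' Events, sites and (when present) per-site escape latencies as CSV files
#' with header rows.
#'
#' @param truth a [GroundTruth-class].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, the written paths.
#' @export
writeGroundTruth <- function(truth, dir, prefix = "cell") {
  paths <- c(
    events = file.path(dir, paste0(prefix, "_truth_events.csv")),
    sites = file.path(dir, paste0(prefix, "_truth_sites.csv")))
  utils::write.csv(truth@events, paths["events"], row.names = FALSE)
  utils::write.csv(truth@sites, paths["sites"], row.names = FALSE)
  if (nrow(truth@escape)) {
    paths["escape"] <- file.path(dir, paste0(prefix, "_truth_escape.csv"))
    utils::write.csv(truth@escape, paths["escape"], row.names = FALSE)
  }
  invisible(paths)
}
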