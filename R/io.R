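# Plain-text interchange formats: landmark CSVs, pen masks, displacement
# fields and dataset manifests.

#' Read / write landmark correspondence tables
#'
#' CSV with columns `pair_id, fixed_x, fixed_y, moving_x, moving_y, label`
#' (coordinates 0-based, x = column, y = row).
#'
#' @param path CSV file path.
#' @param pairId optional filter: keep only rows with this `pair_id`.
#' @return `readLandmarksCSV`: a [PairedLandmarks].
#' @export
readLandmarksCSV <- function(path, pairId = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("fixed_x", "fixed_y", "moving_x", "moving_y", "label")
  if (!all(need %in% names(d)))
    stop(sprintf("landmark CSV must contain columns %s",
                 paste(need, collapse = ", ")))
  if (!is.null(pairId) && "pair_id" %in% names(d))
    d <- d[d$pair_id == pairId, , drop = FALSE]
  if (!nrow(d)) stop("no landmark rows found")
  PairedLandmarks(cbind(d$fixed_x, d$fixed_y),
                  cbind(d$moving_x, d$moving_y), d$label)
}

#' @rdname readLandmarksCSV
#' @param landmarks a [PairedLandmarks].
#' @export
writeLandmarksCSV <- function(landmarks, path, pairId = 1L) {
  stopifnot(is(landmarks, "PairedLandmarks"))
  d <- data.frame(pair_id = pairId,
                  fixed_x = landmarks@fixedPoints[, 1L],
                  fixed_y = landmarks@fixedPoints[, 2L],
                  moving_x = landmarks@movingPoints[, 1L],
                  moving_y = landmarks@movingPoints[, 2L],
                  label = landmarks@labels)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a binary pen mask from a PNG image
#'
#' Pixels with intensity > 0.5 are inside the pen.
#'
#' @param path PNG file path.
#' @return a 0/1 integer matrix.
#' @export
readPenMask <- function(path) {
  m <- readGrayImage(path)
  (m > 0.5) * 1L
}

#' Serialize / restore a displacement field
#'
#' Self-describing JSON container: a header with the grid size and
#' channel order (`dx`, `dy`) plus the flattened displacement values at
#' near-full double precision (relative error below 1e-12 on roundtrip).
#'
#' @param field a [DeformationField].
#' @param path output file path (`.json`).
#' @export
writeField <- function(field, path) {
  stopifnot(is(field, "DeformationField"))
  v <- field@vectors
  jsonlite::write_json(
    list(format = "penreg-field", version = 1L,
         height = dim(v)[1L], width = dim(v)[2L],
         channels = c("dx", "dy"), data = as.numeric(v)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeField
#' @return `readField`: the restored [DeformationField].
#' @export
readField <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "penreg-field"))
    stop("not a penreg displacement-field file")
  DeformationField(array(j$data, c(j$height, j$width, 2L)))
}

#' Load a dataset manifest written by [generateDataset()]
#'
#' Reads the JSON manifest and materializes the records (images and
#' landmark tables) from disk into the in-memory form the training and
#' evaluation functions consume.
#'
#' @param manifestPath path to `manifest.json`.
#' @return a [DatasetSplit] whose records are
#'   `list(fixed, moving, landmarks)` entries.
#' @export
readDatasetManifest <- function(manifestPath) {
  man <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
  base <- dirname(manifestPath)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, basename(p))
  loadRec <- function(i) {
    rec <- list(fixed = readGrayImage(resolve(man$fixedPath[i])),
                moving = readGrayImage(resolve(man$movingPath[i])),
                landmarks = NULL)
    lp <- man$landmarkPath[i]
    if (!is.null(lp) && !is.na(lp))
      rec$landmarks <- readLandmarksCSV(resolve(lp))
    rec
  }
  recs <- lapply(seq_len(nrow(man)), loadRec)
  new("DatasetSplit",
      train = recs[man$split == "train"],
      finetune = recs[man$split == "finetune"],
      test = recs[man$split == "test"],
      manifest = man)
}

#' Write an RGB array as PNG
#'
#' @param rgb H x W x 3 array in `[0, 1]` (e.g. from [makeOverlay()]).
#' @param path output PNG path.
#' @export
writeRGBImage <- function(rgb, path) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3L] != 3L)
    stop("'rgb' must be H x W x 3")
  png::writePNG(pmin(pmax(rgb, 0), 1), path)
  invisible(path)
}

#' Export a TRE report as JSON (plus optional per-pair CSV)
#'
#' @param report a [TREReport].
#' @param path output JSON path.
#' @param csvPath optional CSV path for the per-pair rows.
#' @export
writeTREReport <- function(report, path, csvPath = NULL) {
  stopifnot(is(report, "TREReport"))
  jsonlite::write_json(
    list(convention = report@convention,
         n_pairs = report@nPairs, n_landmarks = report@nLandmarks,
         overall_tre = report@overallTre,
         foreground_tre = report@foregroundTre,
         background_tre = report@backgroundTre,
         per_pair_tre = report@perPairTre,
         multiple_testing_correction = "none"),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(csvPath))
    write.csv(data.frame(pair = seq_along(report@perPairTre),
                         tre = report@perPairTre),
              csvPath, row.names = FALSE)
  invisible(path)
}
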