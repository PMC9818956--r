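# Target registration error, method comparison and overlay visualization.

#' Target registration error between two point sets
#'
#' Mean over landmark pairs of the distance between the fixed landmarks
#' and the mapped moving landmarks. The default convention is the plain
#' Euclidean distance (pixels); `"squared"` aggregates squared distances
#' instead. The choice is recorded in every [TREReport].
#'
#' @param fixedPts n x 2 matrix of fixed-image landmarks.
#' @param mappedPts n x 2 matrix of moving landmarks mapped into the
#'   fixed frame.
#' @param convention `"euclidean"` (default) or `"squared"`.
#' @return a non-negative scalar.
#' @export
computeTRE <- function(fixedPts, mappedPts, convention = "euclidean") {
  f <- checkPoints(fixedPts, "fixedPts")
  m <- checkPoints(mappedPts, "mappedPts")
  if (nrow(f) != nrow(m))
    stop(sprintf("point counts differ (%d vs %d)", nrow(f), nrow(m)))
  convention <- match.arg(convention, c("euclidean", "squared"))
  d2 <- rowSums((f - m)^2)
  if (convention == "euclidean") mean(sqrt(d2)) else mean(d2)
}

#' Evaluate a landmark-mapping method on an annotated test set
#'
#' Applies `method` to every test pair to map its moving landmarks into
#' the fixed frame, then aggregates: the per-pair TRE list (used by the
#' paired statistical tests), and foreground / background / overall means
#' pooled over all landmarks across pairs. An empty label category yields
#' `NA` (absent), never 0.
#'
#' @param method a function `(fixed, moving, movingPoints, pair)` returning
#'   the mapped n x 2 points; see [identityMethod()], [projectiveMethod()],
#'   [fieldMethod()] and [modelMethod()] for ready-made adapters.
#' @param testSet list of [GroundTruthPair] or
#'   `list(fixed, moving, landmarks)` records, each carrying labeled
#'   landmarks.
#' @param convention distance convention, see [computeTRE()].
#' @return a [TREReport].
#' @export
evaluateMethod <- function(method, testSet, convention = "euclidean") {
  stopifnot(is.function(method), length(testSet) >= 1L)
  convention <- match.arg(convention, c("euclidean", "squared"))
  perPair <- numeric(length(testSet))
  allD <- numeric(0); allLab <- character(0)
  for (i in seq_along(testSet)) {
    rec <- asPairRecord(testSet[[i]])
    if (is.null(rec$landmarks))
      stop(sprintf("test pair %d carries no landmarks", i))
    lmk <- rec$landmarks
    mapped <- method(rec$fixed, rec$moving, lmk@movingPoints, testSet[[i]])
    mapped <- checkPoints(mapped, "mapped points")
    d2 <- rowSums((lmk@fixedPoints - mapped)^2)
    d <- if (convention == "euclidean") sqrt(d2) else d2
    perPair[i] <- mean(d)
    allD <- c(allD, d); allLab <- c(allLab, lmk@labels)
  }
  meanOr <- function(sel) if (any(sel)) mean(allD[sel]) else NA_real_
  new("TREReport", perPairTre = perPair,
      foregroundTre = meanOr(allLab == "foreground"),
      backgroundTre = meanOr(allLab == "background"),
      overallTre = mean(allD), convention = convention,
      nPairs = length(testSet), nLandmarks = length(allD))
}

#' Ready-made landmark-mapping adapters for [evaluateMethod()]
#'
#' `identityMethod` leaves landmarks where they are (measures the
#' misalignment already present, e.g. after pre-registration);
#' `projectiveMethod(h)` maps them through a homography;
#' `fieldMethod(field)` inverts a fixed displacement field with
#' [warpPointsDense()]; `modelMethod(model)` predicts the field for each
#' pair with [predictField()] and then inverts it.
#'
#' @return a function suitable as the `method` argument of
#'   [evaluateMethod()].
#' @export
identityMethod <- function() {
  function(fixed, moving, movingPoints, pair) movingPoints
}

#' @rdname identityMethod
#' @param h a [Homography].
#' @export
projectiveMethod <- function(h) {
  force(h)
  function(fixed, moving, movingPoints, pair) mapPointsProjective(movingPoints, h)
}

#' @rdname identityMethod
#' @param field a [DeformationField].
#' @export
fieldMethod <- function(field) {
  force(field)
  function(fixed, moving, movingPoints, pair) warpPointsDense(movingPoints, field)
}

#' @rdname identityMethod
#' @param model a trained [RegistrationModel].
#' @export
modelMethod <- function(model) {
  force(model)
  function(fixed, moving, movingPoints, pair) {
    field <- predictField(model, fixed, moving)
    warpPointsDense(movingPoints, field)
  }
}

#' Paired statistical comparison of two methods' per-pair TRE
#'
#' Normality of each sample is assessed with the Shapiro--Wilk test; when
#' both p-values exceed `alpha` a paired t-test is used, otherwise the
#' Wilcoxon signed-rank test. Identical samples (all differences zero)
#' are a degenerate case reported as p = 1 with a warning. Raw p-values
#' are reported without multiple-testing correction.
#'
#' @param treA,treB per-pair TRE vectors of equal length (>= 3), paired
#'   by image pair.
#' @param alpha normality threshold for test selection (default 0.05).
#' @param labels length-2 character vector naming the methods.
#' @return a [ComparisonResult].
#' @export
compareMethods <- function(treA, treB, alpha = 0.05,
                           labels = c("method_a", "method_b")) {
  stopifnot(is.numeric(treA), is.numeric(treB))
  if (length(treA) != length(treB))
    stop("per-pair TRE vectors must be paired (equal lengths)")
  if (length(treA) < 3L) stop("at least 3 paired values are required")
  swA <- shapiro.test(treA)$p.value
  swB <- shapiro.test(treB)$p.value
  normal <- !is.na(swA) && !is.na(swB) && swA > alpha && swB > alpha
  diffs <- treA - treB
  if (all(diffs == 0)) {
    warning("all paired differences are zero; reporting p = 1")
    return(new("ComparisonResult", methodA = labels[1L], methodB = labels[2L],
               normalityP = c(swA, swB),
               testUsed = "wilcoxon_signed_rank", pValue = 1))
  }
  if (normal && sd(diffs) > 0) {
    p <- t.test(treA, treB, paired = TRUE)$p.value
    test <- "paired_t"
  } else {
    p <- suppressWarnings(wilcox.test(treA, treB, paired = TRUE,
                                      exact = FALSE)$p.value)
    test <- "wilcoxon_signed_rank"
  }
  new("ComparisonResult", methodA = labels[1L], methodB = labels[2L],
      normalityP = c(swA, swB), testUsed = test, pValue = p)
}

#' Magenta/green registration overlay
#'
#' Composite RGB image for visual inspection: the fixed image drives the
#' green channel, the other image drives red and blue (magenta). Where
#' the two intensities agree the composite is gray; green or magenta
#' fringes show where content originates from only one image.
#'
#' @param fixed grayscale matrix.
#' @param other the moving or registered grayscale matrix, same shape.
#' @return an H x W x 3 RGB array in `[0, 1]`.
#' @export
makeOverlay <- function(fixed, other) {
  checkGrayImage(fixed, "fixed"); checkGrayImage(other, "other")
  if (!all(dim(fixed) == dim(other))) stop("image shapes differ")
  array(c(other, fixed, other), c(dim(fixed), 3L))
}

#' Box-plot comparison of per-pair TRE across methods
#'
#' One box per method (x-axis) from each report's per-pair TRE; written
#' as PNG when `file` is given, drawn on the active device otherwise.
#'
#' @param reports named list of [TREReport]s (names label the methods).
#' @param file optional PNG output path.
#' @param main plot title.
#' @export
plotTreBoxplot <- function(reports, file = NULL,
                           main = "Target registration error by method") {
  stopifnot(length(reports) >= 1L, !is.null(names(reports)))
  vals <- lapply(reports, perPairTre)
  if (!is.null(file)) {
    grDevices::png(file, width = 720, height = 480)
    on.exit(grDevices::dev.off())
  }
  graphics::boxplot(vals, ylab = "TRE (px)", main = main, col = "gray85")
  invisible(file)
}

#' Visualize a displacement field as an HSV flow image
#'
#' Direction maps to hue, magnitude to saturation (normalized by the
#' maximum magnitude), full value; the conventional optical-flow
#' coloring.
#'
#' @param field a [DeformationField].
#' @return an H x W x 3 RGB array in `[0, 1]`.
#' @export
flowImage <- function(field) {
  v <- fieldArray(field)
  mag <- sqrt(v[, , 1L]^2 + v[, , 2L]^2)
  ang <- (atan2(v[, , 2L], v[, , 1L]) + pi) / (2 * pi)
  s <- if (max(mag) > 0) mag / max(mag) else mag
  cols <- hsv(h = pmin(ang, 1), s = pmin(s, 1), v = 1)
  rgb <- grDevices::col2rgb(cols) / 255
  array(c(matrix(rgb[1L, ], nrow(mag)), matrix(rgb[2L, ], nrow(mag)),
          matrix(rgb[3L, ], nrow(mag))), c(dim(mag), 3L))
}
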