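#' @include synthetic-arena.R
NULL

#' Flag kinematically implausible frames of a single-animal track
#'
#' Walks the track once, comparing each frame against the last frame accepted
#' as valid: if the implied speed exceeds \code{maxSpeed} the frame is marked
#' invalid and the reference frame is kept. The first valid frame is always
#' accepted. Frames invalid on input stay invalid.
#'
#' @param x,y coordinates in cm
#' @param time_s strictly increasing timestamps in seconds
#' @param valid input validity mask; defaults to non-NA coordinates
#' @param maxSpeed speed gate in cm/s; the default is a generous bound for
#'   rat locomotion
#' @return logical validity mask
#' @export
flagImplausible <- function(x, y, time_s, valid = NULL, maxSpeed = 100) {
  if (length(x) == 0L) stop("empty track")
  if (length(time_s) > 1 && any(diff(time_s) <= 0))
    stop("timestamps must be strictly increasing")
  if (is.null(valid)) valid <- !is.na(x) & !is.na(y)
  out <- valid & !is.na(x) & !is.na(y)
  last <- NA_integer_
  for (i in seq_along(x)) {
    if (!out[i]) next
    if (is.na(last)) {
      last <- i  # first valid frame is always accepted
      next
    }
    sp <- sqrt((x[i] - x[last])^2 + (y[i] - y[last])^2) /
      (time_s[i] - time_s[last])
    if (sp > maxSpeed) out[i] <- FALSE else last <- i
  }
  out
}

#' Resolve identity swaps by per-frame optimal assignment
#'
#' For every frame, the observed positions of the animals valid at that frame
#' are re-assigned to animal labels so that the total displacement from each
#' label's last resolved valid position is minimal (exhaustive assignment
#' over at most four animals). Incumbent labels are kept unless an
#' alternative beats them by more than \code{marginCm} of total displacement:
#' the hysteresis stops measurement noise from swapping the labels of two
#' animals sitting close together (where an exchange is marginally cheaper
#' but wrong, and would then persist). Output positions are a per-frame
#' permutation of input positions; no coordinates are invented.
#'
#' @param ts a \linkS4class{TrajectorySet} with 2--4 animals
#' @param marginCm hysteresis margin in cm; a genuine identity swap displaces
#'   each affected animal by the inter-animal distance, so any margin well
#'   below typical inter-animal distances and above a few step lengths works
#' @return list with \code{tracks} (relabelled TrajectorySet) and
#'   \code{nSwapFrames} (animal-frames whose label changed)
#' @export
resolveSwaps <- function(ts, marginCm = 10) {
  n <- ncol(ts)
  if (n < 2L || n > 4L) stop("resolveSwaps supports 2-4 animals")
  r <- resolve_swaps_cpp(coordsX(ts), coordsY(ts), validMask(ts), marginCm)
  ids <- animalIds(ts)
  dimnames(r$x) <- dimnames(r$y) <- dimnames(r$valid) <- list(NULL, ids)
  out <- TrajectorySet(r$x, r$y, frameTimes(ts), valid = r$valid,
                       animal_ids = ids, arena = arenaDims(ts),
                       frame_rate = frameRate(ts), day = metadata(ts)$day,
                       familiar = setNames(colData(ts)$familiar_partner, ids))
  list(tracks = out, nSwapFrames = r$n_changed)
}

#' Fill short invalid runs by linear interpolation
#'
#' Invalid runs of at most \code{maxGap} frames that are flanked by valid
#' frames on both sides are linearly interpolated and marked imputed; longer
#' runs, and runs touching either end of the track, remain invalid.
#'
#' @param x,y coordinates (NA where invalid)
#' @param valid validity mask
#' @param maxGap largest run length (frames) that may be filled
#' @return list with \code{x}, \code{y}, \code{valid}, and logical
#'   \code{imputed}
#' @export
interpolateGaps <- function(x, y, valid = NULL, maxGap) {
  if (is.null(valid)) valid <- !is.na(x) & !is.na(y)
  if (!any(valid)) stop("track has no valid frames")
  xi <- ifelse(valid, x, NA_real_)
  yi <- ifelse(valid, y, NA_real_)
  xf <- zoo::na.approx(xi, na.rm = FALSE, maxgap = maxGap)
  yf <- zoo::na.approx(yi, na.rm = FALSE, maxgap = maxGap)
  imputed <- !valid & !is.na(xf) & !is.na(yf)
  list(x = ifelse(is.na(xf), x, xf), y = ifelse(is.na(yf), y, yf),
       valid = valid | imputed, imputed = imputed)
}

#' Estimation accuracy of a repaired trajectory against a reference
#'
#' The fraction of animal-frames, among those valid in the reference, whose
#' repaired position is valid and within \code{tol} cm of the reference
#' position.
#'
#' @param repaired,reference \linkS4class{TrajectorySet}s with the same shape
#'   and time base
#' @param tol tolerance in cm (default about a quarter body length)
#' @return numeric fraction in \[0, 1\]
#' @export
estimationAccuracy <- function(repaired, reference, tol = 5) {
  if (!all(dim(repaired) == dim(reference)))
    stop("repaired and reference must have the same shape")
  if (max(abs(frameTimes(repaired) - frameTimes(reference))) > 1e-9)
    stop("repaired and reference must share one time base")
  ref_ok <- validMask(reference)
  if (!any(ref_ok)) stop("reference has no valid animal-frames")
  d2 <- (coordsX(repaired) - coordsX(reference))^2 +
    (coordsY(repaired) - coordsY(reference))^2
  hit <- validMask(repaired) & !is.na(d2) & d2 <= tol^2
  sum(hit[ref_ok]) / sum(ref_ok)
}

#' End-to-end repair of a multi-animal TrajectorySet
#'
#' Runs the three repair stages in order: identity-swap resolution (kinematic
#' continuity), per-animal speed gating, and bounded linear gap
#' interpolation.
#'
#' @param ts a \linkS4class{TrajectorySet}
#' @param maxSpeed speed gate in cm/s
#' @param maxGapS largest gap that may be interpolated, in seconds
#' @param marginCm swap-resolution hysteresis, see [resolveSwaps()]
#' @param reference optional ground-truth TrajectorySet; when given, the
#'   report's accuracy is computed against it
#' @param tol accuracy tolerance in cm
#' @return list with \code{tracks} (repaired TrajectorySet) and \code{report}
#'   (a \linkS4class{RepairReport})
#' @export
repairTracks <- function(ts, maxSpeed = 100, maxGapS = 1, marginCm = 10,
                         reference = NULL, tol = 5) {
  rs <- resolveSwaps(ts, marginCm = marginCm)
  out <- rs$tracks
  x <- coordsX(out); y <- coordsY(out); v <- validMask(out)
  tt <- frameTimes(out)
  maxGap <- max(1L, as.integer(round(maxGapS * frameRate(ts))))
  n_flagged <- 0L
  n_interp <- 0L
  for (j in seq_len(ncol(out))) {
    vj <- flagImplausible(x[, j], y[, j], tt, valid = v[, j],
                          maxSpeed = maxSpeed)
    n_flagged <- n_flagged + sum(v[, j] & !vj)
    x[, j][!vj] <- NA_real_
    y[, j][!vj] <- NA_real_
    g <- interpolateGaps(x[, j], y[, j], valid = vj, maxGap = maxGap)
    n_interp <- n_interp + sum(g$imputed)
    x[, j] <- g$x; y[, j] <- g$y; v[, j] <- g$valid
  }
  ids <- animalIds(ts)
  repaired <- TrajectorySet(x, y, tt, valid = v, animal_ids = ids,
                            arena = arenaDims(ts), frame_rate = frameRate(ts),
                            day = metadata(ts)$day,
                            familiar = setNames(colData(ts)$familiar_partner,
                                                ids))
  acc <- if (is.null(reference)) NA_real_ else
    estimationAccuracy(repaired, reference, tol = tol)
  report <- methods::new("RepairReport", nFrames = nrow(ts),
                         nFlagged = as.integer(n_flagged),
                         nInterpolated = as.integer(n_interp),
                         nSwapFrames = as.integer(rs$nSwapFrames),
                         accuracy = acc)
  list(tracks = repaired, report = report)
}

setMethod("show", "RepairReport", function(object) {
  cat("RepairReport:\n")
  cat(sprintf("  frames: %d\n", object@nFrames))
  cat(sprintf("  flagged by speed gate: %d animal-frames\n", object@nFlagged))
  cat(sprintf("  interpolated: %d animal-frames\n", object@nInterpolated))
  cat(sprintf("  labels re-assigned: %d animal-frames\n", object@nSwapFrames))
  if (!is.na(object@accuracy))
    cat(sprintf("  estimation accuracy: %.1f%%\n", 100 * object@accuracy))
})

#' Serialize a RepairReport to JSON
#'
#' @param report a \linkS4class{RepairReport}
#' @param path optional file path; when NULL the JSON string is returned
#' @return JSON string (invisibly when written to file)
#' @export
repairReportJSON <- function(report, path = NULL) {
  j <- jsonlite::toJSON(list(
    n_frames = report@nFrames, n_flagged = report@nFlagged,
    n_interpolated = report@nInterpolated,
    n_swap_frames = report@nSwapFrames,
    accuracy = report@accuracy), auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(j, path)
    return(invisible(j))
  }
  j
}
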