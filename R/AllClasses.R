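#' @include grouptrax-package.R
NULL

#' TrajectorySet: per-frame planar coordinates for one tracking session
#'
#' A container for one session (one day) of multi-animal tracking: per-animal,
#' per-frame x/y coordinates in cm with a shared time base and per-animal-frame
#' validity flags. Extends \linkS4class{SummarizedExperiment}: assays
#' \code{x}, \code{y} (numeric, frames in rows, animals in columns) and
#' \code{valid} (logical); \code{rowData} carries \code{time_s};
#' \code{colData} carries \code{animal_id} and, when known, the identity of
#' each animal's familiar partner; \code{metadata} carries the arena
#' dimensions, frame rate and day index.
#'
#' @slot ... see \linkS4class{SummarizedExperiment}
#' @seealso [TrajectorySet()], [coordsX()], [validMask()], [asLongTable()]
#' @export
setClass("TrajectorySet", contains = "SummarizedExperiment")

setValidity("TrajectorySet", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("x", "y", "valid") %in% an))
    return("assays 'x', 'y' and 'valid' are required")
  tt <- rowData(object)$time_s
  if (is.null(tt)) return("rowData column 'time_s' is required")
  if (length(tt) > 1 && any(diff(tt) <= 0))
    return("timestamps must be strictly increasing")
  v <- assay(object, "valid")
  if (!is.logical(v)) return("assay 'valid' must be logical")
  md <- metadata(object)
  if (is.null(md$arena) || length(md$arena) != 2 || any(md$arena <= 0))
    return("metadata 'arena' must hold positive width and height")
  x <- assay(object, "x"); y <- assay(object, "y")
  ok <- !v | (!is.na(x) & !is.na(y) &
                x >= -1e-9 & x <= md$arena[1] + 1e-9 &
                y >= -1e-9 & y <= md$arena[2] + 1e-9)
  if (!all(ok)) return("valid positions must lie inside the arena bounds")
  TRUE
})

#' AgentTraits: latent movement parameters of one simulated animal
#'
#' Ground-truth parameters of the correlated-random-walk agents: mean step
#' length per time-step (\code{activity}, cm), per-partner social attraction
#' weights in \[0, 1\] (named by partner id), pull toward a home-base point
#' (\code{homeAffinity} in \[0, 1\]) and angular step-direction noise
#' (\code{noiseSd}, radians).
#'
#' @slot activity numeric(1), mean step length per time-step in cm; > 0
#' @slot attraction named numeric, attraction weight per partner
#' @slot homeAffinity numeric(1) in \[0, 1\]
#' @slot noiseSd numeric(1), radians; >= 0
#' @slot home numeric(2) home-base coordinates in cm, or length 0 for an
#'   arena-corner default assigned at simulation time
#' @export
setClass("AgentTraits", representation(
  activity = "numeric", attraction = "numeric",
  homeAffinity = "numeric", noiseSd = "numeric", home = "numeric"))

setValidity("AgentTraits", function(object) {
  if (length(object@activity) != 1 || !is.finite(object@activity) ||
      object@activity <= 0)
    return("activity must be a single positive finite number")
  if (length(object@attraction) &&
      (is.null(names(object@attraction)) || any(names(object@attraction) == "")))
    return("attraction weights must be named by partner id")
  if (any(!is.finite(object@attraction)) || any(object@attraction < 0))
    return("attraction weights must be finite and non-negative")
  if (length(object@homeAffinity) != 1 || object@homeAffinity < 0 ||
      object@homeAffinity > 1)
    return("homeAffinity must lie in [0, 1]")
  if (length(object@noiseSd) != 1 || object@noiseSd < 0)
    return("noiseSd must be a single non-negative number")
  if (!length(object@home) %in% c(0L, 2L))
    return("home must be empty or an (x, y) pair")
  TRUE
})

#' ArenaConfig: geometry and timing of a simulated tracking session
#'
#' Defaults mirror a 91 x 54 cm group cage footprint tracked in nine-hour
#' nightly sessions over seven days, sampled at 5 Hz.
#'
#' @slot width,height arena dimensions in cm
#' @slot frameRate sampling rate in Hz
#' @slot sessionDuration session length in seconds
#' @slot nDays number of nightly sessions per term
#' @slot seed master RNG seed
#' @export
setClass("ArenaConfig", representation(
  width = "numeric", height = "numeric", frameRate = "numeric",
  sessionDuration = "numeric", nDays = "integer", seed = "integer"))

setValidity("ArenaConfig", function(object) {
  if (object@width <= 0 || object@height <= 0)
    return("arena width and height must be positive")
  if (object@frameRate <= 0) return("frameRate must be positive")
  if (object@sessionDuration <= 0) return("sessionDuration must be positive")
  if (object@nDays < 1L) return("nDays must be at least 1")
  TRUE
})

#' RepairReport: summary of one track-repair pass
#'
#' @slot nFrames frames per animal in the session
#' @slot nFlagged animal-frames invalidated by the speed gate
#' @slot nInterpolated animal-frames filled by bounded linear interpolation
#' @slot nSwapFrames animal-frames whose labels were re-assigned
#' @slot accuracy fraction of animal-frames within tolerance of a reference
#'   trajectory, or NA when no reference was supplied
#' @export
setClass("RepairReport", representation(
  nFrames = "integer", nFlagged = "integer", nInterpolated = "integer",
  nSwapFrames = "integer", accuracy = "numeric"))

setValidity("RepairReport", function(object) {
  if (!is.na(object@accuracy) &&
      (object@accuracy < 0 || object@accuracy > 1))
    return("accuracy must lie in [0, 1]")
  TRUE
})

#' PCAResult: correlation-matrix PCA of a behavioral-test battery
#'
#' @slot loadings items x components matrix of unit-norm eigenvector loadings,
#'   each column sign-oriented so its largest-magnitude item is positive
#' @slot eigenvalues eigenvalues of the correlation matrix
#' @slot proportionOfVariance eigenvalue / total, over all components
#' @slot scores subjects x components score matrix
#' @slot salience data.frame (item, component, loading): the component each
#'   item is assigned to under the salient-loading rule, NA when unassigned
#' @slot nKeep number of components retained for interpretation
#' @slot scaling character, the loading scaling convention in force
#' @export
setClass("PCAResult", representation(
  loadings = "matrix", eigenvalues = "numeric",
  proportionOfVariance = "numeric", scores = "matrix",
  salience = "data.frame", nKeep = "integer", scaling = "character"))

#' ICCResult: ICC(3,k) consistency estimate with its classification
#'
#' Two-way mixed-effects, consistency-type, average-measures intraclass
#' correlation. Values above 0.7 are classed "substantial", values in
#' \[0.4, 0.7\] "moderate", anything lower (including negative or undefined
#' estimates) "low".
#'
#' @slot value the ICC(3,k) estimate (may be negative or NA)
#' @slot k number of occasions used
#' @slot n number of subjects
#' @slot consistency one of "substantial", "moderate", "low"
#' @slot bms,ems between-subject and residual mean squares
#' @export
setClass("ICCResult", representation(
  value = "numeric", k = "integer", n = "integer",
  consistency = "character", bms = "numeric", ems = "numeric"))

#' ProximitySeries: debounced dyadic proximity indicators for one session
#'
#' @slot series frames x dyads logical matrix (NA where either animal of the
#'   dyad is invalid), after bout debouncing
#' @slot dyadA,dyadB animal ids of each dyad column
#' @slot dt frame interval in seconds
#' @slot sessionDuration nominal session length in seconds
#' @slot validFraction per-dyad fraction of frames with both animals valid
#' @slot usable per-dyad flag: valid fraction at least 0.5
#' @slot thresholdCm,minBoutS the proximity threshold and debounce in force
#' @export
setClass("ProximitySeries", representation(
  series = "matrix", dyadA = "character", dyadB = "character",
  dt = "numeric", sessionDuration = "numeric", validFraction = "numeric",
  usable = "logical", thresholdCm = "numeric", minBoutS = "numeric"))
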