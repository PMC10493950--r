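## Constructors, accessors and show methods. Slot access from user code goes
## through these, never through `@`.

#' Construct an ImageStack
#'
#' @param frames numeric 3-d array (`height x width x n_frames`) of
#'   intensities in `[0, 1]`.
#' @param frameTimes numeric frame times in seconds, strictly increasing.
#' @return An [ImageStack-class] object.
#' @export
newImageStack <- function(frames, frameTimes) {
  new("ImageStack", frames = frames, frameTimes = as.numeric(frameTimes))
}

#' Construct a PsiTrace
#'
#' @param times numeric, seconds, strictly increasing.
#' @param psi numeric, water potential in MPa (all `<= 0`).
#' @return A [PsiTrace-class] object.
#' @export
newPsiTrace <- function(times, psi) {
  new("PsiTrace", times = as.numeric(times), psi = as.numeric(psi))
}

#' Construct a MassSeries
#'
#' @param times numeric, seconds, strictly increasing (>= 10 samples).
#' @param masses numeric, branch mass in g.
#' @param temperature numeric scalar, degrees C in (0, 60).
#' @param rh numeric scalar, relative humidity percent in `[0, 100)`.
#' @param leafDryMass numeric scalar, total leaf dry mass in g.
#' @param sla numeric scalar, specific leaf area in m^2 kg^-1.
#' @return A [MassSeries-class] object.
#' @export
newMassSeries <- function(times, masses, temperature, rh, leafDryMass, sla) {
  new("MassSeries", times = as.numeric(times), masses = as.numeric(masses),
      temperature = as.numeric(temperature), rh = as.numeric(rh),
      leafDryMass = as.numeric(leafDryMass), sla = as.numeric(sla))
}

#' Construct a TraitClimateTable
#'
#' @param data data.frame with columns `species`, `subgenus`, and any of the
#'   trait columns `p50`, `gmin`, `tp` and climate columns `MAT`, `MAP`,
#'   `maxT`, `minT`, `Pdq`.
#' @return A [TraitClimateTable-class] object.
#' @export
newTraitClimateTable <- function(data) {
  data$species <- as.character(data$species)
  data$subgenus <- as.character(data$subgenus)
  new("TraitClimateTable", data = data)
}

#' @name accessors
#' @title Accessors for hydrophylo S4 containers
#' @description Small, read-only accessors for the package's S4 classes.
#' @param x an object of the documented class.
#' @return The slot value (see individual functions).
NULL

#' @describeIn accessors number of frames in an [ImageStack-class].
#' @export
nFrames <- function(x) dim(x@frames)[3]

#' @describeIn accessors frame times (s) of an [ImageStack-class].
#' @export
frameTimes <- function(x) x@frameTimes

#' @describeIn accessors the frame array of an [ImageStack-class].
#' @export
frames <- function(x) x@frames

#' @describeIn accessors per-frame retained event pixel counts of an
#'   [EventMap-class].
#' @export
eventCounts <- function(x) x@counts

#' @describeIn accessors per-frame binary masks of an [EventMap-class].
#' @export
eventMasks <- function(x) x@masks

#' @describeIn accessors the underlying data.frame of a
#'   [TraitClimateTable-class].
#' @export
traitData <- function(x) x@data

#' @describeIn accessors species names of a [TraitClimateTable-class].
#' @export
speciesNames <- function(x) x@data$species

#' @describeIn accessors breakpoint temperature T_P of a
#'   [BreakpointFit-class].
#' @export
phaseTransition <- function(x) x@tp

#' @describeIn accessors minimum conductance of a [ConductancePoint-class].
#' @export
gmin <- function(x) x@gmin

#' @describeIn accessors Cook's distances of a [PGLSResult-class].
#' @export
cooksD <- function(x) x@cooksD

#' @describeIn accessors coefficient table of a [PGLSResult-class] as a
#'   data.frame with estimate, SE, t and p columns.
#' @export
coefTable <- function(x) {
  data.frame(term = x@terms, estimate = x@coefficients, se = x@se,
             t = x@tValues, p = x@pValues, row.names = NULL)
}

#' @describeIn accessors per-component percent variance of a
#'   [ClimatePCA-class].
#' @export
varExplained <- function(x) x@varExplained

#' @describeIn accessors score matrix of a [ClimatePCA-class].
#' @export
pcaScores <- function(x) x@scores

#' @describeIn accessors loading matrix of a [ClimatePCA-class].
#' @export
pcaLoadings <- function(x) x@loadings

#' Curve data of a VulnerabilityCurve
#'
#' @param x a [VulnerabilityCurve-class].
#' @return data.frame with columns `frame`, `psi_MPa`, `cum_px`,
#'   `cum_percent`.
#' @export
curveData <- function(x) {
  data.frame(frame = x@frameIndex, psi_MPa = x@psi, cum_px = x@cumPx,
             cum_percent = x@cumPercent)
}

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("ImageStack: %d frames of %d x %d px, t = %.0f..%.0f s\n",
              d[3], d[1], d[2], min(object@frameTimes),
              max(object@frameTimes)))
})

setMethod("show", "PsiTrace", function(object) {
  cat(sprintf("PsiTrace: %d samples, psi %.2f..%.2f MPa\n",
              length(object@psi), max(object@psi), min(object@psi)))
})

setMethod("show", "EventMap", function(object) {
  cat(sprintf("EventMap: %d frames, %d flagged px total\n",
              length(object@counts), sum(object@counts)))
})

setMethod("show", "VulnerabilityCurve", function(object) {
  cat(sprintf(
    "VulnerabilityCurve: %d frames, psi %.2f..%.2f MPa, complete: %s\n",
    length(object@frameIndex), max(object@psi), min(object@psi),
    object@complete))
})

setMethod("show", "MassSeries", function(object) {
  cat(sprintf(
    "MassSeries: %d points at %.1f C, RH %.1f%%, mass %.4f -> %.4f g\n",
    length(object@times), object@temperature, object@rh,
    object@masses[1], object@masses[length(object@masses)]))
})

setMethod("show", "ConductancePoint", function(object) {
  cat(sprintf(
    "ConductancePoint: T = %.1f C, gmin = %.3f mmol m-2 s-1 (VPD %.3f kPa)\n",
    object@temperature, object@gmin, object@vpd))
})

setMethod("show", "BreakpointFit", function(object) {
  cat(sprintf(
    "BreakpointFit: T_P = %.2f C, slopes %.4f / %.4f, SSE = %.4g\n",
    object@tp, object@slopes[1], object@slopes[2], object@sse))
})

setMethod("show", "TraitClimateTable", function(object) {
  cat(sprintf("TraitClimateTable: %d species (%s)\n",
              nrow(object@data),
              paste(names(object@data), collapse = ", ")))
})

setMethod("show", "ClimatePCA", function(object) {
  cat(sprintf("ClimatePCA: %d variables, PC1 explains %.1f%% of variance\n",
              nrow(object@loadings), object@varExplained[1]))
})

setMethod("show", "PhyloSignalResult", function(object) {
  cat(sprintf(
    "PhyloSignal [%s]: K = %.3f (P = %.3g), lambda = %.3f (LRT P = %.3g)\n",
    object@trait, object@k, object@pK, object@lambdaHat, object@pLambda))
})

setMethod("show", "PGLSResult", function(object) {
  cat(sprintf("PGLS fit (lambda = %.3f, n = %d, R2 = %.3f)\n",
              object@lambdaUsed, object@n, object@rSquared))
  print(coefTable(object), digits = 4)
})
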