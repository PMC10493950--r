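## S4 containers for the measurement pipeline. Validity methods enforce the
## structural invariants every downstream operation relies on; accessors are
## in AllGenerics.R.

#' ImageStack: a time-lapse stack of grayscale leaf images
#'
#' Frames are stored as a numeric `height x width x n_frames` array with
#' intensities in `[0, 1]`; `frameTimes` gives seconds from the start of the
#' drydown and must be strictly increasing.
#'
#' @slot frames numeric 3-d array, `height x width x n_frames`.
#' @slot frameTimes numeric vector of frame times (s), strictly increasing.
#' @seealso [newImageStack()], [differenceStack()], [readImageStack()]
#' @exportClass ImageStack
setClass("ImageStack",
  representation(frames = "array", frameTimes = "numeric"))

setValidity("ImageStack", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L)
    msg <- c(msg, "frames must be a 3-d array (height x width x n_frames)")
  else {
    if (d[3] < 2L) msg <- c(msg, "an ImageStack needs at least 2 frames")
    if (length(object@frameTimes) != d[3])
      msg <- c(msg, "frameTimes length must equal the number of frames")
  }
  if (any(diff(object@frameTimes) <= 0))
    msg <- c(msg, "frameTimes must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' PsiTrace: a water-potential time series from a stem psychrometer
#'
#' @slot times numeric, seconds from start, strictly increasing.
#' @slot psi numeric, water potential in MPa; all values must be `<= 0`.
#' @seealso [newPsiTrace()], [assignPsi()]
#' @exportClass PsiTrace
setClass("PsiTrace", representation(times = "numeric", psi = "numeric"))

setValidity("PsiTrace", function(object) {
  msg <- character()
  if (length(object@times) < 2L)
    msg <- c(msg, "a PsiTrace needs at least 2 samples")
  if (length(object@times) != length(object@psi))
    msg <- c(msg, "times and psi must have equal length")
  if (any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (any(object@psi > 0))
    msg <- c(msg, "water potential must be <= 0 MPa")
  if (length(msg)) msg else TRUE
})

#' EventMap: per-frame binary change masks and retained event pixel counts
#'
#' Produced by [differenceStack()] and refined by [filterNoise()]. The mask
#' for frame 1 is empty by construction (differences are between consecutive
#' frames, attributed to the later frame).
#'
#' @slot masks logical 3-d array, same spatial shape as the source stack.
#' @slot counts integer vector of retained flagged pixels per frame.
#' @exportClass EventMap
setClass("EventMap", representation(masks = "array", counts = "integer"))

setValidity("EventMap", function(object) {
  msg <- character()
  d <- dim(object@masks)
  if (length(d) != 3L)
    msg <- c(msg, "masks must be a 3-d logical array")
  else if (length(object@counts) != d[3])
    msg <- c(msg, "counts length must equal the number of frames")
  if (any(object@counts < 0L))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' VulnerabilityCurve: cumulative embolized area (%) against water potential
#'
#' @slot frameIndex integer frame indices.
#' @slot psi numeric water potential per frame (MPa, interpolated).
#' @slot cumPx numeric cumulative retained event pixels per frame.
#' @slot cumPercent numeric cumulative percent of total cavitated area.
#' @slot complete logical; `FALSE` (with a warning at construction) when no
#'   events were detected at all, in which case `cumPercent` is all zero.
#' @seealso [vulnerabilityCurve()], [psiAtEmbolism()]
#' @exportClass VulnerabilityCurve
setClass("VulnerabilityCurve",
  representation(frameIndex = "integer", psi = "numeric", cumPx = "numeric",
                 cumPercent = "numeric", complete = "logical"))

setValidity("VulnerabilityCurve", function(object) {
  msg <- character()
  n <- length(object@frameIndex)
  if (length(object@psi) != n || length(object@cumPx) != n ||
      length(object@cumPercent) != n)
    msg <- c(msg, "frameIndex, psi, cumPx, cumPercent must have equal length")
  if (any(diff(object@cumPercent) < -1e-9))
    msg <- c(msg, "cumPercent must be non-decreasing")
  if (any(object@cumPercent < -1e-9 | object@cumPercent > 100 + 1e-9))
    msg <- c(msg, "cumPercent must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' MassSeries: a branch drydown mass record at one temperature
#'
#' @slot times numeric, seconds, strictly increasing.
#' @slot masses numeric, branch mass in g.
#' @slot temperature numeric scalar, oven air temperature in degrees C.
#' @slot rh numeric scalar, relative humidity in percent, in `[0, 100)`.
#' @slot leafDryMass numeric scalar, total leaf dry mass in g.
#' @slot sla numeric scalar, specific leaf area in m^2 kg^-1 (projected).
#' @seealso [newMassSeries()], [gminAtTemperature()], [readMassSeries()]
#' @exportClass MassSeries
setClass("MassSeries",
  representation(times = "numeric", masses = "numeric",
                 temperature = "numeric", rh = "numeric",
                 leafDryMass = "numeric", sla = "numeric"))

setValidity("MassSeries", function(object) {
  msg <- character()
  if (length(object@times) < 10L)
    msg <- c(msg, "a MassSeries needs at least 10 samples")
  if (length(object@times) != length(object@masses))
    msg <- c(msg, "times and masses must have equal length")
  if (any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(object@temperature) != 1L ||
      object@temperature <= 0 || object@temperature >= 60)
    msg <- c(msg, "temperature must be a scalar in (0, 60) degrees C")
  if (length(object@rh) != 1L || object@rh < 0 || object@rh >= 100)
    msg <- c(msg, "rh must be a scalar in [0, 100) percent")
  if (object@leafDryMass <= 0) msg <- c(msg, "leafDryMass must be > 0")
  if (object@sla <= 0) msg <- c(msg, "sla must be > 0")
  if (length(msg)) msg else TRUE
})

#' ConductancePoint: minimum conductance at one temperature
#'
#' @slot temperature numeric, degrees C.
#' @slot gmin numeric, minimum conductance in mmol m^-2 s^-1.
#' @slot rFlux numeric, steady transpiration rate R in mmol m^-2 s^-1.
#' @slot vpd numeric, vapour pressure deficit in kPa.
#' @slot steadyWindow integer length-2, index range of the steady-state
#'   window in the source mass series.
#' @exportClass ConductancePoint
setClass("ConductancePoint",
  representation(temperature = "numeric", gmin = "numeric", rFlux = "numeric",
                 vpd = "numeric", steadyWindow = "integer"))

setValidity("ConductancePoint", function(object) {
  msg <- character()
  if (object@gmin < 0) msg <- c(msg, "gmin must be >= 0")
  if (object@vpd <= 0 ||
      object@vpd > saturationVaporPressure(object@temperature) + 1e-9)
    msg <- c(msg, "vpd must lie in (0, SVP(temperature)]")
  if (length(object@steadyWindow) != 2L)
    msg <- c(msg, "steadyWindow must be a length-2 index range")
  if (length(msg)) msg else TRUE
})

#' BreakpointFit: a continuous two-segment linear fit of g_min vs temperature
#'
#' Model: `g(T) = b0 + b1*T + b2*(T - tp)_+`, continuous at the breakpoint
#' `tp`, which is reported as the phase-transition temperature T_P.
#'
#' @slot tp numeric, breakpoint temperature (degrees C), strictly inside the
#'   observed temperature range.
#' @slot slopes numeric length-2, segment slopes below and above `tp`.
#' @slot intercept numeric, intercept of the lower segment.
#' @slot sse numeric, residual sum of squares at the optimum.
#' @slot fitted numeric, fitted values at the observed temperatures.
#' @slot temperature numeric, the observed temperatures.
#' @slot gmin numeric, the observed conductances.
#' @seealso [fitBreakpoint()]
#' @exportClass BreakpointFit
setClass("BreakpointFit",
  representation(tp = "numeric", slopes = "numeric", intercept = "numeric",
                 sse = "numeric", fitted = "numeric", temperature = "numeric",
                 gmin = "numeric"))

setValidity("BreakpointFit", function(object) {
  msg <- character()
  if (object@tp <= min(object@temperature) ||
      object@tp >= max(object@temperature))
    msg <- c(msg, "tp must lie strictly inside the temperature range")
  if (length(object@slopes) != 2L)
    msg <- c(msg, "slopes must have length 2 (below, above)")
  if (length(msg)) msg else TRUE
})

#' TraitClimateTable: species traits, climate variables and subgenus labels
#'
#' A validated wrapper around a species-by-variable data.frame. The `species`
#' column must be unique; trait columns (`p50`, `gmin`, `tp`) and climate
#' columns (any of `MAT`, `MAP`, `maxT`, `minT`, `Pdq`) are recognized by
#' name. Missing trait cells are allowed (species are dropped per-analysis).
#'
#' @slot data data.frame with at least columns `species` and `subgenus`.
#' @seealso [newTraitClimateTable()], [eucalyptTraits()], [pglsFit()]
#' @exportClass TraitClimateTable
setClass("TraitClimateTable", representation(data = "data.frame"))

setValidity("TraitClimateTable", function(object) {
  msg <- character()
  d <- object@data
  if (!all(c("species", "subgenus") %in% names(d)))
    msg <- c(msg, "data must contain 'species' and 'subgenus' columns")
  else if (anyDuplicated(d$species))
    msg <- c(msg, "duplicated species in table")
  if (length(msg)) msg else TRUE
})

#' ClimatePCA: principal component analysis of site climate variables
#'
#' @slot loadings numeric matrix (variables x components), orthonormal.
#' @slot scores numeric matrix (species x components).
#' @slot varExplained numeric, percent variance per component (sums to 100).
#' @slot center,scale numeric, the centering and scaling vectors applied.
#' @seealso [climatePCA()]
#' @exportClass ClimatePCA
setClass("ClimatePCA",
  representation(loadings = "matrix", scores = "matrix",
                 varExplained = "numeric", center = "numeric",
                 scale = "numeric"))

setValidity("ClimatePCA", function(object) {
  msg <- character()
  if (abs(sum(object@varExplained) - 100) > 1e-6)
    msg <- c(msg, "varExplained must sum to 100")
  if (length(msg)) msg else TRUE
})

#' PhyloSignalResult: phylogenetic signal of one trait on one tree
#'
#' Houses both Blomberg's K (with its permutation p-value) and Pagel's
#' lambda (with the likelihood-ratio p-value against lambda = 0).
#'
#' @slot trait character, name of the trait tested.
#' @slot k numeric, Blomberg's K.
#' @slot pK numeric, permutation p-value for K.
#' @slot lambdaHat numeric, ML estimate of Pagel's lambda in `[0, 1]`.
#' @slot loglikLambda,loglikZero numeric, log-likelihoods at `lambdaHat`
#'   and at `lambda = 0`.
#' @slot pLambda numeric, LRT p-value (chi-square, 1 df; conservative at
#'   the `lambda = 0` boundary).
#' @seealso [phyloSignal()], [blombergK()], [pagelLambda()]
#' @exportClass PhyloSignalResult
setClass("PhyloSignalResult",
  representation(trait = "character", k = "numeric", pK = "numeric",
                 lambdaHat = "numeric", loglikLambda = "numeric",
                 loglikZero = "numeric", pLambda = "numeric"))

setValidity("PhyloSignalResult", function(object) {
  msg <- character()
  if (object@k < 0) msg <- c(msg, "K must be >= 0")
  if (!is.na(object@pK) && (object@pK <= 0 || object@pK > 1))
    msg <- c(msg, "pK must lie in (0, 1]")
  if (object@lambdaHat < 0 || object@lambdaHat > 1)
    msg <- c(msg, "lambdaHat must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' PGLSResult: a phylogenetic generalized least squares fit
#'
#' @slot call the matched call.
#' @slot coefficients numeric named vector of estimates.
#' @slot se,tValues,pValues numeric, per-coefficient inference (t with
#'   `n - p` df).
#' @slot lambdaUsed numeric, the residual lambda used (ML or fixed).
#' @slot logLik numeric, profile log-likelihood at `lambdaUsed`.
#' @slot rSquared numeric, GLS R-squared, `1 - RSS_V / TSS_V` with TSS from
#'   the GLS intercept-only fit under the same covariance.
#' @slot residuals numeric named, raw-scale residuals.
#' @slot cooksD numeric named, Cook's distance per species computed on the
#'   whitened (decorrelated) regression.
#' @slot n,df integer, observations and residual degrees of freedom.
#' @slot terms character, model term labels.
#' @seealso [pglsFit()], [cooksD()]
#' @exportClass PGLSResult
setClass("PGLSResult",
  representation(call = "call", coefficients = "numeric", se = "numeric",
                 tValues = "numeric", pValues = "numeric",
                 lambdaUsed = "numeric", logLik = "numeric",
                 rSquared = "numeric", residuals = "numeric",
                 cooksD = "numeric", n = "integer", df = "integer",
                 terms = "character"))

setValidity("PGLSResult", function(object) {
  msg <- character()
  if (object@df != object@n - length(object@coefficients))
    msg <- c(msg, "df must equal n - p")
  if (any(object@cooksD < 0, na.rm = TRUE))
    msg <- c(msg, "Cook's distances must be >= 0")
  if (length(msg)) msg else TRUE
})
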