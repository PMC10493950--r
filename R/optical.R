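## Optical vulnerability pipeline: frame differencing -> artifact filtering
## -> cumulative embolized area -> psi assignment -> P50 extraction.

#' Difference consecutive frames of an image stack
#'
#' Flags pixels whose absolute intensity change between consecutive frames
#' exceeds `diffThreshold`; these are candidate cavitation events, attributed
#' to the later frame. Intensities are held as doubles, so the subtraction is
#' carried out in a signed domain with no unsigned wraparound. The mask for
#' the first frame is empty by construction.
#'
#' @param stack an [ImageStack-class].
#' @param diffThreshold numeric > 0, intensity change threshold (same units
#'   as the stack, i.e. the `[0, 1]` scale).
#' @return An [EventMap-class] with per-frame masks and flagged-pixel counts.
#' @export
differenceStack <- function(stack, diffThreshold = 0.15) {
  stopIfNot(is(stack, "ImageStack"), "stack must be an ImageStack")
  stopIfNot(diffThreshold > 0, "diffThreshold must be > 0")
  f <- frames(stack)
  n <- dim(f)[3]
  stopIfNot(n >= 2, "cannot difference a single-frame stack")
  masks <- array(FALSE, dim = dim(f))
  masks[, , 2:n] <- abs(f[, , 2:n, drop = FALSE] -
                        f[, , 1:(n - 1), drop = FALSE]) > diffThreshold
  counts <- as.integer(apply(masks, 3, sum))
  new("EventMap", masks = masks, counts = counts)
}

#' Remove small components and out-of-region pixels from an event map
#'
#' Cavitation events in veins are extended patches; leaf-shrinkage artifacts
#' are isolated flickers. Per frame, connected components (8-connectivity)
#' smaller than `minEventPx` are removed, and pixels outside the optional
#' region `mask` (e.g. a vein mask) are dropped.
#'
#' @param events an [EventMap-class].
#' @param minEventPx integer >= 1, minimum retained component area (px);
#'   `1` disables the area filter.
#' @param mask optional logical matrix of the frame shape; `TRUE` marks the
#'   analysis region.
#' @return A filtered [EventMap-class] with updated counts.
#' @export
filterNoise <- function(events, minEventPx = 4L, mask = NULL) {
  stopIfNot(is(events, "EventMap"), "events must be an EventMap")
  stopIfNot(minEventPx >= 1, "minEventPx must be >= 1")
  m <- eventMasks(events)
  d <- dim(m)
  if (!is.null(mask)) {
    stopIfNot(is.logical(mask) && all(dim(mask) == d[1:2]),
              "mask shape must match the frames")
    m <- m & as.vector(mask)
  }
  if (minEventPx > 1L) {
    for (j in seq_len(d[3])) {
      if (!any(m[, , j])) next
      lab <- labelComponents(m[, , j])
      sz <- tabulate(lab[lab > 0L])
      drop <- which(sz < minEventPx)
      if (length(drop)) {
        mj <- m[, , j]
        mj[lab %in% drop] <- FALSE
        m[, , j] <- mj
      }
    }
  }
  new("EventMap", masks = m, counts = as.integer(apply(m, 3, sum)))
}

#' Cumulative embolized area per frame
#'
#' Running sum of retained event pixels, expressed also as a percentage of
#' the final cumulative total (the area at complete dehydration). When no
#' events were retained at all, the percentages are all zero and the result
#' carries `complete = FALSE` with a warning.
#'
#' @param events an [EventMap-class].
#' @return data.frame with columns `frame`, `count`, `cum_px`,
#'   `cum_percent`, plus attribute `complete`.
#' @export
cumulativeEmbolism <- function(events) {
  stopIfNot(is(events, "EventMap"), "events must be an EventMap")
  counts <- eventCounts(events)
  cum <- cumsum(as.numeric(counts))
  total <- cum[length(cum)]
  complete <- total > 0
  pct <- if (complete) 100 * cum / total else rep(0, length(cum))
  if (!complete)
    warning("no cavitation events detected; curve is incomplete",
            call. = FALSE)
  out <- data.frame(frame = seq_along(counts), count = counts,
                    cum_px = cum, cum_percent = pct)
  attr(out, "complete") <- complete
  out
}

#' Interpolate water potential at each frame time
#'
#' Linear interpolation of the psychrometer trace at the image frame times.
#' Frame times outside the trace's span are clamped to the nearest endpoint
#' with a warning.
#'
#' @param frameTimes numeric, frame times (s).
#' @param trace a [PsiTrace-class].
#' @return Numeric vector of water potentials (MPa), one per frame.
#' @export
assignPsi <- function(frameTimes, trace) {
  stopIfNot(is(trace, "PsiTrace"), "trace must be a PsiTrace")
  tt <- trace@times; pp <- trace@psi
  outside <- frameTimes < min(tt) | frameTimes > max(tt)
  if (any(outside))
    warning(sprintf("%d frame time(s) outside the psi trace; clamped",
                    sum(outside)), call. = FALSE)
  approx(tt, pp, xout = pmin(pmax(frameTimes, min(tt)), max(tt)),
         method = "linear", rule = 2)$y
}

#' Build a vulnerability curve from an event map and a psi trace
#'
#' Combines [cumulativeEmbolism()] and [assignPsi()] into a
#' [VulnerabilityCurve-class].
#'
#' @param events an [EventMap-class] (already filtered).
#' @param frameTimes numeric frame times (s), as from [frameTimes()].
#' @param trace a [PsiTrace-class].
#' @return A [VulnerabilityCurve-class].
#' @export
vulnerabilityCurve <- function(events, frameTimes, trace) {
  ce <- cumulativeEmbolism(events)
  psi <- assignPsi(frameTimes, trace)
  new("VulnerabilityCurve", frameIndex = ce$frame, psi = psi,
      cumPx = ce$cum_px, cumPercent = ce$cum_percent,
      complete = attr(ce, "complete"))
}

#' Water potential at a given cumulative embolism percentage
#'
#' Walks the curve in dehydration order (decreasing psi) and returns the
#' water potential at the first crossing of `percent`, linearly interpolated
#' between the bracketing frames. With `percent = 50` this is P50.
#'
#' @param curve a complete [VulnerabilityCurve-class].
#' @param percent numeric in (0, 100).
#' @return Water potential (MPa) at the crossing.
#' @export
psiAtEmbolism <- function(curve, percent = 50) {
  stopIfNot(is(curve, "VulnerabilityCurve"),
            "curve must be a VulnerabilityCurve")
  stopIfNot(percent > 0 && percent < 100, "percent must lie in (0, 100)")
  stopIfNot(curve@complete,
            "incomplete dehydration: no events were detected")
  pct <- curve@cumPercent; psi <- curve@psi
  k <- which(pct >= percent)
  if (!length(k))
    stop(sprintf("incomplete dehydration: curve never reaches %g%%",
                 percent), call. = FALSE)
  k <- min(k)
  if (k == 1L || pct[k] == percent) return(psi[k])
  ## interpolate on (percent, psi) between the bracketing frames
  p0 <- pct[k - 1L]; p1 <- pct[k]
  w <- (percent - p0) / (p1 - p0)
  psi[k - 1L] + w * (psi[k] - psi[k - 1L])
}

#' Logistic fit alternative for P_x extraction
#'
#' Fits the logistic vulnerability curve [logisticVC()] to the empirical
#' (psi, cumulative %) points by nonlinear least squares and reads P50 (or
#' another percentile) from the fitted curve. Offered for sensitivity
#' analysis next to the default empirical-crossing estimate of
#' [psiAtEmbolism()].
#'
#' @param curve a complete [VulnerabilityCurve-class].
#' @param percent numeric in (0, 100).
#' @return Water potential (MPa) at `percent` on the fitted logistic.
#' @export
psiAtEmbolismLogistic <- function(curve, percent = 50) {
  stopIfNot(is(curve, "VulnerabilityCurve"),
            "curve must be a VulnerabilityCurve")
  stopIfNot(curve@complete, "incomplete dehydration")
  psi <- curve@psi; pct <- curve@cumPercent
  start <- list(p50 = psiAtEmbolism(curve, 50), slope = 60)
  fit <- stats::nls(pct ~ 100 / (1 + exp(slope / 25 * (psi - p50))),
                    start = start,
                    control = stats::nls.control(warnOnly = TRUE))
  cf <- coef(fit)
  logisticVCinv(percent, cf[["p50"]], cf[["slope"]])
}

#' Species mean and standard error of replicate P50 values
#'
#' @param p50s numeric, per-replicate P50 estimates (MPa), length >= 1.
#' @return list with `mean` and `se` (`se` is `NA` for a single replicate).
#' @export
speciesP50 <- function(p50s) {
  stopIfNot(length(p50s) >= 1, "need at least one replicate")
  n <- length(p50s)
  list(mean = mean(p50s), se = if (n > 1) sd(p50s) / sqrt(n) else NA_real_)
}

#' Full optical pipeline: stack + trace to P50
#'
#' Convenience composition of [differenceStack()], [filterNoise()],
#' [vulnerabilityCurve()] and [psiAtEmbolism()].
#'
#' @param stack an [ImageStack-class].
#' @param trace a [PsiTrace-class].
#' @param diffThreshold,minEventPx,mask see [differenceStack()] and
#'   [filterNoise()].
#' @param percent percent embolism at which to read the water potential.
#' @param method `"empirical"` (linear interpolation of the curve, default)
#'   or `"logistic"` (fitted-sigmoid alternative).
#' @return list with `p50` (MPa) and `curve` (the
#'   [VulnerabilityCurve-class]).
#' @export
opticalP50 <- function(stack, trace, diffThreshold = 0.15, minEventPx = 4L,
                       mask = NULL, percent = 50,
                       method = c("empirical", "logistic")) {
  method <- match.arg(method)
  ev <- filterNoise(differenceStack(stack, diffThreshold), minEventPx, mask)
  curve <- vulnerabilityCurve(ev, frameTimes(stack), trace)
  p <- if (method == "empirical") psiAtEmbolism(curve, percent)
       else psiAtEmbolismLogistic(curve, percent)
  list(p50 = p, curve = curve)
}
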