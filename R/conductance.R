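## Minimum conductance from drydown mass series: Buck saturation vapour
## pressure, VPD, leaf area from SLA, steady-state detection, transpiration
## rate, conductance, and the two-segment breakpoint fit for T_P.

#' Saturation vapour pressure (Buck equation)
#'
#' `SVP = (610.7 * 10^(7.5 * T / (237.3 + T))) / 1000` kPa, the Buck
#' formulation of saturation vapour pressure over water.
#'
#' @param temperature numeric, air temperature (degrees C), `> -237.3`.
#' @return Saturation vapour pressure (kPa).
#' @examples
#' saturationVaporPressure(0)   # 0.6107
#' saturationVaporPressure(25)  # ~3.167
#' @export
saturationVaporPressure <- function(temperature) {
  stopIfNot(all(temperature > -237.3), "temperature must be > -237.3 C")
  (610.7 * 10^(7.5 * temperature / (237.3 + temperature))) / 1000
}

#' Vapour pressure deficit
#'
#' `VPD = (1 - RH/100) * SVP(T)` kPa.
#'
#' @param temperature numeric, degrees C.
#' @param rh numeric, relative humidity in percent, in `[0, 100]`.
#' @return Vapour pressure deficit (kPa).
#' @export
vaporPressureDeficit <- function(temperature, rh) {
  stopIfNot(all(rh >= 0 & rh <= 100), "rh must lie in [0, 100]")
  (1 - rh / 100) * saturationVaporPressure(temperature)
}

#' Leaf area from dry mass and specific leaf area
#'
#' Projected area is `dry mass (kg) * SLA`; the conventional SLA is
#' projected (one-sided), while the transpiring surface of a branchlet is
#' double-sided, so the default doubles the projected area.
#'
#' @param leafDryMass numeric > 0, total leaf dry mass (g).
#' @param sla numeric > 0, specific leaf area (m^2 kg^-1, projected).
#' @param doubleSided logical, return the double-sided area (default TRUE).
#' @return Leaf area (m^2).
#' @export
leafArea <- function(leafDryMass, sla, doubleSided = TRUE) {
  stopIfNot(all(leafDryMass > 0), "leafDryMass must be > 0")
  stopIfNot(all(sla > 0), "sla must be > 0")
  a <- (leafDryMass / 1000) * sla
  if (doubleSided) 2 * a else a
}

#' Detect the terminal steady-state window of a drydown
#'
#' Computes rolling least-squares slopes of mass against time over windows
#' of `window` points and finds the longest terminal run of windows whose
#' slope deviates from the final window's slope by at most `relTol`
#' (relative). This excludes the early stomatal-closure phase, in which the
#' water-loss rate is still decaying towards the cuticular steady state.
#' The run must contain at least two qualifying windows; a series that is
#' still curving at its end (no plateau) raises an error.
#'
#' @param series a [MassSeries-class].
#' @param window integer >= 3, points per rolling slope.
#' @param relTol numeric > 0, relative slope tolerance.
#' @return Integer length-2, first and last index of the steady window.
#' @export
detectSteadyState <- function(series, window = 5L, relTol = 0.15) {
  stopIfNot(is(series, "MassSeries"), "series must be a MassSeries")
  stopIfNot(window >= 3, "window must be >= 3")
  t <- series@times; m <- series@masses
  n <- length(t)
  nw <- n - window + 1L
  stopIfNot(nw >= 2, "series too short for the window")
  slopes <- vapply(seq_len(nw), function(i) {
    ii <- i:(i + window - 1L)
    tc <- t[ii] - mean(t[ii])
    sum(tc * m[ii]) / sum(tc * tc)
  }, numeric(1))
  ref <- slopes[nw]
  ok <- abs(slopes - ref) <= relTol * max(abs(ref), .Machine$double.eps)
  ## longest terminal run of qualifying windows
  first <- nw
  while (first > 1L && ok[first - 1L]) first <- first - 1L
  if (first == nw)
    stop("no steady state: water-loss rate is still changing at the end",
         call. = FALSE)
  c(first, n)
}

#' Transpiration rate over a steady window
#'
#' `R = delta w / (delta t * A)`: the least-squares slope of mass against
#' time over the window (g s^-1, noise-robust version of first-vs-last
#' differencing), converted to a water flux in mmol m^-2 s^-1 via the molar
#' mass of water, with the sign flipped so mass loss gives `R >= 0`. A
#' non-negative mass slope yields `R = 0` with a warning.
#'
#' @param series a [MassSeries-class].
#' @param range integer length-2, index range (>= 3 points).
#' @param area numeric > 0, leaf area (m^2).
#' @return Transpiration rate R (mmol m^-2 s^-1).
#' @export
transpirationRate <- function(series, range, area) {
  stopIfNot(is(series, "MassSeries"), "series must be a MassSeries")
  stopIfNot(length(range) == 2L && range[2] - range[1] >= 2,
            "range must span at least 3 points")
  stopIfNot(area > 0, "area must be > 0")
  ii <- range[1]:range[2]
  t <- series@times[ii]; m <- series@masses[ii]
  tc <- t - mean(t)
  slope <- sum(tc * m) / sum(tc * tc)  # g s^-1
  if (slope >= 0) {
    warning("non-negative mass slope; transpiration rate set to 0",
            call. = FALSE)
    return(0)
  }
  (-slope) / .WATER_MOLAR_MASS * 1000 / area
}

#' Minimum conductance at one temperature
#'
#' Composes steady-state detection, the transpiration rate and the
#' conductance equation `g = R / VPD * P_atm`, with `P_atm = 101.6` kPa
#' (sea-level atmospheric pressure) by default.
#'
#' @param series a [MassSeries-class].
#' @param window,relTol steady-state detection parameters
#'   (see [detectSteadyState()]).
#' @param doubleSided logical, double-sided leaf area (see [leafArea()]).
#' @param patm numeric, atmospheric pressure (kPa).
#' @return A [ConductancePoint-class].
#' @export
gminAtTemperature <- function(series, window = 5L, relTol = 0.15,
                              doubleSided = TRUE, patm = 101.6) {
  stopIfNot(is(series, "MassSeries"), "series must be a MassSeries")
  vpd <- vaporPressureDeficit(series@temperature, series@rh)
  if (vpd <= 0)
    stop("VPD is zero (RH = 100%): conductance is undefined", call. = FALSE)
  win <- detectSteadyState(series, window = window, relTol = relTol)
  area <- leafArea(series@leafDryMass, series@sla, doubleSided = doubleSided)
  r <- transpirationRate(series, win, area)
  new("ConductancePoint", temperature = series@temperature,
      gmin = r / vpd * patm, rFlux = r, vpd = vpd,
      steadyWindow = as.integer(win))
}

## ---- breakpoint (phase transition temperature) ----

# SSE of the continuous two-segment model g = b0 + b1*T + b2*(T - bp)_+
# at a fixed breakpoint, by ordinary least squares.
segmentedSSE <- function(temperature, g, bp) {
  X <- cbind(1, temperature, pmax(temperature - bp, 0))
  fit <- lm.fit(X, g)
  sum(fit$residuals^2)
}

#' Fit a single breakpoint to conductance vs temperature
#'
#' Fits the continuous two-segment linear model
#' `g(T) = b0 + b1*T + b2*(T - tp)_+` by an exhaustive 0.1-degree grid over
#' candidate breakpoints strictly between the 2nd and penultimate observed
#' temperatures (minimizing the residual sum of squares), followed by
#' golden-section refinement around the best grid point. The breakpoint is
#' reported as the phase-transition temperature T_P. When the SSE profile is
#' flat across the whole grid (e.g. globally linear data), the breakpoint is
#' not identifiable and an error is raised.
#'
#' @param points a list of [ConductancePoint-class] objects, or a data.frame
#'   with columns `temperature` and `gmin`; at least 5 temperatures.
#' @return A [BreakpointFit-class].
#' @export
fitBreakpoint <- function(points) {
  if (is.data.frame(points)) {
    temp <- points$temperature; g <- points$gmin
  } else {
    stopIfNot(all(vapply(points, is, logical(1), "ConductancePoint")),
              "points must be ConductancePoints or a data.frame")
    temp <- vapply(points, function(p) p@temperature, numeric(1))
    g <- vapply(points, function(p) p@gmin, numeric(1))
  }
  stopIfNot(length(temp) >= 5, "need at least 5 temperature points")
  o <- order(temp)
  temp <- temp[o]; g <- g[o]
  lo <- temp[2]; hi <- temp[length(temp) - 1L]
  grid <- seq(lo, hi, by = 0.1)
  grid <- grid[grid > lo & grid < hi]
  stopIfNot(length(grid) >= 3, "temperature span too narrow for a breakpoint")
  sse <- vapply(grid, function(bp) segmentedSSE(temp, g, bp), numeric(1))
  if (max(sse) - min(sse) <= 1e-8 * (max(sse) + 1e-12))
    stop("breakpoint not identifiable: SSE is flat across the grid ",
         "(relationship is effectively linear)", call. = FALSE)
  best <- which.min(sse)
  lower <- grid[max(1L, best - 1L)]
  upper <- grid[min(length(grid), best + 1L)]
  opt <- optimize(function(bp) segmentedSSE(temp, g, bp),
                  interval = c(lower, upper), tol = 1e-6)
  bp <- opt$minimum
  X <- cbind(1, temp, pmax(temp - bp, 0))
  fit <- lm.fit(X, g)
  b <- fit$coefficients
  new("BreakpointFit", tp = bp, slopes = unname(c(b[2], b[2] + b[3])),
      intercept = unname(b[1]), sse = sum(fit$residuals^2),
      fitted = unname(X %*% b)[, 1], temperature = temp, gmin = g)
}

#' Species-mean conductance curve and phase transition temperature
#'
#' Averages replicate conductance estimates per temperature into a mean
#' curve and fits the breakpoint to it (T_P is extracted from a mean curve
#' across replicates, so it carries no standard error). Per-replicate
#' fitting is available via `perReplicate = TRUE`, which fits a breakpoint
#' to each replicate column instead.
#'
#' @param points list of [ConductancePoint-class] (replicates at repeated
#'   temperatures are averaged), or a data.frame with `temperature`, `gmin`
#'   and optionally `replicate`.
#' @param perReplicate logical; fit each replicate separately.
#' @return A [BreakpointFit-class], or a list of them when
#'   `perReplicate = TRUE`.
#' @export
speciesTp <- function(points, perReplicate = FALSE) {
  df <- if (is.data.frame(points)) points else
    data.frame(temperature = vapply(points, function(p) p@temperature,
                                    numeric(1)),
               gmin = vapply(points, function(p) p@gmin, numeric(1)))
  if (perReplicate && !is.null(df$replicate)) {
    return(lapply(split(df, df$replicate), fitBreakpoint))
  }
  agg <- stats::aggregate(gmin ~ temperature, data = df, FUN = mean)
  fitBreakpoint(agg)
}
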