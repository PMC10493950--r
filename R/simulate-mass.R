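## Simulator for the drydown stage: branch mass series whose water flux is
## driven by a conductance that relaxes exponentially from a stomatal value
## to a temperature-dependent minimum, with the minimum piecewise linear in
## temperature around a known phase-transition breakpoint.

#' Piecewise-linear temperature response of minimum conductance
#'
#' `g_min(T)` is linear with slope `slopeBelow` up to the breakpoint `tp`
#' and slope `slopeAbove` beyond it, anchored at `gminRef` at the reference
#' temperature `refT` (assumed at or below `tp`).
#'
#' @param temperature numeric, degrees C.
#' @param gminRef numeric, g_min at `refT` (mmol m^-2 s^-1).
#' @param slopeBelow,slopeAbove numeric, segment slopes
#'   (mmol m^-2 s^-1 per degree C).
#' @param tp numeric, breakpoint temperature (degrees C).
#' @param refT numeric, reference temperature (degrees C).
#' @return g_min at `temperature` (mmol m^-2 s^-1).
#' @export
gminTemperatureModel <- function(temperature, gminRef = 5, slopeBelow = 0.05,
                                 slopeAbove = 0.6, tp = 36, refT = 25) {
  gminRef + slopeBelow * (pmin(temperature, tp) - refT) +
    slopeAbove * pmax(temperature - tp, 0)
}

# Molar mass of water, g mol^-1.
.WATER_MOLAR_MASS <- 18.015

#' Simulate branch drydown mass series across temperatures
#'
#' For each temperature, the instantaneous conductance is
#' `g(t) = gmin(T) + (initialStomatalG - gmin(T)) * exp(-t / closureTau)`
#' (stomatal closure as a single exponential decaying to the cuticular
#' steady state). Water flux is `g(t) * VPD(T, rh) / P_atm * area` in
#' mmol s^-1, converted to grams via the molar mass of water and integrated
#' analytically; Gaussian noise of sd `noiseSdMass` is then added to the
#' mass readings. The series metadata (dry mass, SLA) is set so that
#' [leafArea()] (double-sided) recovers `leafArea` exactly.
#'
#' @param temps numeric, oven temperatures (degrees C), each in (0, 60).
#' @param gminRef,slopeBelow,slopeAbove,tp parameters of
#'   [gminTemperatureModel()].
#' @param rh numeric, relative humidity percent, `< 100`.
#' @param leafArea numeric, double-sided leaf area (m^2).
#' @param sla numeric, specific leaf area (m^2 kg^-1, projected).
#' @param initialStomatalG numeric, conductance at t = 0 (mmol m^-2 s^-1).
#' @param closureTau numeric, stomatal closure time constant (s).
#' @param duration,dt numeric, series length and sampling interval (s);
#'   `duration / dt` must be >= 30.
#' @param noiseSdMass numeric >= 0, Gaussian mass noise sd (g).
#' @param initialMassFactor numeric, initial fresh mass as a multiple of
#'   leaf dry mass.
#' @param patm numeric, atmospheric pressure (kPa).
#' @param seed integer, RNG seed.
#' @return list with `series` (list of [MassSeries-class], one per
#'   temperature) and `truth` (list: `gminByT` named vector, `tp`,
#'   `leafArea`, `fluxByT` steady mass-loss rate in g s^-1 per temperature).
#' @export
simulateMassSeries <- function(temps = c(25, 28, 32, 36, 40, 44, 48),
                               gminRef = 5, slopeBelow = 0.05,
                               slopeAbove = 0.6, tp = 36, rh = 40,
                               leafArea = 0.01, sla = 10,
                               initialStomatalG = 60, closureTau = 900,
                               duration = 10800, dt = 300,
                               noiseSdMass = 5e-4,
                               initialMassFactor = 3, patm = 101.6,
                               seed = 1) {
  stopIfNot(all(temps > 0 & temps < 60), "temps must lie in (0, 60)")
  stopIfNot(rh >= 0 && rh < 100,
            "rh must be < 100 (VPD of zero gives no flux)")
  stopIfNot(leafArea > 0, "leafArea must be > 0")
  stopIfNot(duration / dt >= 30, "need at least 30 points (duration / dt)")
  stopIfNot(noiseSdMass >= 0, "noiseSdMass must be >= 0")
  dryMass <- 1000 * leafArea / (2 * sla)  # g; leafArea is double-sided
  m0 <- initialMassFactor * dryMass
  times <- seq(0, duration, by = dt)
  gByT <- gminTemperatureModel(temps, gminRef, slopeBelow, slopeAbove, tp)
  names(gByT) <- as.character(temps)
  withSeed(seed, {
    series <- vector("list", length(temps))
    fluxByT <- numeric(length(temps))
    for (i in seq_along(temps)) {
      Tc <- temps[i]
      gm <- gByT[i]
      vpd <- vaporPressureDeficit(Tc, rh)
      ## cumulative conductance-time integral (mmol m^-2)
      gInt <- gm * times +
        (initialStomatalG - gm) * closureTau * (1 - exp(-times / closureTau))
      loss <- gInt * vpd / patm * leafArea * .WATER_MOLAR_MASS / 1000  # g
      masses <- m0 - loss
      if (noiseSdMass > 0)
        masses <- masses + rnorm(length(masses), sd = noiseSdMass)
      fluxByT[i] <- gm * vpd / patm * leafArea * .WATER_MOLAR_MASS / 1000
      series[[i]] <- newMassSeries(times, masses, Tc, rh, dryMass, sla)
    }
    names(series) <- as.character(temps)
    list(series = series,
         truth = list(gminByT = gByT, tp = tp, leafArea = leafArea,
                      fluxByT = setNames(fluxByT, as.character(temps))))
  })
}
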