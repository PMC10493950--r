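test_that("Buck saturation vapour pressure and VPD follow the formulas", {
  expect_identical(saturationVaporPressure(0), 0.6107)
  expect_equal(saturationVaporPressure(25), 3.167, tolerance = 1e-3)
  expect_equal(saturationVaporPressure(48), 11.16, tolerance = 1e-3)
  # strictly increasing over the working range
  svp <- saturationVaporPressure(seq(0, 48, by = 0.5))
  expect_true(all(diff(svp) > 0))

  expect_equal(vaporPressureDeficit(25, 100), 0)
  expect_equal(vaporPressureDeficit(25, 0), saturationVaporPressure(25))
  expect_equal(vaporPressureDeficit(25, 50), 1.583, tolerance = 1e-3)
  # decreasing in RH, and g scales as R/VPD
  expect_true(all(diff(vaporPressureDeficit(30, c(0, 25, 50, 75, 95))) < 0))
})

test_that("leaf area from SLA, with the double-sided convention", {
  expect_equal(leafArea(10, 10, doubleSided = FALSE), 0.1)
  expect_equal(leafArea(10, 10, doubleSided = TRUE), 0.2)
  expect_error(leafArea(-1, 10), "leafDryMass")
  # the simulator's metadata inverts exactly to the area it used
  sim <- simulateMassSeries(leafArea = 0.0123, sla = 12, seed = 1)
  s <- sim$series[[1]]
  expect_equal(leafArea(s@leafDryMass, s@sla, doubleSided = TRUE), 0.0123,
               tolerance = 1e-12)
})

test_that("steady-state detection isolates the terminal linear phase", {
  mkSeries <- function(masses, dt = 300, Tc = 25, rh = 40)
    newMassSeries((seq_along(masses) - 1) * dt, masses, Tc, rh, 0.5, 10)
  # perfectly linear: the whole series qualifies
  lin <- mkSeries(2 - (0:39) * 1e-3)
  expect_equal(detectSteadyState(lin), c(1, 40))
  # biphasic with a long plateau: the window starts after the stomatal
  # phase (past 5 closure time constants for a large initial conductance)
  sim <- simulateMassSeries(gminRef = 5, initialStomatalG = 150,
                            closureTau = 600, duration = 18000, dt = 300,
                            noiseSdMass = 0, temps = 25, seed = 1)
  s <- sim$series[[1]]
  win <- detectSteadyState(s, relTol = 0.05)
  expect_gt(s@times[win[1]], 5 * 600)
  expect_gte(win[2] - win[1] + 1, 5)
  # monotone curvature throughout with a tight tolerance: no steady state
  expo <- mkSeries(2 * exp(-(0:39) / 10))
  expect_error(detectSteadyState(expo, relTol = 1e-4), "no steady state")
})

test_that("transpiration rate converts a mass slope to a molar flux", {
  # 0.0018 g over 600 s on 0.01 m^2: R = 0.0018/18.015*1000/600/0.01
  t <- seq(0, 600, by = 60)
  m <- 1.5 - t / 600 * 0.0018
  s <- newMassSeries(t, m, 25, 40, 0.5, 10)
  r <- transpirationRate(s, c(1, length(t)), area = 0.01)
  expect_equal(r, 0.0018 / 18.015 * 1000 / 600 / 0.01, tolerance = 1e-9)
  expect_equal(r, 0.016653, tolerance = 1e-4)
  flat <- newMassSeries(t, rep(1.5, length(t)), 25, 40, 0.5, 10)
  expect_warning(r0 <- transpirationRate(flat, c(1, length(t)), 0.01),
                 "non-negative")
  expect_equal(r0, 0)
})

test_that("the conductance equation g = R / VPD * 101.6 is applied", {
  # construct a series whose steady mass slope implies a known R
  area <- 0.02  # double-sided, from dry mass 1 g at SLA 10
  vpd <- vaporPressureDeficit(25, 50)
  t <- seq(0, 9000, by = 300)
  slope <- -2e-6  # g/s
  s <- newMassSeries(t, 1.5 + slope * t, 25, 50, 1, 10)
  cp <- gminAtTemperature(s)
  rExp <- (-slope) / 18.015 * 1000 / area
  expect_equal(cp@rFlux, rExp, tolerance = 1e-9)
  expect_equal(gmin(cp), rExp / vpd * 101.6, tolerance = 1e-9)
  # identity point of the formula: when VPD == P_atm, g equals R
  expect_equal(0.05 / 1.583 * 101.6, 3.209, tolerance = 1e-3)
})

test_that("noiseless drydowns invert to the true conductance", {
  sim <- simulateMassSeries(noiseSdMass = 0, initialStomatalG = 60,
                            closureTau = 600, duration = 30000, dt = 300,
                            seed = 1)
  for (nm in names(sim$series)) {
    cp <- gminAtTemperature(sim$series[[nm]], relTol = 0.02)
    relErr <- abs(gmin(cp) - sim$truth$gminByT[[nm]]) /
      sim$truth$gminByT[[nm]]
    expect_lt(relErr, 1e-3)
  }
  # with 0.5 mg noise the estimate stays within 5%
  noisy <- simulateMassSeries(noiseSdMass = 5e-4, seed = 2)
  for (nm in names(noisy$series)) {
    cp <- gminAtTemperature(noisy$series[[nm]])
    relErr <- abs(gmin(cp) - noisy$truth$gminByT[[nm]]) /
      noisy$truth$gminByT[[nm]]
    expect_lt(relErr, 0.05)
  }
})

test_that("breakpoint fitting recovers an exact two-segment model", {
  temps <- c(25, 28, 32, 36, 40, 44, 48)
  g <- gminTemperatureModel(temps, gminRef = 5, slopeBelow = 0,
                            slopeAbove = 0.5, tp = 36)
  fit <- fitBreakpoint(data.frame(temperature = temps, gmin = g))
  expect_equal(phaseTransition(fit), 36, tolerance = 0.05)
  expect_equal(fit@slopes, c(0, 0.5), tolerance = 1e-6)
  # nesting: the segmented SSE cannot exceed the single-line SSE
  gn <- g + c(0.1, -0.05, 0.02, -0.1, 0.07, 0.05, -0.02)
  fitN <- fitBreakpoint(data.frame(temperature = temps, gmin = gn))
  sseLine <- sum(lm(gn ~ temps)$residuals^2)
  expect_lte(fitN@sse, sseLine + 1e-12)
  # globally linear data leave the breakpoint unidentifiable
  expect_error(
    fitBreakpoint(data.frame(temperature = temps, gmin = 1 + 0.2 * temps)),
    "not identifiable")
  expect_error(
    fitBreakpoint(data.frame(temperature = temps[1:4], gmin = g[1:4])),
    "at least 5")
})

test_that("species T_P comes from the mean curve across replicates", {
  temps <- c(25, 28, 32, 36, 40, 44, 48)
  g <- gminTemperatureModel(temps, gminRef = 5, slopeBelow = 0.02,
                            slopeAbove = 0.6, tp = 36)
  df <- rbind(data.frame(temperature = temps, gmin = g + 0.2,
                         replicate = 1),
              data.frame(temperature = temps, gmin = g - 0.2,
                         replicate = 2))
  fit <- speciesTp(df)
  expect_equal(phaseTransition(fit), 36, tolerance = 0.05)
  perRep <- speciesTp(df, perReplicate = TRUE)
  expect_length(perRep, 2)
  expect_equal(phaseTransition(perRep[[1]]), 36, tolerance = 0.05)
})
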