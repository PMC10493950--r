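## Simulator for the optical vulnerability stage: a time-lapse stack of a
## dehydrating leaf in which cavitation events appear as bright connected
## patches whose cumulative area follows a logistic vulnerability curve with
## known P50, plus Gaussian sensor noise and single-pixel "shrinkage"
## flickers that the noise filter must remove.

#' Logistic vulnerability curve
#'
#' Cumulative percent embolized area as a function of water potential:
#' `F(psi) = 100 / (1 + exp(slope/25 * (psi - p50)))`. `F` increases as psi
#' declines and `F(p50) = 50`; `slope` is the rate of embolism accumulation
#' at the midpoint in percent per MPa.
#'
#' @param psi numeric, water potential (MPa).
#' @param p50 numeric, water potential at 50% embolism (MPa, negative).
#' @param slope numeric > 0, midpoint slope (% per MPa).
#' @return Cumulative embolized percent in `(0, 100)`.
#' @export
logisticVC <- function(psi, p50, slope = 60) {
  100 / (1 + exp(slope / 25 * (psi - p50)))
}

# Inverse of logisticVC: psi at a given cumulative percent.
logisticVCinv <- function(percent, p50, slope = 60) {
  p50 + (25 / slope) * log(100 / percent - 1)
}

# Grow a connected blob of `size` pixels among allowed pixels, starting from
# a random allowed seed; 8-connectivity by construction. Returns linear
# indices, or NULL when no seed is available.
growBlob <- function(allowed, size, nr, nc) {
  seedPool <- which(allowed)
  if (!length(seedPool)) return(NULL)
  seedPx <- seedPool[sample.int(length(seedPool), 1L)]
  blob <- seedPx
  allowed[seedPx] <- FALSE
  frontier <- seedPx
  while (length(blob) < size) {
    cand <- integer(0)
    for (p in frontier) {
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      for (dr in -1L:1L) for (dc in -1L:1L) {
        r2 <- r + dr; c2 <- cc + dc
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        q <- (c2 - 1L) * nr + r2
        if (allowed[q]) cand <- c(cand, q)
      }
    }
    cand <- unique(cand)
    if (!length(cand)) break
    take <- cand[sample.int(length(cand), min(length(cand),
                                              size - length(blob)))]
    allowed[take] <- FALSE
    blob <- c(blob, take)
    frontier <- take
  }
  blob
}

# Dilate a set of linear indices by one pixel (8-neighbourhood).
dilateIdx <- function(idx, nr, nc) {
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  out <- integer(0)
  for (dr in -1L:1L) for (dc in -1L:1L) {
    r2 <- r + dr; c2 <- cc + dc
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    out <- c(out, (c2[ok] - 1L) * nr + r2[ok])
  }
  unique(out)
}

#' Simulate a drydown image stack with known P50
#'
#' Builds a grayscale stack in which water potential declines linearly in
#' time from `psiStart` to `psiEnd` across frames. A pool of "embolizable"
#' pixels is partitioned into `nEvents` connected patches; each patch turns
#' bright at the frame where psi first crosses its threshold, chosen so the
#' cumulative bright fraction against psi follows [logisticVC()] with the
#' given `p50` and `slopeVc`, and stays bright in all later frames. Gaussian
#' intensity noise (sd `noiseSd`) is added everywhere, and `shrinkEvents`
#' single-pixel one-frame flickers emulate leaf-shrinkage artifacts (below
#' any sensible minimum event area, so [filterNoise()] removes them).
#' Frames are captured every 3 simulated minutes; the psychrometer trace is
#' sampled every 10 minutes.
#'
#' @param p50 numeric, true P50 (MPa); must satisfy
#'   `psiEnd < p50 < psiStart`.
#' @param slopeVc numeric > 0, midpoint slope of the vulnerability curve
#'   (% per MPa).
#' @param height,width integer, frame size in pixels.
#' @param nFrames integer >= 20.
#' @param psiStart,psiEnd numeric, water potential at the first and last
#'   frame (MPa, `psiStart <= 0`).
#' @param noiseSd numeric >= 0, Gaussian intensity noise sd (intensity units
#'   on the `[0, 1]` scale).
#' @param shrinkEvents integer >= 0, number of single-pixel flickers.
#' @param nEvents integer, number of cavitation events.
#' @param sizeRange integer length-2, min and max event area (px).
#' @param amplitude numeric, intensity step of an event.
#' @param background numeric, baseline intensity.
#' @param seed integer, RNG seed.
#' @return list with `stack` ([ImageStack-class]), `trace`
#'   ([PsiTrace-class]), and `truth` (list: `p50`, `slopeVc`, `psiPerFrame`,
#'   `eventLog` data.frame of `frame`/`px`, `totalPx`).
#' @examples
#' sim <- simulateDrydownImages(p50 = -4.5, height = 48, width = 48,
#'                              nFrames = 40, noiseSd = 0, shrinkEvents = 0,
#'                              nEvents = 12, seed = 1)
#' sim$stack
#' @export
simulateDrydownImages <- function(p50, slopeVc = 60, height = 128,
                                  width = 128, nFrames = 200,
                                  psiStart = -0.5, psiEnd = -8,
                                  noiseSd = 0.02, shrinkEvents = 20,
                                  nEvents = 60, sizeRange = c(6L, 40L),
                                  amplitude = 0.35, background = 0.2,
                                  seed = 1) {
  stopIfNot(psiStart <= 0, "psiStart must be <= 0")
  stopIfNot(psiEnd < p50 && p50 < psiStart,
            "p50 must lie strictly between psiEnd and psiStart")
  stopIfNot(nFrames >= 20, "nFrames must be >= 20")
  stopIfNot(noiseSd >= 0, "noiseSd must be >= 0")
  nr <- as.integer(height); nc <- as.integer(width)
  nFrames <- as.integer(nFrames)
  frameDt <- 180; traceDt <- 600
  times <- (seq_len(nFrames) - 1) * frameDt
  psiFrame <- psiStart + (psiEnd - psiStart) * times / max(times)

  withSeed(seed, {
    sizes <- sample(seq.int(sizeRange[1], sizeRange[2]), nEvents,
                    replace = TRUE)
    ## place non-overlapping, non-adjacent blobs
    blocked <- matrix(FALSE, nr, nc)
    blobs <- vector("list", nEvents)
    minBlob <- max(4L, sizeRange[1])
    for (k in seq_len(nEvents)) {
      b <- NULL
      for (attempt in 1:25) {
        b <- growBlob(!blocked, sizes[k], nr, nc)
        if (!is.null(b) && length(b) >= minBlob) break
        b <- NULL
      }
      if (is.null(b))
        stop("frame too crowded to place all events; reduce nEvents or sizes",
             call. = FALSE)
      blobs[[k]] <- b
      blocked[dilateIdx(b, nr, nc)] <- TRUE
    }
    sizes <- lengths(blobs)
    ## event psi thresholds from the logistic inverse at the midpoint of
    ## each event's cumulative-area interval
    cum <- cumsum(sizes)
    total <- cum[nEvents]
    fMid <- 100 * (cum - sizes / 2) / total
    psiThresh <- logisticVCinv(fMid, p50, slopeVc)
    eventFrame <- vapply(psiThresh, function(pk) {
      j <- which(psiFrame <= pk)
      if (!length(j)) nFrames else max(2L, min(j))
    }, integer(1))

    ## assemble the stack
    stack <- array(background, dim = c(nr, nc, nFrames))
    if (noiseSd > 0)
      stack <- stack + array(rnorm(nr * nc * nFrames, sd = noiseSd),
                             dim = c(nr, nc, nFrames))
    planeOffset <- (seq_len(nFrames) - 1L) * (nr * nc)
    for (k in seq_len(nEvents)) {
      for (j in seq.int(eventFrame[k], nFrames))
        stack[blobs[[k]] + planeOffset[j]] <-
          stack[blobs[[k]] + planeOffset[j]] + amplitude
    }
    ## single-pixel one-frame flickers, kept clear of real events
    if (shrinkEvents > 0) {
      freePool <- which(!blocked)
      if (length(freePool) < shrinkEvents)
        stop("no room for shrink flickers", call. = FALSE)
      px <- sample(freePool, shrinkEvents)
      fr <- sample(seq.int(2L, nFrames - 1L), shrinkEvents, replace = TRUE)
      for (k in seq_len(shrinkEvents))
        stack[px[k] + planeOffset[fr[k]]] <-
          stack[px[k] + planeOffset[fr[k]]] + amplitude
    }

    traceTimes <- unique(c(seq(0, max(times), by = traceDt), max(times)))
    tracePsi <- psiStart + (psiEnd - psiStart) * traceTimes / max(times)
    log <- data.frame(frame = eventFrame, px = sizes)
    log <- log[order(log$frame), , drop = FALSE]
    list(stack = newImageStack(stack, times),
         trace = newPsiTrace(traceTimes, tracePsi),
         truth = list(p50 = p50, slopeVc = slopeVc, psiPerFrame = psiFrame,
                      eventLog = log, totalPx = total))
  })
}
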