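## Run configuration: defaults, validation (range checks, unknown-key
## rejection) and a reproducible config hash.

#' Default pipeline configuration
#'
#' The full default configuration for [runPipeline()], as a nested list.
#' Every parameter block corresponds to one pipeline stage; see the methods
#' vignette for the rationale behind each default.
#'
#' @return Nested list of defaults.
#' @export
defaultConfig <- function() {
  list(
    seed = 1,
    simulate = TRUE,
    outDir = NULL,
    verbose = FALSE,
    nSpecies = 14,
    inputs = list(tree = NULL, table = NULL),
    optical = list(
      nReplicates = 2, height = 64, width = 64, nFrames = 120,
      psiStart = -0.5, psiEnd = -8, noiseSd = 0.02, shrinkEvents = 10,
      nEvents = 40, sizeRange = c(4, 16), slopeVc = 60,
      diffThreshold = 0.15, minEventPx = 4),
    conductance = list(
      temps = c(25, 28, 32, 36, 40, 44, 48), nReplicates = 2, rh = 40,
      leafArea = 0.01, sla = 10, noiseSdMass = 5e-4, initialStomatalG = 60,
      closureTau = 900, duration = 10800, dt = 300, window = 5,
      relTol = 0.15, patm = 101.6, doubleSided = TRUE,
      slopeBelow = 0.05, slopeAbove = 0.6),
    traits = list(
      p50Beta = c(-4.8, 0.25, 0.2), gminBeta = c(6.5, -0.8, 0.5),
      tpBeta = c(36, 0.2, 0), lambdaResid = 0.2,
      sigma2p50 = 0.09, sigma2gmin = 0.16, sigma2tp = 0.25,
      outlier = TRUE, outlierDelta = -4),
    comparative = list(nPerm = 199, cooksCutoff = NULL)
  )
}

# Merge user values into defaults, rejecting unknown keys, recursively.
mergeConfig <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop("unknown config key: ", full, call. = FALSE)
    if (is.list(defaults[[key]]) && !is.null(user[[key]])) {
      if (!is.list(user[[key]]))
        stop("config key ", full, " must be a block", call. = FALSE)
      defaults[[key]] <- mergeConfig(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

checkRange <- function(value, key, lo = -Inf, hi = Inf, loOpen = FALSE,
                       hiOpen = FALSE) {
  bad <- if (loOpen) any(value <= lo) else any(value < lo)
  bad <- bad || if (hiOpen) any(value >= hi) else any(value > hi)
  if (bad)
    stop(sprintf("config key %s out of range %s%g, %g%s", key,
                 if (loOpen) "(" else "[", lo, hi,
                 if (hiOpen) ")" else "]"), call. = FALSE)
  invisible(value)
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a nested list, fills in all defaults,
#' rejects unknown keys, and range-checks every parameter. Referenced input
#' paths must exist when `simulate` is `FALSE`.
#'
#' @param config a YAML file path, a nested list, or `NULL` for the
#'   defaults.
#' @return The fully-defaulted, validated configuration (a list with class
#'   `"hydrophyloConfig"` and a `hash` attribute).
#' @export
validateConfig <- function(config = NULL) {
  user <- if (is.null(config)) list()
          else if (is.character(config)) {
            stopIfNot(file.exists(config),
                      paste0("config file not found: ", config))
            yaml::read_yaml(config)
          } else if (is.list(config)) config
          else stop("config must be a path, a list, or NULL", call. = FALSE)
  cfg <- mergeConfig(defaultConfig(), user)
  checkRange(cfg$seed, "seed", lo = 0)
  checkRange(cfg$nSpecies, "nSpecies", lo = 3)
  op <- cfg$optical
  checkRange(op$nFrames, "optical.nFrames", lo = 20)
  checkRange(op$noiseSd, "optical.noiseSd", lo = 0)
  if (!(op$psiEnd < op$psiStart && op$psiStart <= 0))
    stop("config: optical.psiEnd < optical.psiStart <= 0 required",
         call. = FALSE)
  checkRange(op$diffThreshold, "optical.diffThreshold", lo = 0,
             loOpen = TRUE)
  checkRange(op$minEventPx, "optical.minEventPx", lo = 1)
  co <- cfg$conductance
  checkRange(co$rh, "conductance.rh", lo = 0, hi = 100, hiOpen = TRUE)
  checkRange(co$temps, "conductance.temps", lo = 0, hi = 60,
             loOpen = TRUE, hiOpen = TRUE)
  checkRange(co$leafArea, "conductance.leafArea", lo = 0, loOpen = TRUE)
  checkRange(co$noiseSdMass, "conductance.noiseSdMass", lo = 0)
  checkRange(co$window, "conductance.window", lo = 3)
  if (co$duration / co$dt < 30)
    stop("config: conductance.duration/dt must be >= 30 points",
         call. = FALSE)
  tr <- cfg$traits
  checkRange(tr$lambdaResid, "traits.lambdaResid", lo = 0, hi = 1)
  checkRange(cfg$comparative$nPerm, "comparative.nPerm", lo = 99)
  if (!isTRUE(cfg$simulate)) {
    for (key in c("tree", "table")) {
      p <- cfg$inputs[[key]]
      if (is.null(p) || !file.exists(p))
        stop("config: simulate is FALSE but inputs.", key,
             " does not exist", call. = FALSE)
    }
  }
  class(cfg) <- c("hydrophyloConfig", "list")
  attr(cfg, "hash") <- configHash(cfg)
  cfg
}

#' Reproducible hash of a configuration (or any list)
#'
#' MD5 of a canonical JSON serialization; identical configurations hash
#' identically across sessions.
#'
#' @param x a list.
#' @return Character MD5 hash.
#' @export
configHash <- function(x) {
  attributes(x) <- attributes(x)["names"]
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12, null = "null")
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(js, tf)
  unname(md5sum(tf))
}
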