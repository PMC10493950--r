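## Climate PCA, Pearson correlation, Bonferroni correction, Loess smoothing.

.CLIMATE_VARS <- c("MAT", "MAP", "maxT", "minT", "Pdq")

#' Principal component analysis of climate variables
#'
#' Columns are centered and (by default) scaled to unit variance — the
#' climate variables mix units (degrees C, mm), so the correlation-matrix
#' PCA is the default. Scores, loadings and percent variance explained are
#' returned; the PC1 sign is fixed so that its loading on `minT` (when
#' present) is positive, i.e. larger PC1 means warmer/drier.
#'
#' @param x a data.frame/matrix of climate variables, or a
#'   [TraitClimateTable-class] (its recognized climate columns are used).
#' @param standardize logical, scale columns to unit variance (default TRUE).
#' @return A [ClimatePCA-class].
#' @export
climatePCA <- function(x, standardize = TRUE) {
  if (is(x, "TraitClimateTable")) {
    d <- traitData(x)
    x <- d[, intersect(.CLIMATE_VARS, names(d)), drop = FALSE]
    rownames(x) <- d$species
  }
  x <- as.matrix(x)
  stopIfNot(ncol(x) >= 2, "need at least 2 variables")
  stopIfNot(nrow(x) >= 3, "need at least 3 rows")
  stopIfNot(!anyNA(x), "missing values in climate variables")
  if (standardize) {
    zero <- colnames(x)[apply(x, 2, sd) == 0]
    if (length(zero))
      stop("zero-variance column(s) cannot be standardized: ",
           paste(zero, collapse = ", "), call. = FALSE)
  }
  pc <- prcomp(x, center = TRUE, scale. = standardize)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  load <- pc$rotation
  scores <- pc$x
  if ("minT" %in% rownames(load) && load["minT", 1] < 0) {
    load[, 1] <- -load[, 1]
    scores[, 1] <- -scores[, 1]
  }
  ctr <- pc$center
  scl <- if (standardize) pc$scale else setNames(rep(1, ncol(x)),
                                                 colnames(x))
  new("ClimatePCA", loadings = load, scores = scores, varExplained = ve,
      center = ctr, scale = scl)
}

#' Pearson correlation with a t-test
#'
#' Product-moment correlation and the two-sided p-value from the t
#' transform with `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3, non-constant.
#' @return list with `r` and `p`.
#' @export
pearsonCorrelation <- function(x, y) {
  stopIfNot(length(x) == length(y), "x and y must have equal length")
  stopIfNot(length(x) >= 3, "need at least 3 observations")
  stopIfNot(sd(x) > 0 && sd(y) > 0, "constant vector: correlation undefined")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Bonferroni correction
#'
#' `min(1, p * m)` elementwise, for a declared family of `m` tests.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param m integer, family size; must be at least `length(p)`.
#' @return Adjusted p-values.
#' @export
bonferroniAdjust <- function(p, m = length(p)) {
  stopIfNot(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  stopIfNot(m >= length(p), "family size m must be >= number of tests")
  p.adjust(p, method = "bonferroni", n = m)
}

#' Loess smooth on a grid
#'
#' Local linear regression with tricube weights (`stats::loess`,
#' `degree = 1`, direct surface so spans above 1 use all points with
#' distances scaled by the enlarged bandwidth). A high span (e.g. the 1.5
#' default) gives a near-global smooth useful for visualizing a broad
#' trend such as a parabolic trait-climate relationship.
#'
#' @param x,y numeric vectors, `length >= 4`.
#' @param span numeric > 0, smoothing span (fraction of points; values
#'   above 1 increase the bandwidth beyond the data range).
#' @param gridN integer, number of grid points for the fitted curve.
#' @return data.frame with columns `x` and `fitted`.
#' @export
loessSmooth <- function(x, y, span = 1.5, gridN = 100L) {
  stopIfNot(length(x) == length(y), "x and y must have equal length")
  stopIfNot(length(x) >= 4, "need at least 4 points")
  stopIfNot(span > 0, "span must be > 0")
  if (ceiling(span * length(x)) < 3 && span <= 1)
    stop("bandwidth too narrow: fewer than 3 points per local window",
         call. = FALSE)
  fit <- loess(y ~ x, span = span, degree = 1, family = "gaussian",
               control = loess.control(surface = "direct"))
  grid <- seq(min(x), max(x), length.out = gridN)
  data.frame(x = grid, fitted = as.numeric(predict(fit, newdata =
    data.frame(x = grid))))
}
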