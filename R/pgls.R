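## Phylogenetic generalized least squares with ML (or fixed) lambda,
## GLS R-squared and Cook's distance on the whitened regression.

# GLS quantities at a fixed lambda: coefficients, residuals, RSS, profile
# log-likelihood. X and y are in tip order matching V1's dimnames.
glsAtLambda <- function(V1, dV, y, X, lam) {
  V <- V1 * lam
  diag(V) <- dV
  R <- chol(V)
  logdet <- 2 * sum(log(diag(R)))
  ## whiten: t(R)^-1 has cov I
  ys <- forwardsolve(t(R), y)
  Xs <- forwardsolve(t(R), X)
  qrX <- qr(Xs)
  if (qrX$rank < ncol(Xs)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(Xs)]]
    stop("singular design: collinear column(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, ys)
  rs <- ys - Xs %*% beta
  rss <- sum(rs^2)
  n <- length(y)
  sigma2 <- rss / n
  ll <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  list(beta = beta, rss = rss, loglik = ll, R = R, ys = ys, Xs = Xs,
       qrX = qrX, resWhite = drop(rs))
}

#' Phylogenetic generalized least squares
#'
#' Fits `response ~ predictors` by GLS with residual covariance
#' `sigma2 * V(lambda)`, where V is the Brownian covariance of the tree and
#' `lambda` scales its off-diagonal entries. `lambda` is estimated by
#' maximum likelihood over `[0, 1]` (profile likelihood, the same one as
#' [pagelLambda()] but with the regression mean structure) unless a fixed
#' value is supplied. Coefficient standard errors use
#' `sigma_hat^2 (X' V^-1 X)^-1` with `sigma_hat^2 = RSS_V / (n - p)`;
#' p-values are two-sided t with `n - p` df. The reported R-squared is
#' GLS-based: `1 - RSS_V / TSS_V`, with TSS from the GLS intercept-only fit
#' under the same `V(lambda)`. Cook's distances are computed on the
#' whitened regression (y and X premultiplied by `V(lambda)^(-1/2)`), which
#' reduces to the textbook OLS formula at `lambda = 0`.
#'
#' @param formula a model formula, e.g. `gmin ~ pc1 + subgenus`.
#'   Interaction terms are supported.
#' @param data a [TraitClimateTable-class] or a data.frame with a `species`
#'   column matching the tree's tip labels.
#' @param tree a rooted `ape::phylo` tree. Species present in only one of
#'   tree and table are dropped jointly with a warning.
#' @param lambda `"ML"` (default) or a fixed numeric in `[0, 1]`.
#' @return A [PGLSResult-class].
#' @export
pglsFit <- function(formula, data, tree, lambda = "ML") {
  cl <- match.call()
  d <- if (is(data, "TraitClimateTable")) traitData(data) else data
  stopIfNot("species" %in% names(d), "data needs a 'species' column")
  common <- intersect(tree$tip.label, d$species)
  respName <- all.vars(formula)[1]
  dComplete <- d[stats::complete.cases(d[, all.vars(formula), drop = FALSE]), ]
  dropped <- setdiff(union(tree$tip.label, d$species),
                     intersect(common, dComplete$species))
  common <- intersect(common, dComplete$species)
  stopIfNot(length(common) >= 3, "fewer than 3 species shared by tree and data")
  if (length(dropped))
    warning(sprintf("dropped %d species not shared (or with missing data): %s",
                    length(dropped), paste(dropped, collapse = ", ")),
            call. = FALSE)
  tr <- if (length(common) < ape::Ntip(tree))
    ape::drop.tip(tree, setdiff(tree$tip.label, common)) else tree
  d <- dComplete[match(tr$tip.label, dComplete$species), , drop = FALSE]

  mf <- stats::model.frame(formula, data = d)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, data = mf)
  n <- nrow(X); p <- ncol(X)
  stopIfNot(n > p, "need more species than parameters")
  V1 <- phyloCovariance(tr, 1)
  dV <- diag(V1)

  if (identical(lambda, "ML")) {
    prof <- function(lam) glsAtLambda(V1, dV, y, X, lam)$loglik
    opt <- optimize(prof, interval = c(0, 1), maximum = TRUE, tol = 1e-6)
    cand <- c(opt$maximum, 0, 1)
    lls <- c(opt$objective, prof(0), prof(1))
    lamUsed <- cand[which.max(lls)]
  } else {
    stopIfNot(is.numeric(lambda) && lambda >= 0 && lambda <= 1,
              "lambda must be 'ML' or a number in [0, 1]")
    lamUsed <- lambda
  }

  g <- glsAtLambda(V1, dV, y, X, lamUsed)
  beta <- g$beta
  s2 <- g$rss / (n - p)
  XtViX_inv <- chol2inv(qr.R(g$qrX))
  se <- sqrt(diag(XtViX_inv) * s2)
  tv <- beta / se
  pv <- 2 * pt(abs(tv), df = n - p, lower.tail = FALSE)

  ## GLS R^2 against the intercept-only fit under the same V(lambda)
  g0 <- glsAtLambda(V1, dV, y, matrix(1, n, 1,
                                      dimnames = list(NULL, "(Intercept)")),
                    lamUsed)
  r2 <- 1 - g$rss / g0$rss

  ## Cook's distance on the whitened regression
  Q <- qr.Q(g$qrX)
  h <- rowSums(Q^2)
  rw <- g$resWhite
  cooks <- ifelse(h >= 1 - 1e-12, Inf,
                  rw^2 * h / (p * s2 * (1 - h)^2))
  names(cooks) <- tr$tip.label
  resRaw <- drop(y - X %*% beta)
  names(resRaw) <- tr$tip.label

  new("PGLSResult", call = cl, coefficients = setNames(beta, colnames(X)),
      se = setNames(se, colnames(X)), tValues = setNames(tv, colnames(X)),
      pValues = setNames(pv, colnames(X)), lambdaUsed = lamUsed,
      logLik = g$loglik, rSquared = r2, residuals = resRaw, cooksD = cooks,
      n = as.integer(n), df = as.integer(n - p), terms = colnames(X))
}

#' Flag influential species from a PGLS fit
#'
#' Species whose Cook's distance exceeds the cutoff (default the common
#' `4 / n` rule) are flagged as candidate outliers.
#'
#' @param fit a [PGLSResult-class].
#' @param cutoff numeric; `NULL` uses `4 / n`.
#' @return Character vector of flagged species (possibly empty), ordered by
#'   decreasing influence.
#' @export
influentialSpecies <- function(fit, cutoff = NULL) {
  stopIfNot(is(fit, "PGLSResult"), "fit must be a PGLSResult")
  if (is.null(cutoff)) cutoff <- 4 / fit@n
  d <- sort(fit@cooksD[fit@cooksD > cutoff], decreasing = TRUE)
  names(d)
}
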