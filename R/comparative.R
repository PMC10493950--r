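## Phylogenetic signal statistics: the lambda-scaled phylogenetic covariance
## matrix, Blomberg's K with a tip-permutation test, and Pagel's lambda by
## profile maximum likelihood with a likelihood-ratio test.

#' Lambda-scaled phylogenetic covariance matrix
#'
#' `V[i, j]` is the shared root-to-MRCA path length of tips i and j,
#' multiplied by `lambda` off the diagonal; `V[i, i]` is the root-to-tip
#' path length. `lambda = 1` is the Brownian-motion covariance, `lambda = 0`
#' is diagonal.
#'
#' @param tree a rooted `ape::phylo` tree with branch lengths.
#' @param lambda numeric in `[0, 1]`.
#' @return Symmetric positive semi-definite matrix with tip-label dimnames.
#' @export
phyloCovariance <- function(tree, lambda = 1) {
  stopIfNot(inherits(tree, "phylo"), "tree must be an ape phylo object")
  ## a star tree (one internal node) is rooted by construction even though
  ## its basal polytomy makes ape::is.rooted() report otherwise
  stopIfNot(ape::is.rooted(tree) || tree$Nnode == 1L,
            "tree must be rooted")
  stopIfNot(lambda >= 0 && lambda <= 1, "lambda must lie in [0, 1]")
  V <- ape::vcv(tree)
  if (lambda != 1) {
    d <- diag(V)
    V <- V * lambda
    diag(V) <- d
  }
  V
}

# Match a named trait vector to the tips of a tree; errors on missing tips.
matchTrait <- function(tree, trait) {
  stopIfNot(!is.null(names(trait)), "trait must be named by tip label")
  missing <- setdiff(tree$tip.label, names(trait))
  stopIfNot(length(missing) == 0,
            paste("trait missing for tips:", paste(missing, collapse = ", ")))
  trait[tree$tip.label]
}

# Precompute the V-derived quantities K needs, so the permutation test can
# re-evaluate K cheaply for many trait vectors.
blombergKPrep <- function(tree) {
  V <- phyloCovariance(tree, 1)
  Vi <- solve(V)
  one <- rep(1, nrow(V))
  Vi1 <- Vi %*% one
  sumVi <- sum(Vi)
  expected <- (sum(diag(V)) - nrow(V) / sumVi) / (nrow(V) - 1)
  list(Vi = Vi, Vi1 = Vi1, sumVi = sumVi, expected = expected,
       n = nrow(V), tips = rownames(V))
}

# K for one or many trait vectors (columns of y) under a prepared tree.
blombergKCore <- function(prep, y) {
  y <- as.matrix(y)
  ahat <- drop(crossprod(prep$Vi1, y)) / prep$sumVi
  r <- sweep(y, 2, ahat, `-`)
  mse0 <- colSums(r * r)
  mse <- colSums(r * (prep$Vi %*% r))
  (mse0 / mse) / prep$expected
}

#' Blomberg's K
#'
#' The ratio of the observed mean squared error of the tip data (around the
#' phylogenetically corrected mean) to the phylogenetically expected mean
#' squared error, standardized by its Brownian-motion expectation:
#' `K = (MSE0 / MSE) / E[MSE0 / MSE]` with
#' `a_hat = (1' V^-1 1)^-1 1' V^-1 y`,
#' `MSE0 = (y - a_hat)'(y - a_hat) / (n - 1)`,
#' `MSE = (y - a_hat)' V^-1 (y - a_hat) / (n - 1)` and
#' `E[MSE0 / MSE] = (tr(V) - n / (1' V^-1 1)) / (n - 1)`, where V is the
#' Brownian covariance of the tree. K is about 1 under Brownian motion and
#' falls towards 0 when relatives resemble each other less than expected.
#'
#' @param tree a rooted `ape::phylo` tree.
#' @param trait named numeric vector of tip values (non-constant).
#' @return K (numeric scalar).
#' @export
blombergK <- function(tree, trait) {
  y <- matchTrait(tree, trait)
  stopIfNot(sd(y) > 0, "trait is constant: K is undefined")
  prep <- blombergKPrep(tree)
  unname(blombergKCore(prep, y))
}

#' Permutation test for Blomberg's K
#'
#' Permutes trait values across tips and compares the observed K with the
#' permutation distribution:
#' `p = (1 + #{K_perm >= K_obs}) / (nPerm + 1)`.
#'
#' @param tree a rooted `ape::phylo` tree.
#' @param trait named numeric vector of tip values.
#' @param nPerm integer >= 99, number of permutations.
#' @param seed integer, RNG seed.
#' @return list with `k` (observed K) and `p` (permutation p-value).
#' @export
signalPermutationTest <- function(tree, trait, nPerm = 999, seed = 1) {
  stopIfNot(nPerm >= 99, "nPerm must be >= 99")
  y <- matchTrait(tree, trait)
  stopIfNot(sd(y) > 0, "trait is constant: K is undefined")
  prep <- blombergKPrep(tree)
  kObs <- blombergKCore(prep, y)
  perms <- withSeed(seed,
    vapply(seq_len(nPerm), function(i) sample(y), numeric(length(y))))
  kPerm <- blombergKCore(prep, perms)
  list(k = unname(kObs), p = (1 + sum(kPerm >= kObs)) / (nPerm + 1))
}

# Profile log-likelihood of the single-mean Brownian model with covariance
# sigma2 * V(lambda); mean and sigma2 profiled out analytically.
lambdaProfileLoglik <- function(V, y) {
  n <- length(y)
  R <- chol(V)
  logdet <- 2 * sum(log(diag(R)))
  w <- backsolve(R, forwardsolve(t(R), cbind(y, rep(1, n))))
  ## w = V^-1 [y, 1]
  Viy <- w[, 1]; Vi1 <- w[, 2]
  ahat <- sum(Viy) / sum(Vi1)
  r <- y - ahat
  q <- sum(r * backsolve(R, forwardsolve(t(R), r)))
  sigma2 <- q / n
  -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
}

#' Pagel's lambda by maximum likelihood
#'
#' Profiles the log-likelihood of the single-mean Brownian model with
#' covariance `sigma2 * V(lambda)` over `lambda` in `[0, 1]` (mean and rate
#' profiled analytically; bounded scalar optimization, tolerance 1e-6) and
#' tests `lambda_hat` against `lambda = 0` with a likelihood-ratio test on
#' the chi-square(1) reference. The chi-square reference is conservative at
#' the `lambda = 0` boundary.
#'
#' @param tree a rooted `ape::phylo` tree.
#' @param trait named numeric vector of tip values (non-constant).
#' @return list with `lambda` (ML estimate), `loglik` (at the ML),
#'   `loglik0` (at lambda = 0), and `p` (LRT p-value).
#' @export
pagelLambda <- function(tree, trait) {
  y <- matchTrait(tree, trait)
  stopIfNot(sd(y) > 0, "trait is constant: lambda is undefined")
  V1 <- phyloCovariance(tree, 1)
  dV <- diag(V1)
  f <- function(lam) {
    V <- V1 * lam
    diag(V) <- dV
    lambdaProfileLoglik(V, y)
  }
  opt <- optimize(f, interval = c(0, 1), maximum = TRUE, tol = 1e-6)
  ## the optimum can sit at a boundary; check both ends explicitly
  ll0 <- f(0); ll1 <- f(1)
  cand <- c(opt$maximum, 0, 1)
  lls <- c(opt$objective, ll0, ll1)
  best <- which.max(lls)
  lamHat <- cand[best]; llHat <- lls[best]
  stat <- 2 * (llHat - ll0)
  list(lambda = lamHat, loglik = llHat, loglik0 = ll0,
       p = pchisq(max(stat, 0), df = 1, lower.tail = FALSE))
}

#' Phylogenetic signal of a trait (K and lambda together)
#'
#' Runs [blombergK()] with its permutation test and [pagelLambda()] and
#' collects both into a [PhyloSignalResult-class].
#'
#' @param tree a rooted `ape::phylo` tree.
#' @param trait named numeric vector of tip values.
#' @param nPerm integer, permutations for the K test.
#' @param seed integer, RNG seed for the permutation test.
#' @param traitName character label carried in the result.
#' @return A [PhyloSignalResult-class].
#' @export
phyloSignal <- function(tree, trait, nPerm = 999, seed = 1,
                        traitName = deparse(substitute(trait))) {
  kt <- signalPermutationTest(tree, trait, nPerm = nPerm, seed = seed)
  pl <- pagelLambda(tree, trait)
  new("PhyloSignalResult", trait = as.character(traitName)[1], k = kt$k,
      pK = kt$p, lambdaHat = pl$lambda, loglikLambda = pl$loglik,
      loglikZero = pl$loglik0, pLambda = pl$p)
}
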