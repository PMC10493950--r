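## Synthetic-data generators for the comparative stage: trees, trait values
## under lambda-scaled Brownian motion, climate tables, and trait tables tied
## to climate through a known linear model. Every generator is a pure
## function of its arguments including `seed`.

#' Simulate an ultrametric pure-birth phylogeny
#'
#' Generates a Yule (pure-birth) tree with `nTaxa` tips and rescales it so
#' the root-to-tip depth is exactly 1. Tip labels are `t1 ... tN`.
#'
#' @param nTaxa integer >= 3, number of tips.
#' @param seed integer, RNG seed.
#' @return An ultrametric `ape::phylo` tree of depth 1.
#' @examples
#' tr <- simulatePhylogeny(14, seed = 1)
#' max(ape::node.depth.edgelength(tr))  # 1
#' @export
simulatePhylogeny <- function(nTaxa, seed = 1) {
  stopIfNot(is.numeric(nTaxa) && nTaxa >= 3, "nTaxa must be >= 3")
  tr <- withSeed(seed, ape::rphylo(as.integer(nTaxa), birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- paste0("t", seq_len(as.integer(nTaxa)))
  tr
}

#' Simulate tip trait values under lambda-scaled Brownian motion
#'
#' Draws one multivariate-normal sample with mean `rootValue` and covariance
#' `sigma2 * V(lambda)`, where `V` is the shared root-to-MRCA path-length
#' matrix of the tree and `V(lambda)` multiplies its off-diagonal entries by
#' `lambda`. `lambda = 1` is plain Brownian motion; `lambda = 0` gives
#' independent tips.
#'
#' @param tree an `ape::phylo` tree.
#' @param sigma2 numeric > 0, Brownian rate (trait variance per unit depth).
#' @param rootValue numeric, trait value at the root.
#' @param lambda numeric in `[0, 1]`, Pagel's lambda of the generating model.
#' @param seed integer, RNG seed.
#' @return Named numeric vector of tip trait values.
#' @export
simulateTraitsBM <- function(tree, sigma2 = 1, rootValue = 0, lambda = 1,
                             seed = 1) {
  stopIfNot(sigma2 > 0, "sigma2 must be > 0")
  stopIfNot(lambda >= 0 && lambda <= 1, "lambda must lie in [0, 1]")
  V <- phyloCovariance(tree, lambda)
  n <- nrow(V)
  R <- tryCatch(chol(sigma2 * V), error = function(e)
    stop("V(lambda) is not positive definite: ", conditionMessage(e),
         call. = FALSE))
  z <- withSeed(seed, rnorm(n))
  y <- drop(rootValue + crossprod(R, z))
  names(y) <- rownames(V)
  y
}

#' Simulate a site climate table with a target correlation structure
#'
#' Draws `nSites` multivariate-normal rows with the given 5 x 5 correlation
#' matrix, then affinely rescales each column to realistic Tasmanian spans
#' (mean annual temperature 6-12 C, annual precipitation 600-1500 mm,
#' warmest-month maxima near 14-22 C, coldest-month minima near -3-4 C,
#' driest-quarter precipitation 120-260 mm). The affine step preserves the
#' correlation structure exactly.
#'
#' @param nSites integer, number of sites (rows).
#' @param targetCorr 5 x 5 symmetric positive-definite correlation matrix
#'   (unit diagonal) for columns `MAT`, `MAP`, `maxT`, `minT`, `Pdq`.
#' @param seed integer, RNG seed.
#' @return data.frame with columns `MAT`, `MAP`, `maxT`, `minT`, `Pdq`.
#' @export
simulateClimate <- function(nSites, targetCorr = defaultClimateCorr(),
                            seed = 1) {
  stopIfNot(nSites >= 1, "nSites must be >= 1")
  stopIfNot(is.matrix(targetCorr) && all(dim(targetCorr) == c(5L, 5L)),
            "targetCorr must be a 5 x 5 matrix")
  stopIfNot(max(abs(targetCorr - t(targetCorr))) < 1e-8,
            "targetCorr must be symmetric")
  stopIfNot(max(abs(diag(targetCorr) - 1)) < 1e-8,
            "targetCorr must have unit diagonal")
  R <- tryCatch(chol(targetCorr), error = function(e)
    stop("targetCorr is not positive definite", call. = FALSE))
  z <- withSeed(seed, matrix(rnorm(nSites * 5L), nSites, 5L)) %*% R
  centers <- c(MAT = 9, MAP = 1050, maxT = 18.5, minT = 0.9, Pdq = 190)
  spreads <- c(MAT = 1.8, MAP = 260, maxT = 2.5, minT = 2.2, Pdq = 45)
  out <- sweep(sweep(z, 2L, spreads, `*`), 2L, centers, `+`)
  colnames(out) <- names(centers)
  as.data.frame(out)
}

#' Default climate correlation matrix
#'
#' Strong co-variation of the temperature variables and anti-correlation of
#' precipitation with temperature, mimicking a coastal-to-subalpine gradient
#' where warm sites are dry. One dominant axis results, so PC1 carries most
#' of the climatic variance.
#'
#' @return 5 x 5 correlation matrix (columns `MAT`, `MAP`, `maxT`, `minT`,
#'   `Pdq`).
#' @export
defaultClimateCorr <- function() {
  nm <- c("MAT", "MAP", "maxT", "minT", "Pdq")
  C <- matrix(c(
    1.00, -0.80, 0.92, 0.90, -0.82,
   -0.80,  1.00, -0.78, -0.75, 0.92,
    0.92, -0.78,  1.00, 0.88, -0.80,
    0.90, -0.75,  0.88, 1.00, -0.78,
   -0.82,  0.92, -0.80, -0.78, 1.00), 5L, 5L,
    dimnames = list(nm, nm))
  C
}

#' Subgenus labels from the root bipartition of a tree
#'
#' Splits the tips at the root into the two descendant clades, mirroring a
#' two-subgenus sampling design. The clade containing the first tip is
#' labelled `"Symphyomyrtus"`, the other `"Eucalyptus"`.
#'
#' @param tree a rooted `ape::phylo` tree.
#' @return Named character vector of subgenus labels, one per tip.
#' @export
rootBipartition <- function(tree) {
  stopIfNot(ape::is.rooted(tree), "tree must be rooted")
  root <- ape::Ntip(tree) + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  tipsOf <- function(node) {
    if (node <= ape::Ntip(tree)) return(node)
    unlist(lapply(tree$edge[tree$edge[, 1] == node, 2], tipsOf))
  }
  cladeA <- tipsOf(kids[1])
  lab <- rep("Eucalyptus", ape::Ntip(tree))
  lab[cladeA] <- "Symphyomyrtus"
  if (!(1L %in% cladeA)) lab <- ifelse(lab == "Eucalyptus",
                                       "Symphyomyrtus", "Eucalyptus")
  names(lab) <- tree$tip.label
  lab
}

#' Simulate a trait-climate table with known regression coefficients
#'
#' Generates a species trait as `X beta + eps` where the design `X` holds an
#' intercept, PC1 of the climate table, and a binary subgenus indicator
#' (1 for subgenus Eucalyptus) assigned by splitting the tree at its root;
#' `eps ~ N(0, sigma2 * V(lambdaResid))`. This is the generating model that
#' [pglsFit()] should recover.
#'
#' @param tree an `ape::phylo` tree; one climate row per tip.
#' @param climate data.frame of climate variables (one row per tip, in tip
#'   order), as from [simulateClimate()].
#' @param beta numeric length-3: intercept, PC1 slope, subgenus offset.
#' @param lambdaResid numeric in `[0, 1]`, residual phylogenetic signal.
#' @param sigma2 numeric >= 0, residual variance.
#' @param seed integer, RNG seed.
#' @param traitName character, column name for the trait.
#' @return list with `table` (a [TraitClimateTable-class] including columns
#'   `pc1` and the trait) and `truth` (list: `beta`, `lambdaResid`,
#'   `sigma2`, `pc1`, `subgenusIndicator`).
#' @export
simulateTraitClimate <- function(tree, climate, beta = c(0, -1, 0.5),
                                 lambdaResid = 0.5, sigma2 = 0.25, seed = 1,
                                 traitName = "trait") {
  stopIfNot(nrow(climate) == ape::Ntip(tree),
            "climate must have one row per tip")
  stopIfNot(lambdaResid >= 0 && lambdaResid <= 1,
            "lambdaResid must lie in [0, 1]")
  stopIfNot(length(beta) == 3L, "beta must have length 3")
  pca <- climatePCA(climate, standardize = TRUE)
  pc1 <- pcaScores(pca)[, 1]
  subg <- rootBipartition(tree)
  ind <- as.numeric(subg == "Eucalyptus")
  X <- cbind(1, pc1, ind)
  mu <- drop(X %*% beta)
  eps <- if (sigma2 > 0)
    simulateTraitsBM(tree, sigma2 = sigma2, rootValue = 0,
                     lambda = lambdaResid, seed = seed)
  else setNames(numeric(ape::Ntip(tree)), tree$tip.label)
  trait <- mu + eps[tree$tip.label]
  d <- data.frame(species = tree$tip.label, subgenus = unname(subg),
                  pc1 = pc1, stringsAsFactors = FALSE)
  d[[traitName]] <- unname(trait)
  d <- cbind(d, climate)
  list(table = newTraitClimateTable(d),
       truth = list(beta = beta, lambdaResid = lambdaResid, sigma2 = sigma2,
                    pc1 = pc1, subgenusIndicator = ind))
}
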