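# Independent oracles used across tests. Each re-derives a quantity by a
# different route than the package implementation.

# Brute-force phylogenetic covariance: for every tip pair, the shared
# root-to-MRCA path length by explicit root-path enumeration.
bruteForceVCV <- function(tree) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  pathTo <- function(tip) {
    nodes <- integer(0)
    v <- tip
    while (v != root) {
      nodes <- c(nodes, v)
      v <- parent[v]
    }
    nodes
  }
  paths <- lapply(seq_len(n), pathTo)
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    shared <- intersect(paths[[i]], paths[[j]])
    V[i, j] <- sum(elen[shared])
  }
  V
}

# Textbook GLS by explicit matrix inversion.
bruteForceGLS <- function(X, y, V) {
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  drop(beta)
}

# Direct evaluation of the K formula, written independently of the package
# internals (explicit inverses, no shared helpers).
bruteForceK <- function(tree, y) {
  V <- bruteForceVCV(tree)
  y <- y[tree$tip.label]
  n <- length(y)
  Vi <- solve(V)
  one <- rep(1, n)
  ahat <- drop((t(one) %*% Vi %*% y) / (t(one) %*% Vi %*% one))
  r <- y - ahat
  mse0 <- sum(r^2) / (n - 1)
  mse <- drop(t(r) %*% Vi %*% r) / (n - 1)
  expect <- (sum(diag(V)) - n / sum(Vi)) / (n - 1)
  (mse0 / mse) / expect
}

# Brute-force connected component sizes under 8-connectivity: repeated
# dilation-style flood fill over a pixel coordinate list.
bruteForceComponentSizes <- function(mask) {
  coords <- which(mask, arr.ind = TRUE)
  if (nrow(coords) == 0L) return(integer(0))
  unassigned <- rep(TRUE, nrow(coords))
  sizes <- integer(0)
  adjacent <- function(a, b) max(abs(a - b)) <= 1L
  while (any(unassigned)) {
    comp <- which(unassigned)[1]
    unassigned[comp] <- FALSE
    repeat {
      added <- FALSE
      for (i in which(unassigned)) {
        if (any(vapply(comp, function(j)
          adjacent(coords[i, ], coords[j, ]), TRUE))) {
          comp <- c(comp, i)
          unassigned[i] <- FALSE
          added <- TRUE
        }
      }
      if (!added) break
    }
    sizes <- c(sizes, length(comp))
  }
  sizes
}

# A fixed, hand-specified 4-taxon tree for exact-value tests.
fixedQuartet <- function() {
  ape::read.tree(text = "((A:0.3,B:0.3):0.7,(C:0.6,D:0.6):0.4);")
}
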