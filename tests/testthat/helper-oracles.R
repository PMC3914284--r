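# Independent oracles, coded without reference to the package internals.

# AUC by exhaustive pair enumeration: (concordant + 0.5 ties) / (n1 * n0).
aucOracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  num <- 0
  for (a in pos) for (b in neg)
    num <- num + if (a > b) 1 else if (a == b) 0.5 else 0
  num / (length(pos) * length(neg))
}

# Brute-force re-implementation of the greedy colinearity rule: repeatedly
# locate the highest offending pair (lexicographically smallest on ties),
# drop the member with the larger mean |corr| over the other survivors
# (lower index on exact tie).
colinearityOracle <- function(corr, cutoff) {
  keep <- seq_len(ncol(corr))
  removedSet <- integer()
  repeat {
    bestVal <- -Inf
    bestPair <- NULL
    for (ii in seq_along(keep)) {
      for (jj in seq_along(keep)) {
        if (ii >= jj) next
        v <- corr[keep[ii], keep[jj]]
        if (v > cutoff && v > bestVal) {
          bestVal <- v
          bestPair <- c(keep[ii], keep[jj])
        }
      }
    }
    if (is.null(bestPair)) break
    others <- function(i) keep[keep != i]
    ma <- mean(corr[bestPair[1], others(bestPair[1])])
    mb <- mean(corr[bestPair[2], others(bestPair[2])])
    victim <- if (ma > mb) bestPair[1]
              else if (mb > ma) bestPair[2]
              else min(bestPair)
    keep <- keep[keep != victim]
    removedSet <- c(removedSet, victim)
  }
  list(removed = sort(removedSet), kept = keep)
}

# Random absolute-correlation matrix of size p.
randomAbsCorr <- function(p, seed) {
  set.seed(seed)
  a <- matrix(rnorm(p * (p + 2)), p + 2, p)
  cc <- abs(stats::cor(a))
  diag(cc) <- 1
  cc
}

# Small block-sparse unified fixture with randomized shapes; both classes
# present in each modality so class-conditional imputation is defined.
randomUnified <- function(seed) {
  set.seed(seed)
  mk <- function(n0, n1, p, tag, idp) {
    n <- n0 + n1
    m <- matrix(rnorm(n * p), n, p,
                dimnames = list(paste0(idp, seq_len(n)),
                                paste0(tag, seq_len(p))))
    FeatureTable(m, c(rep(0, n0), rep(1, n1)), tag)
  }
  a <- mk(sample(3:6, 1), sample(2:4, 1), sample(2:4, 1), "a", "x")
  b <- mk(sample(3:6, 1), sample(2:4, 1), sample(3:6, 1), "b", "y")
  mergeSeparate(list(a, b))
}

extfile <- function(name) system.file("extdata", name, package = "modalFuse")
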