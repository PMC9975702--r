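# shared machinery: PCA once per block (the PCA basis of each block is
# invariant to permuting the other block's rows), then per permutation the
# behaviour scores are row-shuffled and CCA recomputed from the QR factors.
# A row permutation of a column-centered matrix permutes its Q factor and
# leaves R unchanged, so per-permutation cost is one crossprod + small SVD —
# an exact optimization, not an approximation.
permNullSetup <- function(imaging, behaviour, nCompBrain, nCompBehav) {
  X <- asValues(imaging); Y <- asValues(behaviour)
  n <- nrow(X)
  nCompBrain <- nCompBrain %||% min(n - 1, ncol(X), 100)
  nCompBehav <- nCompBehav %||% min(n - 1, ncol(Y), 100)
  pB <- fitPCA(X, nCompBrain)
  pY <- fitPCA(Y, nCompBehav)
  qx <- qr(pB@scores); qy <- qr(pY@scores)
  dx <- qx$rank; dy <- qy$rank
  list(n = n, nCompBrain = nCompBrain, nCompBehav = nCompBehav,
       Qx = qr.Q(qx)[, seq_len(dx), drop = FALSE],
       Qy = qr.Q(qy)[, seq_len(dy), drop = FALSE])
}

validatePerm <- function(nPerm) {
  stopIfNot(nPerm >= 100,
            "nPerm must be >= 100 (empirical p-value resolution)")
}

#' Permutation test of the canonical correlations (max-statistic FWE)
#'
#' The behaviour block's participant rows are randomly permuted relative to
#' the imaging block; for each permutation the maximum canonical correlation
#' is recorded. Family-wise-error-corrected p-values compare each observed
#' canonical correlation against this null of maxima:
#' `p[k] = (1 + sum(nullMax >= observed[k])) / (1 + nPerm)`, which can never
#' be zero and controls the probability of any false-positive component.
#'
#' @param imaging,behaviour preprocessed, aligned [DataBlock-class] objects.
#' @param K number of components tested.
#' @param nCompBrain,nCompBehav PCA dimensionalities (defaults as in
#'   [runFullDecomposition()]).
#' @param nPerm number of permutations (>= 100; the reference analysis used
#'   1000).
#' @param seed integer seed.
#' @return a [PermutationReport-class].
#' @export
permutationTestCCA <- function(imaging, behaviour, K = 2, nCompBrain = NULL,
                               nCompBehav = NULL, nPerm = 1000, seed = 1) {
  validatePerm(nPerm)
  checkAligned(imaging, behaviour)
  st <- permNullSetup(imaging, behaviour, nCompBrain, nCompBehav)
  Kmax <- min(ncol(st$Qx), ncol(st$Qy))
  stopIfNot(K <= Kmax, sprintf("K exceeds the attainable rank %d", Kmax))
  observed <- svd(crossprod(st$Qx, st$Qy))$d[seq_len(K)]
  observed <- pmin(pmax(observed, 0), 1)
  nullMax <- withSeed(seed, {
    vapply(seq_len(nPerm), function(i) {
      idx <- sample(st$n)
      svd(crossprod(st$Qx, st$Qy[idx, , drop = FALSE]))$d[1]
    }, numeric(1))
  })
  new("PermutationReport", statistic = "cca", observed = observed,
      nullMax = nullMax, pFwe = fwePValues(observed, nullMax),
      nPerm = as.integer(nPerm), seed = as.integer(seed))
}

#' Permutation test of the CCA-ICA mode correlations (max-statistic FWE)
#'
#' As [permutationTestCCA()], but the observed statistics are the mode
#' correlations after the ICA rotation, and by default the ICA rotation is
#' recomputed inside every permutation so the null reflects the full
#' pipeline. `icaInNull = FALSE` uses the cheaper maximum canonical
#' correlation as the null statistic instead (the max mode correlation is
#' bounded by the max canonical correlation, so this null is conservative).
#'
#' @inheritParams permutationTestCCA
#' @param icaInNull recompute the ICA rotation within each permutation
#'   (default `TRUE`; a single ICA restart is used inside the null).
#' @param nRestarts ICA restarts for the observed fit.
#' @return a [PermutationReport-class].
#' @export
permutationTestModes <- function(imaging, behaviour, K = 2, nCompBrain = NULL,
                                 nCompBehav = NULL, nPerm = 1000, seed = 1,
                                 icaInNull = TRUE, nRestarts = 5) {
  validatePerm(nPerm)
  checkAligned(imaging, behaviour)
  st <- permNullSetup(imaging, behaviour, nCompBrain, nCompBehav)
  Kmax <- min(ncol(st$Qx), ncol(st$Qy))
  stopIfNot(K <= Kmax, sprintf("K exceeds the attainable rank %d", Kmax))
  modes <- runFullDecomposition(imaging, behaviour, nCompBrain = st$nCompBrain,
                                nCompBehav = st$nCompBehav, K = K, seed = seed,
                                nRestarts = nRestarts, computeLoadings = FALSE)
  observed <- modeCorrs(modes)
  n <- st$n; sc <- sqrt(n - 1)
  nullMax <- withSeed(seed, {
    vapply(seq_len(nPerm), function(i) {
      idx <- sample(n)
      sv <- svd(crossprod(st$Qx, st$Qy[idx, , drop = FALSE]), nu = K, nv = K)
      if (!icaInNull) return(min(max(sv$d[1], 0), 1))
      U <- st$Qx %*% sv$u * sc
      V <- st$Qy[idx, , drop = FALSE] %*% sv$v * sc
      cca <- new("CCAResult", brainWeights = sv$u, behavWeights = sv$v,
                 U = U, V = V,
                 canonicalCorrs = pmin(pmax(sv$d[seq_len(K)], 0), 1))
      # single restart with a relaxed tolerance; if the fixed point fails on
      # (near-Gaussian) null data, the max canonical correlation bounds the
      # max mode correlation from above, so it is a safe stand-in
      m <- tryCatch(
        fitICARotation(cca, K = K, seed = childSeed(seed, i), nRestarts = 1,
                       tol = 1e-5),
        error = function(e) NULL)
      if (is.null(m)) min(max(sv$d[1], 0), 1) else max(modeCorrs(m))
    }, numeric(1))
  })
  new("PermutationReport", statistic = "modes", observed = observed,
      nullMax = nullMax, pFwe = fwePValues(observed, nullMax),
      nPerm = as.integer(nPerm), seed = as.integer(seed))
}
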