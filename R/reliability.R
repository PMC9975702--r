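# exact optimal assignment of modes across two loading matrices (p x K):
# maximize total |correlation| over all K! permutations (K <= 8)
matchModes <- function(loadA, loadB) {
  K <- ncol(loadA)
  stopIfNot(K <= 8, "mode matching supports at most 8 modes")
  C <- abs(stats::cor(loadA, loadB))
  C[is.na(C)] <- 0
  perms <- permuteAll(K)
  scores <- vapply(seq_len(nrow(perms)), function(i)
    sum(C[cbind(seq_len(K), perms[i, ])]), numeric(1))
  perms[which.max(scores), ]
}

permuteAll <- function(K) {
  if (K == 1L) return(matrix(1L, 1, 1))
  sub <- permuteAll(K - 1L)
  out <- matrix(0L, 0, K)
  for (pos in seq_len(K)) {
    out <- rbind(out, cbind(sub[, seq_len(pos - 1), drop = FALSE], as.integer(K),
                            sub[, seq(pos, K - 1)[seq_len(K - pos)], drop = FALSE]))
  }
  dimnames(out) <- NULL
  out
}

# variable-loading matrices (concatenated brain+behaviour, and behaviour
# only) from a fitted ModeSet, as variables x K matrices
loadingMatrices <- function(modes) {
  vl <- modes@variableLoadings
  K <- nModes(modes)
  sideMat <- function(sideName) {
    sub <- vl[vl$side == sideName, ]
    m <- matrix(sub$loading, ncol = K)
    rownames(m) <- sub$variable[sub$mode == 1]
    m
  }
  brain <- sideMat("brain"); behav <- sideMat("behaviour")
  list(all = rbind(brain, behav), behaviour = behav)
}

#' One split-half reliability estimate
#'
#' Participants are randomly split into two halves (stratified by `site`
#' when given, so scanner composition cannot differ between halves), the
#' full decomposition is run independently in each half, modes are matched
#' across halves by maximizing total |correlation| of the behaviour-side
#' variable-loading vectors over all assignments, and each matched pair's
#' reliability is the |r| of the concatenated (brain + behaviour)
#' variable-loading vectors.
#'
#' @param imaging,behaviour preprocessed, aligned [DataBlock-class] objects.
#' @param dims triple `c(pcaBrain, pcaBehav, K)`.
#' @param seed integer seed (split and per-half ICA).
#' @param site optional per-participant stratification factor.
#' @return numeric length-K reliability vector in [0, 1].
#' @export
splitHalfOnce <- function(imaging, behaviour, dims, seed = 1, site = NULL) {
  checkAligned(imaging, behaviour)
  n <- nParticipants(imaging)
  needed <- 2 * (max(dims[1], dims[2]) + 2)
  stopIfNot(n >= needed,
            sprintf("need n >= %d participants for dims (%d, %d)", needed,
                    dims[1], dims[2]))
  idx <- withSeed(seed, {
    if (is.null(site)) sample(n) else {
      # stratified: shuffle within site, interleave
      ord <- unlist(lapply(split(seq_len(n), site), sample), use.names = FALSE)
      ord
    }
  })
  half1 <- sort(idx[seq(1, n, by = 2)])
  half2 <- sort(idx[seq(2, n, by = 2)])
  fitHalf <- function(rows, s) {
    run <- function(tol, maxit) runFullDecomposition(
      DataBlock(blockValues(imaging)[rows, , drop = FALSE]),
      DataBlock(blockValues(behaviour)[rows, , drop = FALSE]),
      nCompBrain = dims[1], nCompBehav = dims[2], K = dims[3], seed = s,
      tol = tol, maxit = maxit)
    # excess components are near-Gaussian and the ICA fixed point may not
    # reach the tight default tolerance; retry relaxed, and treat a
    # candidate whose rotation will not converge at all as maximally
    # unreliable rather than aborting the selection
    tryCatch(run(1e-7, 500),
             error = function(e) tryCatch(run(1e-4, 1000),
                                          error = function(e2) NULL))
  }
  m1 <- fitHalf(half1, childSeed(seed, 1))
  m2 <- fitHalf(half2, childSeed(seed, 2))
  if (is.null(m1) || is.null(m2)) return(rep(0, dims[3]))
  l1 <- loadingMatrices(m1); l2 <- loadingMatrices(m2)
  perm <- matchModes(l1$behaviour, l2$behaviour)
  vapply(seq_len(dims[3]), function(k) {
    r <- safeCor(l1$all[, k], l2$all[, perm[k]])
    if (is.na(r)) 0 else abs(r)
  }, numeric(1))
}

#' Select PCA/ICA dimensionality by split-half reliability
#'
#' For each candidate `(pcaBrain, pcaBehav, K)` triple, runs `nSplits`
#' split-half estimates and scores the candidate by the mean over splits of
#' the reliability of its least reliable mode. The candidate with the
#' highest score wins; ties break toward smaller total dimensionality.
#'
#' @param imaging,behaviour preprocessed, aligned [DataBlock-class] objects.
#' @param candidateDims list of `c(pcaBrain, pcaBehav, K)` triples.
#' @param nSplits number of random splits per candidate (default 10).
#' @param seed integer seed.
#' @param site optional stratification factor, passed to [splitHalfOnce()].
#' @return list with the [SplitHalfReport-class] `report` and the `chosen`
#'   dims triple.
#' @export
selectDimensionality <- function(imaging, behaviour, candidateDims,
                                 nSplits = 10, seed = 1, site = NULL) {
  stopIfNot(length(candidateDims) >= 1, "need at least one candidate")
  rows <- list(); scores <- numeric(length(candidateDims))
  for (ci in seq_along(candidateDims)) {
    dims <- candidateDims[[ci]]
    rel <- matrix(NA_real_, nSplits, dims[3])
    for (s in seq_len(nSplits)) {
      rel[s, ] <- splitHalfOnce(imaging, behaviour, dims,
                                seed = childSeed(seed, (ci - 1) * nSplits + s),
                                site = site)
      rows[[length(rows) + 1L]] <- data.frame(
        candidate = ci, split = s, mode = seq_len(dims[3]),
        reliability = rel[s, ])
    }
    scores[ci] <- mean(apply(rel, 1, min))
  }
  totals <- vapply(candidateDims, sum, numeric(1))
  chosen <- order(-scores, totals)[1]
  cand <- do.call(rbind, lapply(candidateDims, function(d)
    data.frame(pcaBrain = d[1], pcaBehav = d[2], K = d[3])))
  report <- new("SplitHalfReport", candidates = cand,
                perSplit = do.call(rbind, rows), minReliability = scores,
                chosen = as.integer(chosen), nSplits = as.integer(nSplits),
                seed = as.integer(seed))
  list(report = report, chosen = candidateDims[[chosen]])
}
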