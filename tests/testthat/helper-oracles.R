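# independent oracles and small fixture builders shared across tests

# canonical correlations by the textbook generalized-eigenproblem route:
# eigenvalues of Sxx^{-1} Sxy Syy^{-1} Syx (explicit inverses on purpose --
# this is the brute-force reference the stable QR/SVD path is checked
# against, never the implementation)
ccaOracle <- function(X, Y) {
  n <- nrow(X)
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  Sxx <- crossprod(Xc) / (n - 1)
  Syy <- crossprod(Yc) / (n - 1)
  Sxy <- crossprod(Xc, Yc) / (n - 1)
  # ginv instead of solve so rank-deficient (noise-free) blocks also have a
  # reference value; on full-rank input they agree to machine precision
  M <- MASS::ginv(Sxx) %*% Sxy %*% MASS::ginv(Syy) %*% t(Sxy)
  ev <- Re(eigen(M, only.values = TRUE)$values)
  sort(sqrt(pmax(ev, 0)), decreasing = TRUE)
}

# closed-form partial correlation of x and y given z
partialCorOracle <- function(x, y, z) {
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# exhaustive nearest-variable imputation oracle: enumerate all variable
# pairs, rank by Euclidean distance over mutually observed participants,
# fill with the unweighted mean of the k nearest variables observed at the
# target participant
knnImputeOracle <- function(X, k) {
  p <- ncol(X)
  out <- X
  for (j in seq_len(p)) {
    for (i in which(is.na(X[, j]))) {
      d <- rep(Inf, p)
      for (l in seq_len(p)) {
        if (l == j) next
        shared <- !is.na(X[, j]) & !is.na(X[, l])
        if (any(shared)) d[l] <- sqrt(sum((X[shared, j] - X[shared, l])^2))
      }
      cand <- setdiff(which(!is.na(X[i, ]) & is.finite(d)), j)
      cand <- cand[order(d[cand], cand)]
      out[i, j] <- mean(X[i, cand[seq_len(min(k, length(cand)))]])
    }
  }
  out
}

# small linked dataset reused across tests
tinySim <- function(n = 300, pBrain = 30, pBehav = 40, rho = c(0.9, 0.7),
                    seed = 1, ...) {
  generateLinkedBlocks(n = n, pBrain = pBrain, pBehav = pBehav,
                       kTrue = length(rho), crossBlockCorr = rho,
                       seed = seed, ...)
}

# a matrix with dimnames suitable for DataBlock()
namedMatrix <- function(data, n, p, prefix = "v") {
  matrix(data, n, p, dimnames = list(sprintf("p%02d", seq_len(n)),
                                     sprintf("%s%02d", prefix, seq_len(p))))
}

# best |correlation| of each column of A against any column of B (handles
# sign/permutation indeterminacy of ICA-style recoveries)
bestAbsCor <- function(A, B) {
  apply(abs(cor(A, B)), 1, max)
}
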