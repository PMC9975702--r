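#' Principal component reduction of a block
#'
#' Centers the block and takes the leading right singular vectors as the
#' component basis; used to reduce both blocks before CCA so the canonical
#' analysis neither hits rank deficiency nor fits noise.
#'
#' @param block [DataBlock-class] or numeric matrix (dense).
#' @param nComp number of components, at most `min(n - 1, p)` and at most
#'   the numerical rank.
#' @return a [PCAResult-class].
#' @export
fitPCA <- function(block, nComp) {
  X <- asValues(block)
  if (is(block, "DataBlock"))
    stopIfNot(all(blockMask(block)), "PCA requires a dense block (impute first)")
  n <- nrow(X); p <- ncol(X)
  stopIfNot(nComp >= 1, "nComp must be >= 1")
  stopIfNot(nComp <= min(n - 1, p),
            sprintf("nComp must be <= min(n - 1, p) = %d", min(n - 1, p)))
  ctr <- centerColumns(X)
  sv <- svd(ctr$x)
  rank <- sum(sv$d > max(n, p) * .Machine$double.eps * sv$d[1])
  if (nComp > rank)
    stop(sprintf("nComp = %d exceeds the attainable rank %d", nComp, rank),
         call. = FALSE)
  basis <- sv$v[, seq_len(nComp), drop = FALSE]
  rownames(basis) <- colnames(X)
  scores <- ctr$x %*% basis
  rownames(scores) <- rownames(X)
  new("PCAResult", basis = basis, scores = scores,
      explainedVariance = sv$d[seq_len(nComp)]^2 / (n - 1),
      center = ctr$center, nComp = as.integer(nComp))
}

#' Canonical correlation analysis of two score matrices
#'
#' Finds successive weight vectors maximizing the correlation between the
#' two sides' weighted scores, subject to within-block orthogonality.
#' Computed by the numerically stable QR/SVD route (QR of each centered
#' matrix, SVD of the cross-product of the orthonormal factors) — no
#' covariance matrix is inverted. Canonical variates are scaled to unit
#' sample variance.
#'
#' @param scoresBrain,scoresBehav participants x d matrices (rows aligned).
#' @param K number of canonical pairs, at most the smaller attainable rank.
#' @return a [CCAResult-class].
#' @export
fitCCA <- function(scoresBrain, scoresBehav, K) {
  X <- as.matrix(scoresBrain); Y <- as.matrix(scoresBehav)
  stopIfNot(nrow(X) == nrow(Y), "score matrices must have the same rows")
  n <- nrow(X)
  stopIfNot(n >= 3, "need at least 3 participants")
  sdx <- apply(X, 2, stats::sd); sdy <- apply(Y, 2, stats::sd)
  if (any(sdx == 0) || any(sdy == 0))
    stop("zero-variance column in CCA input", call. = FALSE)
  Xc <- centerColumns(X)$x; Yc <- centerColumns(Y)$x
  qx <- qr(Xc); qy <- qr(Yc)
  dx <- qx$rank; dy <- qy$rank
  if (K > min(dx, dy))
    stop(sprintf("K = %d exceeds the attainable rank %d", K, min(dx, dy)),
         call. = FALSE)
  Qx <- qr.Q(qx)[, seq_len(dx), drop = FALSE]
  Qy <- qr.Q(qy)[, seq_len(dy), drop = FALSE]
  sv <- svd(crossprod(Qx, Qy), nu = K, nv = K)
  corrs <- pmin(pmax(sv$d[seq_len(K)], 0), 1)

  unpivot <- function(qrObj, d, coefPiv, p) {
    A <- matrix(0, p, K)
    Rd <- qr.R(qrObj)[seq_len(d), seq_len(d), drop = FALSE]
    A[qrObj$pivot[seq_len(d)], ] <- backsolve(Rd, coefPiv)
    A
  }
  sc <- sqrt(n - 1)
  A <- unpivot(qx, dx, sv$u, ncol(X)) * sc
  B <- unpivot(qy, dy, sv$v, ncol(Y)) * sc
  U <- Xc %*% A
  V <- Yc %*% B
  rownames(U) <- rownames(V) <- rownames(X)
  new("CCAResult", brainWeights = A, behavWeights = B, U = U, V = V,
      canonicalCorrs = corrs)
}

# fixed-point fastICA: log-cosh contrast (a = 1), symmetric decorrelation.
# Z is whitened n x K; returns the K x K orthonormal unmixing matrix of the
# restart with the largest summed negentropy proxy. RNG state is the
# caller's responsibility.
fastIcaSymm <- function(Z, tol = 1e-7, maxit = 500, nRestarts = 5) {
  n <- nrow(Z); K <- ncol(Z)
  eLogcoshGauss <- 0.3745672 # E[log cosh Z], Z ~ N(0,1)
  best <- NULL; bestJ <- -Inf; lastConv <- NA_real_
  for (r in seq_len(nRestarts)) {
    W <- qr.Q(qr(matrix(stats::rnorm(K * K), K, K)))
    converged <- FALSE
    for (it in seq_len(maxit)) {
      S <- Z %*% t(W)
      G <- tanh(S)
      W1 <- crossprod(G, Z) / n - diag(colMeans(1 - G^2), K) %*% W
      sv <- svd(W1)
      W1 <- sv$u %*% t(sv$v) # symmetric decorrelation: (W1 W1')^{-1/2} W1
      conv <- max(abs(abs(diag(W1 %*% t(W))) - 1))
      W <- W1
      if (conv < tol) { converged <- TRUE; break }
    }
    lastConv <- conv
    if (!converged) next
    S <- Z %*% t(W)
    J <- sum((colMeans(log(cosh(S))) - eLogcoshGauss)^2)
    if (J > bestJ) { bestJ <- J; best <- W }
  }
  if (is.null(best))
    stop(sprintf("fastICA failed to converge in %d restarts (final tolerance %.3g)",
                 nRestarts, lastConv), call. = FALSE)
  best
}

#' Rotate canonical variates into independent modes by fastICA
#'
#' A single K x K unmixing matrix is estimated from the vertically stacked
#' canonical scores `[U; V]` (fixed-point ICA, log-cosh contrast, symmetric
#' decorrelation on whitened input) and then applied separately to U and V.
#' Estimating one rotation on the stack guarantees that an imaging-only
#' weight matrix exists, which out-of-sample projection requires. Modes are
#' ordered by descending cross-side correlation; each unmixing row is
#' provisionally oriented so its largest-magnitude entry is positive (the
#' full pipeline re-orients by behaviour variable loadings).
#'
#' @param cca a [CCAResult-class].
#' @param K number of modes (defaults to all canonical pairs).
#' @param seed integer seed for the ICA restarts.
#' @param nRestarts random restarts; the run with the best negentropy sum
#'   is kept (default 5).
#' @param tol,maxit fixed-point convergence tolerance and iteration cap.
#' @param pcaBrain,pcaBehav optional [PCAResult-class] objects used to
#'   compose variable-space projection matrices (otherwise projections live
#'   on the PCA-score spaces).
#' @return a [ModeSet-class] (with empty `variableLoadings`; see
#'   [computeVariableLoadings()]).
#' @export
fitICARotation <- function(cca, K = length(cca@canonicalCorrs), seed = 1,
                           nRestarts = 5, tol = 1e-7, maxit = 500,
                           pcaBrain = NULL, pcaBehav = NULL) {
  stopIfNot(K >= 1 && K <= ncol(cca@U), "K must be within the canonical pairs")
  U <- cca@U[, seq_len(K), drop = FALSE]
  V <- cca@V[, seq_len(K), drop = FALSE]
  S <- rbind(U, V)
  S <- centerColumns(S)$x
  ev <- eigen(stats::cov(S), symmetric = TRUE)
  stopIfNot(all(ev$values > 1e-12), "degenerate canonical-score covariance")
  Wh <- ev$vectors %*% diag(1 / sqrt(ev$values), K) %*% t(ev$vectors)
  Z <- S %*% Wh
  W <- if (K == 1L) matrix(1, 1, 1) else
    withSeed(seed, fastIcaSymm(Z, tol = tol, maxit = maxit, nRestarts = nRestarts))

  Tm <- Wh %*% t(W) # canonical-score space -> mode space
  brainML <- U %*% Tm
  behavML <- V %*% Tm
  mc <- vapply(seq_len(K), function(k) safeCor(brainML[, k], behavML[, k]),
               numeric(1))

  # provisional sign: flip modes with negative cross-side correlation would
  # change nothing (both sides flip together); orient each unmixing row so
  # its largest-|entry| is positive, for run-to-run comparability
  for (k in seq_len(K)) {
    j <- which.max(abs(W[k, ]))
    if (W[k, j] < 0) {
      W[k, ] <- -W[k, ]; Tm[, k] <- -Tm[, k]
      brainML[, k] <- -brainML[, k]; behavML[, k] <- -behavML[, k]
    }
  }
  ord <- order(mc, decreasing = TRUE)
  W <- W[ord, , drop = FALSE]; Tm <- Tm[, ord, drop = FALSE]
  brainML <- brainML[, ord, drop = FALSE]; behavML <- behavML[, ord, drop = FALSE]
  mc <- mc[ord]

  Abrain <- cca@brainWeights[, seq_len(K), drop = FALSE] %*% Tm
  Abehav <- cca@behavWeights[, seq_len(K), drop = FALSE] %*% Tm
  if (!is.null(pcaBrain)) {
    brainProj <- pcaBrain@basis %*% Abrain
    brainCenter <- pcaBrain@center
  } else { brainProj <- Abrain; brainCenter <- numeric() }
  if (!is.null(pcaBehav)) {
    behavProj <- pcaBehav@basis %*% Abehav
    behavCenter <- pcaBehav@center
  } else { behavProj <- Abehav; behavCenter <- numeric() }
  colnames(brainProj) <- colnames(behavProj) <-
    colnames(brainML) <- colnames(behavML) <- paste0("mode", seq_len(K))

  new("ModeSet", unmixing = W, brainModeLoadings = brainML,
      behavModeLoadings = behavML, modeCorrs = mc,
      brainProjection = brainProj, behavProjection = behavProj,
      brainCenter = brainCenter, behavCenter = behavCenter,
      variableLoadings = data.frame(variable = character(), side = character(),
                                    mode = integer(), loading = numeric()),
      canonicalCorrs = cca@canonicalCorrs, seed = as.integer(seed))
}

# residualise columns of Y against a covariate design built from df
residCovariates <- function(Y, df) {
  for (nm in names(df)) if (!is.numeric(df[[nm]])) df[[nm]] <- factor(df[[nm]])
  M <- stats::model.matrix(~ ., data = df)
  qr.resid(qr(M), as.matrix(Y))
}

#' Correlate mode loadings with the original de-confounded variables
#'
#' The interpretive surface of a mode: per mode and variable, the Pearson
#' correlation between the mode's participant loadings (brain side for
#' imaging variables, behaviour side for behavioural variables) and the
#' variable. With `partialCovariates`, partial correlations are computed by
#' residualising both the loadings and the variables against the named
#' covariates first.
#'
#' @param modes a [ModeSet-class].
#' @param imaging,behaviour the de-confounded [DataBlock-class] pair,
#'   row-aligned with the mode loadings.
#' @param partialCovariates optional character vector of covariate names.
#' @param confounds confound table supplying the partial covariates.
#' @return data.frame (`variable`, `side`, `mode`, `loading`); constant
#'   variables yield `NA` loadings.
#' @export
computeVariableLoadings <- function(modes, imaging, behaviour,
                                    partialCovariates = NULL, confounds = NULL) {
  K <- nModes(modes)
  oneSide <- function(block, ML, sideName) {
    X <- asValues(block)
    stopIfNot(nrow(X) == nrow(ML), "blocks and loadings are not row-aligned")
    if (length(partialCovariates)) {
      stopIfNot(!is.null(confounds), "partialCovariates given but no confound table")
      df <- confounds[, partialCovariates, drop = FALSE]
      X <- residCovariates(X, df)
      ML <- residCovariates(ML, df)
    }
    sds <- apply(X, 2, stats::sd)
    r <- suppressWarnings(stats::cor(X, ML)) # constant columns -> NA below
    r[sds == 0, ] <- NA_real_
    data.frame(variable = rep(colnames(X), K),
               side = sideName,
               mode = rep(seq_len(K), each = ncol(X)),
               loading = as.vector(r), stringsAsFactors = FALSE)
  }
  rbind(oneSide(imaging, modes@brainModeLoadings, "brain"),
        oneSide(behaviour, modes@behavModeLoadings, "behaviour"))
}

#' Run the full CCA-ICA decomposition
#'
#' Composes [fitPCA()] per block, [fitCCA()], [fitICARotation()] and
#' [computeVariableLoadings()]. Each mode is finally oriented so that the
#' behavioural variable with the largest absolute loading has a positive
#' loading — the ICA sign is unidentifiable, and a deterministic convention
#' keeps runs comparable.
#'
#' @param imaging,behaviour preprocessed, row-aligned [DataBlock-class]
#'   objects (or matrices).
#' @param nCompBrain,nCompBehav PCA dimensionalities (defaults: smallest of
#'   n - 1, p and 100).
#' @param K number of modes.
#' @param seed integer seed (ICA restarts).
#' @param nRestarts ICA restarts (default 5).
#' @param computeLoadings set `FALSE` to skip variable loadings (used inside
#'   permutation nulls).
#' @param tol,maxit ICA convergence controls, passed to [fitICARotation()].
#' @return a [ModeSet-class].
#' @export
runFullDecomposition <- function(imaging, behaviour, nCompBrain = NULL,
                                 nCompBehav = NULL, K = 2, seed = 1,
                                 nRestarts = 5, computeLoadings = TRUE,
                                 tol = 1e-7, maxit = 500) {
  checkAligned(imaging, behaviour)
  X <- asValues(imaging); Y <- asValues(behaviour)
  n <- nrow(X)
  nCompBrain <- nCompBrain %||% min(n - 1, ncol(X), 100)
  nCompBehav <- nCompBehav %||% min(n - 1, ncol(Y), 100)
  pB <- tryCatch(fitPCA(X, nCompBrain),
                 error = function(e) stop("pca(imaging): ", conditionMessage(e), call. = FALSE))
  pY <- tryCatch(fitPCA(Y, nCompBehav),
                 error = function(e) stop("pca(behaviour): ", conditionMessage(e), call. = FALSE))
  cca <- tryCatch(fitCCA(pB@scores, pY@scores, K),
                  error = function(e) stop("cca: ", conditionMessage(e), call. = FALSE))
  modes <- tryCatch(
    fitICARotation(cca, K = K, seed = seed, nRestarts = nRestarts,
                   tol = tol, maxit = maxit, pcaBrain = pB, pcaBehav = pY),
    error = function(e) stop("ica: ", conditionMessage(e), call. = FALSE))
  if (!computeLoadings) return(modes)

  vl <- computeVariableLoadings(modes, imaging, behaviour)
  # sign convention: behaviour variable with the largest |loading| positive
  for (k in seq_len(nModes(modes))) {
    beh <- vl[vl$side == "behaviour" & vl$mode == k, ]
    if (!nrow(beh) || all(is.na(beh$loading))) next
    top <- which.max(abs(beh$loading))
    if (beh$loading[top] < 0) {
      modes@unmixing[k, ] <- -modes@unmixing[k, ]
      modes@brainModeLoadings[, k] <- -modes@brainModeLoadings[, k]
      modes@behavModeLoadings[, k] <- -modes@behavModeLoadings[, k]
      modes@brainProjection[, k] <- -modes@brainProjection[, k]
      modes@behavProjection[, k] <- -modes@behavProjection[, k]
      vl$loading[vl$mode == k] <- -vl$loading[vl$mode == k]
    }
  }
  modes@variableLoadings <- vl
  modes
}
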