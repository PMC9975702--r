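#' Clean a block for extreme scores and heavy missingness
#'
#' Three steps in fixed order: (1) cells whose robust z-score
#' (median/MAD-based) exceeds `zExtreme` in absolute value are set missing;
#' (2) variables whose missing fraction then exceeds `maxVarMissing` are
#' dropped; (3) participants whose missing fraction over the surviving
#' variables exceeds `maxParticipantMissing` are dropped.
#'
#' @param block a [DataBlock-class].
#' @param zExtreme robust-z threshold for extreme cells (default 4).
#' @param maxVarMissing,maxParticipantMissing missing-fraction thresholds
#'   (defaults 0.5).
#' @return list with the cleaned `block` and a [CleaningReport-class]
#'   `report`.
#' @export
cleanBlock <- function(block, zExtreme = 4, maxVarMissing = 0.5,
                       maxParticipantMissing = 0.5) {
  stopIfNot(zExtreme > 0 && maxVarMissing > 0 && maxParticipantMissing > 0,
            "thresholds must be positive")
  X <- blockValues(block)
  mask <- blockMask(block)
  stopIfNot(length(X) > 0, "block is empty")

  z <- robustZ(X)
  extreme <- mask & !is.na(z) & abs(z) > zExtreme
  nExtreme <- sum(extreme)
  mask[extreme] <- FALSE
  X[!mask] <- NA_real_

  varMiss <- colMeans(!mask)
  keepVar <- varMiss <= maxVarMissing
  if (!any(keepVar))
    stop(sprintf(
      "all variables dropped: every missing fraction exceeds maxVarMissing = %g (zExtreme = %g)",
      maxVarMissing, zExtreme), call. = FALSE)
  droppedVars <- data.frame(
    name = colnames(X)[!keepVar],
    reason = sprintf("missing fraction %.3f > %g", varMiss[!keepVar], maxVarMissing),
    stringsAsFactors = FALSE)
  X <- X[, keepVar, drop = FALSE]
  mask <- mask[, keepVar, drop = FALSE]

  partMiss <- rowMeans(!mask)
  keepPart <- partMiss <= maxParticipantMissing
  droppedParts <- data.frame(
    id = rownames(X)[!keepPart],
    reason = sprintf("missing fraction %.3f > %g", partMiss[!keepPart],
                     maxParticipantMissing),
    stringsAsFactors = FALSE)
  X <- X[keepPart, , drop = FALSE]
  mask <- mask[keepPart, , drop = FALSE]

  report <- new("CleaningReport", droppedVariables = droppedVars,
                droppedParticipants = droppedParts,
                cellsSetMissing = as.integer(nExtreme), cellsImputed = 0L)
  list(block = DataBlock(X, mask), report = report)
}

#' Nearest-neighbour imputation over variables
#'
#' Imputation treats variables as rows: for a variable with a missing entry,
#' the k nearest other variables by Euclidean distance over mutually
#' observed participants — restricted to variables observed at the target
#' participant — supply the fill value as their unweighted mean at that
#' participant. Observed cells are never altered.
#'
#' @param block a [DataBlock-class]; every variable needs at least one
#'   observed value.
#' @param k neighbour count (default 1, nearest neighbour).
#' @return a dense [DataBlock-class] (mask all `TRUE`).
#' @export
knnImpute <- function(block, k = 1) {
  stopIfNot(k >= 1, "k must be >= 1")
  X <- blockValues(block)
  mask <- blockMask(block)
  if (all(mask)) return(block)
  stopIfNot(all(colSums(mask) >= 1),
            paste("variables with no observed values:",
                  paste(colnames(X)[colSums(mask) == 0], collapse = ", ")))
  p <- ncol(X)
  # pairwise Euclidean distances over mutually observed participants
  needs <- which(colSums(!mask) > 0)
  D <- matrix(Inf, p, p)
  for (j in needs) {
    for (l in seq_len(p)) {
      if (l == j) next
      shared <- mask[, j] & mask[, l]
      if (!any(shared)) next
      D[j, l] <- sqrt(sum((X[shared, j] - X[shared, l])^2))
    }
  }
  for (j in needs) {
    for (i in which(!mask[, j])) {
      cand <- which(mask[i, ] & is.finite(D[j, ]))
      if (!length(cand))
        stop(sprintf(
          "variable '%s' has no observed overlap with any variable observed for participant '%s'",
          colnames(X)[j], rownames(X)[i]), call. = FALSE)
      ord <- cand[order(D[j, cand], cand)]
      nb <- ord[seq_len(min(k, length(ord)))]
      X[i, j] <- mean(X[i, nb])
    }
  }
  DataBlock(X, matrix(TRUE, nrow(X), p, dimnames = dimnames(X)))
}

#' Residualise a block against confounds
#'
#' Each variable is replaced by its ordinary-least-squares residuals against
#' an intercept plus the dummy-coded categorical and continuous confounds in
#' `confoundSpec`. Variables named in `volumetricVars` are additionally
#' residualised for the global-volume covariate `globalCovariate` (the
#' covariate itself may still be carried as an analysis variable in the
#' block). Residual columns have zero mean.
#'
#' @param block dense [DataBlock-class] (no missing values).
#' @param confounds confound table row-aligned with the block.
#' @param confoundSpec character vector of confound column names to remove
#'   from every variable; empty means intercept-only (column centering).
#' @param volumetricVars optional character vector of variable names that
#'   also get the global covariate removed.
#' @param globalCovariate name of the global-volume column in `confounds`
#'   (default `"etiv"`).
#' @return residualised [DataBlock-class].
#' @export
residualise <- function(block, confounds, confoundSpec = character(),
                        volumetricVars = NULL, globalCovariate = "etiv") {
  X <- blockValues(block)
  stopIfNot(all(blockMask(block)), "residualise requires a dense block (impute first)")
  checkAligned(block, confounds, "block and confound table")

  buildDesign <- function(spec) {
    if (!length(spec)) return(matrix(1, nrow(X), 1, dimnames = list(NULL, "(Intercept)")))
    missingCols <- setdiff(spec, names(confounds))
    stopIfNot(!length(missingCols),
              paste("confounds not in table:", paste(missingCols, collapse = ", ")))
    df <- confounds[, spec, drop = FALSE]
    for (nm in spec) if (!is.numeric(df[[nm]])) df[[nm]] <- factor(df[[nm]])
    stats::model.matrix(~ ., data = df)
  }
  resid_against <- function(Y, M) {
    qrM <- qr(M)
    if (qrM$rank < ncol(M)) {
      bad <- colnames(M)[qrM$pivot[(qrM$rank + 1):ncol(M)]]
      stop(paste("confound design is rank-deficient; collinear columns:",
                 paste(bad, collapse = ", ")), call. = FALSE)
    }
    qr.resid(qrM, Y)
  }

  M <- buildDesign(confoundSpec)
  out <- resid_against(X, M)
  if (length(volumetricVars)) {
    vv <- intersect(volumetricVars, colnames(X))
    if (length(vv)) {
      stopIfNot(globalCovariate %in% names(confounds),
                sprintf("global covariate '%s' not in confound table", globalCovariate))
      Mg <- cbind(M, global = as.numeric(confounds[[globalCovariate]]))
      out[, vv] <- resid_against(X[, vv, drop = FALSE], Mg)
    }
  }
  DataBlock(out)
}

#' Rank-based inverse normal transformation
#'
#' Each variable is independently mapped through
#' \eqn{z = \Phi^{-1}\big((r - c)/(n - 2c + 1)\big)} where r are the ranks
#' (ties receive average ranks) and c is the transform offset: Blom
#' (c = 3/8, the default), Tukey (1/3), van der Waerden (0) or rankit (1/2).
#' The transform is a monotone function of each column, enforcing Gaussian
#' marginals.
#'
#' @param block dense [DataBlock-class].
#' @param variant offset variant, `"blom"` (default), `"tukey"`,
#'   `"waerden"` or `"rankit"`.
#' @param constantAction `"error"` (default) to fail on a constant column,
#'   or `"zero"` to pass it through as all zeros with a warning.
#' @return transformed [DataBlock-class].
#' @export
rankInverseNormal <- function(block, variant = c("blom", "tukey", "waerden", "rankit"),
                              constantAction = c("error", "zero")) {
  variant <- match.arg(variant)
  constantAction <- match.arg(constantAction)
  X <- blockValues(block)
  stopIfNot(all(blockMask(block)), "transform requires a dense block (impute first)")
  cc <- switch(variant, blom = 3 / 8, tukey = 1 / 3, waerden = 0, rankit = 1 / 2)
  n <- nrow(X)
  const <- apply(X, 2, function(x) length(unique(x)) == 1L)
  if (any(const)) {
    if (constantAction == "error")
      stop(paste("constant variables cannot be rank-normalised:",
                 paste(colnames(X)[const], collapse = ", ")), call. = FALSE)
    warning(sprintf("%d constant variable(s) passed through as zeros", sum(const)))
  }
  out <- apply(X, 2, function(x) {
    if (length(unique(x)) == 1L) return(rep(0, n))
    r <- rank(x, ties.method = "average")
    stats::qnorm((r - cc) / (n - 2 * cc + 1))
  })
  dimnames(out) <- dimnames(X)
  DataBlock(out)
}

#' Run the full preprocessing chain on one block
#'
#' Applies, in order: [cleanBlock()], [knnImpute()], [residualise()],
#' [rankInverseNormal()]. The confound table is subset to the participants
#' that survive cleaning.
#'
#' @inheritParams cleanBlock
#' @inheritParams knnImpute
#' @inheritParams residualise
#' @inheritParams rankInverseNormal
#' @return list `block` (processed [DataBlock-class]), `report`
#'   ([CleaningReport-class], with `cellsImputed` filled in) and
#'   `confounds` (the row-subset confound table).
#' @export
preprocessBlock <- function(block, confounds = NULL,
                            confoundSpec = character(), volumetricVars = NULL,
                            globalCovariate = "etiv",
                            zExtreme = 4, maxVarMissing = 0.5,
                            maxParticipantMissing = 0.5, k = 1,
                            variant = "blom") {
  cl <- cleanBlock(block, zExtreme, maxVarMissing, maxParticipantMissing)
  b <- cl$block
  nMissing <- sum(!blockMask(b))
  b <- knnImpute(b, k = k)
  conf <- confounds
  if (!is.null(conf)) {
    conf <- conf[match(participantIds(b), conf$participant_id), , drop = FALSE]
    stopIfNot(!anyNA(conf$participant_id), "confound table lacks some block participants")
    rownames(conf) <- NULL
    b <- residualise(b, conf, confoundSpec, volumetricVars, globalCovariate)
  } else {
    stopIfNot(!length(confoundSpec), "confoundSpec given but no confound table")
    b <- DataBlock(centerColumns(blockValues(b))$x)
  }
  b <- rankInverseNormal(b, variant = variant)
  report <- cl$report
  report@cellsImputed <- as.integer(nMissing)
  list(block = b, report = report, confounds = conf)
}
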