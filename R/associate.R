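# build the standard covariate data.frame: centered age, its square, sex
covariateFrame <- function(confounds, terms = c("age", "age2", "sex")) {
  df <- data.frame(row.names = seq_len(nrow(confounds)))
  for (tm in terms) {
    if (tm == "age2") {
      stopIfNot("age" %in% names(confounds), "age2 requested but no age column")
      ac <- confounds$age - mean(confounds$age)
      df$age2 <- ac^2
    } else {
      stopIfNot(tm %in% names(confounds),
                sprintf("covariate '%s' not in confound table", tm))
      v <- confounds[[tm]]
      if (tm == "age") v <- v - mean(v) # centered so age and age2 decorrelate
      df[[tm]] <- if (is.numeric(v)) v else factor(v)
    }
  }
  df
}

#' Linear covariate model for mode loadings
#'
#' Ordinary least squares of a participant mode-loading vector on the named
#' covariate terms (default `age + age^2 + sex`, with age centered before
#' squaring so the linear and quadratic terms decorrelate).
#'
#' @param loadings numeric per-participant mode loading vector.
#' @param confounds confound table row-aligned with `loadings`.
#' @param terms covariate terms; `"age2"` expands to centered-age squared.
#' @return list with `coefficients`, `fitted`, `residuals` and the `lm` fit.
#' @export
fitCovariateModel <- function(loadings, confounds, terms = c("age", "age2", "sex")) {
  stopIfNot(length(loadings) == nrow(confounds),
            "loadings and confound table differ in length")
  df <- covariateFrame(confounds, terms)
  df$.y <- as.numeric(loadings)
  fit <- stats::lm(.y ~ ., data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(paste("rank-deficient covariate design; offending columns:",
               paste(bad, collapse = ", ")), call. = FALSE)
  }
  list(coefficients = stats::coef(fit), fitted = stats::fitted(fit),
       residuals = stats::resid(fit), fit = fit)
}

#' Diagnosis-category contrasts with Tukey adjustment
#'
#' Fits `loading ~ diagnosis + covariates`, computes estimated marginal
#' means per category at the covariate sample means, and contrasts each
#' category against the reference group (or all pairs with
#' `allPairwise = TRUE`). Multiplicity is adjusted with the Tukey
#' studentized-range distribution at the number of groups and residual df:
#' `p_adj = ptukey(|t| * sqrt(2), k, df, lower.tail = FALSE)`. With two
#' groups this reduces exactly to the pooled two-sample t-test. Confidence
#' intervals are unadjusted (`beta +/- qt(0.975, df) * SE`).
#'
#' @param loadings per-participant mode loading vector.
#' @param diagnosis category per participant (character or factor).
#' @param confounds confound table (for the covariates).
#' @param reference reference category (default `"no diagnosis"`).
#' @param terms covariate terms as in [fitCovariateModel()].
#' @param allPairwise contrast all category pairs instead of each vs the
#'   reference.
#' @return data.frame with columns `comparison`, `beta`, `se`, `df`,
#'   `lower`, `upper`, `t`, `pAdjusted`, plus attributes `reference` and
#'   `kGroups`.
#' @export
diagnosisContrasts <- function(loadings, diagnosis, confounds,
                               reference = "no diagnosis",
                               terms = c("age", "age2", "sex"),
                               allPairwise = FALSE) {
  diagnosis <- as.character(diagnosis)
  tab <- table(diagnosis)
  stopIfNot(length(tab) >= 2, "need at least two diagnosis categories")
  stopIfNot(all(tab >= 2), paste("categories with < 2 participants:",
                                 paste(names(tab)[tab < 2], collapse = ", ")))
  stopIfNot(reference %in% diagnosis,
            sprintf("reference category '%s' absent", reference))
  df <- if (length(terms)) covariateFrame(confounds, terms) else
    data.frame(row.names = seq_along(loadings))
  df$diagnosis <- factor(diagnosis,
                         levels = c(reference, sort(setdiff(unique(diagnosis), reference))))
  df$.y <- as.numeric(loadings)
  fit <- stats::lm(.y ~ ., data = df)
  k <- nlevels(df$diagnosis)
  rdf <- fit$df.residual
  Vc <- stats::vcov(fit)
  cf <- stats::coef(fit)

  # design rows per category at covariate sample means -> EMM contrast
  # vectors; contrasts between categories cancel the covariate part, and
  # pairwise EMM differences are invariant to category weighting
  mm <- stats::model.matrix(fit)
  emmRow <- function(lev) {
    r <- colMeans(mm)
    dcols <- grep("^diagnosis", colnames(mm), value = TRUE)
    r[dcols] <- 0
    own <- paste0("diagnosis", lev)
    if (own %in% dcols) r[own] <- 1
    r
  }
  levs <- levels(df$diagnosis)
  pairs <- if (allPairwise) utils::combn(levs, 2, simplify = FALSE) else
    lapply(setdiff(levs, reference), function(l) c(reference, l))
  rows <- lapply(pairs, function(pr) {
    cvec <- emmRow(pr[2]) - emmRow(pr[1])
    beta <- sum(cvec * cf)
    se <- sqrt(drop(t(cvec) %*% Vc %*% cvec))
    tval <- beta / se
    pAdj <- stats::ptukey(abs(tval) * sqrt(2), nmeans = k, df = rdf,
                          lower.tail = FALSE)
    ci <- beta + c(-1, 1) * stats::qt(0.975, rdf) * se
    data.frame(comparison = paste(pr[2], "-", pr[1]), beta = beta, se = se,
               df = rdf, lower = ci[1], upper = ci[2], t = tval,
               pAdjusted = pAdj, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "reference") <- reference
  attr(out, "kGroups") <- k
  out
}

#' Linear trend of mode loadings with the number of diagnoses
#'
#' Fits `loading ~ n_diagnoses + covariates`, optionally excluding the
#' zero-diagnosis group so the trend is not driven by a case-control
#' difference.
#'
#' @param loadings per-participant mode loading vector.
#' @param nDiagnoses non-negative integer count per participant.
#' @param confounds confound table.
#' @param includeZero keep the zero-diagnosis participants (default `TRUE`).
#' @param terms covariate terms.
#' @return list `slope`, `se`, `p`, `n` and the `lm` fit.
#' @export
comorbidityTrend <- function(loadings, nDiagnoses, confounds,
                             includeZero = TRUE, terms = c("age", "age2", "sex")) {
  stopIfNot(all(nDiagnoses >= 0), "nDiagnoses must be non-negative")
  keep <- if (includeZero) rep(TRUE, length(nDiagnoses)) else nDiagnoses > 0
  stopIfNot(length(unique(nDiagnoses[keep])) > 1,
            "all participants share one diagnosis count")
  df <- if (length(terms))
    covariateFrame(confounds[keep, , drop = FALSE], terms) else
    data.frame(row.names = seq_len(sum(keep)))
  df$nDiag <- as.numeric(nDiagnoses[keep])
  df$.y <- as.numeric(loadings[keep])
  fit <- stats::lm(.y ~ ., data = df)
  sm <- summary(fit)$coefficients
  list(slope = sm["nDiag", 1], se = sm["nDiag", 2], p = sm["nDiag", 4],
       n = sum(keep), fit = fit)
}

#' Robustness re-runs of the decomposition
#'
#' Re-derives the variable loadings under one of the robustness schemes and
#' reports the per-mode Pearson concordance with the original
#' variable-loading vectors:
#' \describe{
#'   \item{`sex-residualised`}{refit the full pipeline with the behaviour
#'     block residualised for sex.}
#'   \item{`age-partial`, `income-partial`, `medication-partial`}{recompute
#'     variable loadings as partial correlations controlling the named
#'     covariate.}
#'   \item{`leave-out-category`}{drop every participant in `leaveOut`
#'     (diagnosis category), project the remainder through the original
#'     weights and recompute loadings.}
#' }
#'
#' @param imaging,behaviour the de-confounded [DataBlock-class] pair used
#'   for the original fit.
#' @param confounds confound table (columns `sex`, `age`, `income`,
#'   `medication` as needed by the scheme).
#' @param modes the original fitted [ModeSet-class].
#' @param scheme one of the schemes above.
#' @param diagnosis per-participant category (for `leave-out-category`).
#' @param leaveOut category to drop (for `leave-out-category`).
#' @param nCompBrain,nCompBehav PCA dimensionalities for the refit scheme
#'   (use the original fit's values; defaults as in
#'   [runFullDecomposition()]).
#' @param seed seed for the refit scheme.
#' @return named numeric vector: per-mode concordance r between original
#'   and re-run variable loadings (matched by mode index).
#' @export
robustnessReruns <- function(imaging, behaviour, confounds, modes,
                             scheme = c("sex-residualised", "age-partial",
                                        "income-partial", "medication-partial",
                                        "leave-out-category"),
                             diagnosis = NULL, leaveOut = "ADHD",
                             nCompBrain = NULL, nCompBehav = NULL, seed = 1) {
  scheme <- match.arg(scheme)
  K <- nModes(modes)
  orig <- loadingMatrices(modes)$all

  reloaded <- switch(scheme,
    "sex-residualised" = {
      behR <- residualise(behaviour, confounds, "sex")
      m2 <- runFullDecomposition(imaging, behR, nCompBrain = nCompBrain,
                                 nCompBehav = nCompBehav, K = K, seed = seed)
      loadingMatrices(m2)$all
    },
    "age-partial" = ,
    "income-partial" = ,
    "medication-partial" = {
      cov <- sub("-partial$", "", scheme)
      vl <- computeVariableLoadings(modes, imaging, behaviour,
                                    partialCovariates = cov,
                                    confounds = confounds)
      tmp <- modes; tmp@variableLoadings <- vl
      loadingMatrices(tmp)$all
    },
    "leave-out-category" = {
      stopIfNot(!is.null(diagnosis), "leave-out scheme needs diagnosis labels")
      keep <- diagnosis != leaveOut
      Xk <- DataBlock(blockValues(imaging)[keep, , drop = FALSE])
      Yk <- DataBlock(blockValues(behaviour)[keep, , drop = FALSE])
      Lb <- projectOutOfSample(Xk, modes)
      Vt <- sweep(blockValues(Yk), 2, modes@behavCenter, "-") %*%
        modes@behavProjection
      tmp <- modes
      tmp@brainModeLoadings <- Lb
      tmp@behavModeLoadings <- Vt
      vl <- computeVariableLoadings(tmp, Xk, Yk)
      tmp@variableLoadings <- vl
      loadingMatrices(tmp)$all
    })

  # modes of a refit may come back permuted/flipped: match before scoring
  perm <- if (scheme == "sex-residualised") matchModes(orig, reloaded) else
    seq_len(K)
  out <- vapply(seq_len(K), function(k) {
    r <- safeCor(orig[, k], reloaded[, perm[k]])
    if (is.na(r)) NA_real_ else abs(r)
  }, numeric(1))
  names(out) <- paste0("mode", seq_len(K))
  out
}
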