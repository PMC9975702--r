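#' Generate linked two-block data with planted cross-block modes
#'
#' Simulates an imaging-like and a behaviour-like block observed on the same
#' participants, sharing `kTrue` latent modes. For mode k each side's latent
#' score is \eqn{z_{side} = \sqrt{\rho_k} z_{shared} + \sqrt{1-\rho_k}
#' z_{unique}}, so the two sides correlate at exactly \eqn{\rho_k} in
#' expectation — giving analytic control over the canonical correlations the
#' pipeline should recover. Latent factors are standardized draws from a
#' Laplace distribution by default: the ICA rotation that separates modes of
#' equal correlation strength is only identifiable for non-Gaussian sources,
#' which also matches the heavy-tailed composite scores seen in practice
#' after rank-based normalisation of real questionnaire and morphometry
#' data.
#'
#' Observed variables are random linear mixtures of the side latents plus
#' i.i.d. Gaussian measurement noise of standard deviation `noiseSd`.
#'
#' @param n number of participants (>= 10).
#' @param pBrain,pBehav number of imaging and behavioural variables.
#' @param kTrue number of planted modes (>= 1).
#' @param crossBlockCorr length-`kTrue` vector of target cross-block
#'   correlations, each in [0, 1].
#' @param noiseSd additive measurement-noise SD (applied to both blocks;
#'   give a length-2 vector for per-block values).
#' @param latentDist `"laplace"` (default) or `"gaussian"` latent factors.
#' @param seed integer seed; identical seeds reproduce the output exactly.
#' @return list with elements `imaging` ([DataBlock-class]), `behaviour`
#'   ([DataBlock-class]) and `truth` ([SyntheticTruth-class]).
#' @examples
#' sim <- generateLinkedBlocks(n = 200, pBrain = 20, pBehav = 30,
#'                             kTrue = 2, crossBlockCorr = c(0.9, 0.7),
#'                             seed = 1)
#' sim$imaging
#' @export
generateLinkedBlocks <- function(n, pBrain = 120, pBehav = 200, kTrue = 2,
                                 crossBlockCorr = c(0.9, 0.7), noiseSd = 1,
                                 latentDist = c("laplace", "gaussian"),
                                 seed = 1) {
  latentDist <- match.arg(latentDist)
  stopIfNot(n >= 10, "n must be >= 10")
  stopIfNot(kTrue >= 1, "kTrue must be >= 1")
  stopIfNot(length(crossBlockCorr) == kTrue,
            "crossBlockCorr must have one entry per planted mode")
  stopIfNot(all(crossBlockCorr >= 0 & crossBlockCorr <= 1),
            "crossBlockCorr entries must lie in [0, 1]")
  noiseSd <- rep_len(noiseSd, 2)
  stopIfNot(all(noiseSd >= 0), "noiseSd must be non-negative")

  withSeed(seed, {
    rlat <- function(n, k) {
      if (latentDist == "laplace") {
        # standardized Laplace: sd 1, excess kurtosis 3
        u <- stats::runif(n * k) - 0.5
        matrix(-sign(u) * log(1 - 2 * abs(u)) / sqrt(2), n, k)
      } else matrix(stats::rnorm(n * k), n, k)
    }
    zShared <- rlat(n, kTrue)
    zBrain <- sweep(zShared, 2, sqrt(crossBlockCorr), "*") +
      sweep(rlat(n, kTrue), 2, sqrt(1 - crossBlockCorr), "*")
    zBehav <- sweep(zShared, 2, sqrt(crossBlockCorr), "*") +
      sweep(rlat(n, kTrue), 2, sqrt(1 - crossBlockCorr), "*")

    aBrain <- matrix(stats::rnorm(pBrain * kTrue), pBrain, kTrue)
    aBehav <- matrix(stats::rnorm(pBehav * kTrue), pBehav, kTrue)

    X <- zBrain %*% t(aBrain) +
      noiseSd[1] * matrix(stats::rnorm(n * pBrain), n, pBrain)
    Y <- zBehav %*% t(aBehav) +
      noiseSd[2] * matrix(stats::rnorm(n * pBehav), n, pBehav)

    ids <- sprintf("sub-%04d", seq_len(n))
    dimnames(X) <- list(ids, sprintf("brain_%03d", seq_len(pBrain)))
    dimnames(Y) <- list(ids, sprintf("behav_%03d", seq_len(pBehav)))
    rownames(zShared) <- rownames(zBrain) <- rownames(zBehav) <- ids

    truth <- new("SyntheticTruth",
                 latentFactors = zShared, brainLatents = zBrain,
                 behavLatents = zBehav, brainLoadings = aBrain,
                 behavLoadings = aBehav,
                 crossBlockCorr = as.numeric(crossBlockCorr),
                 noiseSdBrain = noiseSd[1], noiseSdBehav = noiseSd[2],
                 seed = as.integer(seed))
    list(imaging = DataBlock(X), behaviour = DataBlock(Y), truth = truth)
  })
}

#' Generate a synthetic confound table
#'
#' Builds the per-participant covariates the preprocessing stage removes:
#' scanner site and scan sequence (categorical), sex, age, household income
#' and a global-volume covariate (eTIV-like), plus a medication indicator.
#'
#' @param n number of participants (or a [DataBlock-class] whose IDs to use).
#' @param nSites number of scanner sites.
#' @param seed integer seed.
#' @return data.frame with a `participant_id` column and covariate columns
#'   `site`, `sequence`, `sex`, `age`, `income`, `etiv`, `medication`.
#' @export
generateConfoundTable <- function(n, nSites = 3, seed = 1) {
  ids <- if (is(n, "DataBlock")) participantIds(n) else sprintf("sub-%04d", seq_len(n))
  n <- length(ids)
  withSeed(seed, {
    data.frame(
      participant_id = ids,
      site = sample(paste0("site", LETTERS[seq_len(nSites)]), n, replace = TRUE),
      sequence = sample(c("seq1", "seq2"), n, replace = TRUE, prob = c(0.7, 0.3)),
      sex = sample(c("F", "M"), n, replace = TRUE),
      age = round(stats::runif(n, 5, 21), 2),
      income = round(exp(stats::rnorm(n, log(60), 0.5))), # thousands
      etiv = round(stats::rnorm(n, 1500, 120), 1),        # cm^3 scale
      medication = sample(c("no", "yes"), n, replace = TRUE, prob = c(0.83, 0.17)),
      stringsAsFactors = FALSE
    )
  })
}

#' Inject confound structure, missingness and extreme values into a block
#'
#' Adds additive confound effects, then sets a fraction of cells missing
#' completely at random, then replaces a fraction of the remaining observed
#' cells with extreme values at least 8 population SDs from the column mean
#' — far beyond any sensible cleaning threshold, so the cleaning stage's
#' effect is testable without tuning.
#'
#' @param block a [DataBlock-class].
#' @param confounds confound table with `participant_id` aligned to the
#'   block.
#' @param effects named list of additive effects. For a categorical confound
#'   give a named vector of per-level offsets (e.g. `list(site = c(siteB =
#'   5))`); for a continuous confound a single slope or a length-p vector of
#'   per-variable slopes (applied to the centered covariate).
#' @param missingRate,extremeRate cell fractions in [0, 0.5).
#' @param seed integer seed.
#' @return a new [DataBlock-class] with updated values and mask.
#' @export
injectConfoundsAndNoise <- function(block, confounds = NULL, effects = list(),
                                    missingRate = 0, extremeRate = 0, seed = 1) {
  stopIfNot(missingRate >= 0 && missingRate < 0.5,
            "missingRate must lie in [0, 0.5)")
  stopIfNot(extremeRate >= 0 && extremeRate < 0.5,
            "extremeRate must lie in [0, 0.5)")
  X <- blockValues(block)
  if (length(effects)) {
    stopIfNot(!is.null(confounds), "effects given but no confound table")
    checkAligned(block, confounds, "block and confound table")
    for (nm in names(effects)) {
      stopIfNot(nm %in% names(confounds),
                sprintf("confound '%s' not in the confound table", nm))
      covv <- confounds[[nm]]
      eff <- effects[[nm]]
      if (is.numeric(covv)) {
        slope <- rep_len(eff, ncol(X))
        X <- X + outer(covv - mean(covv), slope)
      } else {
        off <- rep(0, nrow(X))
        for (lev in names(eff)) off[covv == lev] <- off[covv == lev] + eff[[lev]]
        X <- X + off # recycled column-wise: same offset for every variable
      }
    }
  }
  withSeed(seed, {
    mask <- blockMask(block)
    ncell <- length(X)
    if (missingRate > 0) {
      drop <- which(stats::runif(ncell) < missingRate)
      mask[drop] <- FALSE
    }
    if (extremeRate > 0) {
      mu <- colMeans(X, na.rm = TRUE)
      sdv <- apply(X, 2, stats::sd, na.rm = TRUE)
      sdv[sdv == 0 | is.na(sdv)] <- 1
      obs <- which(mask)
      hit <- obs[stats::runif(length(obs)) < extremeRate]
      if (length(hit)) {
        colIdx <- ((hit - 1) %/% nrow(X)) + 1
        sgn <- sample(c(-1, 1), length(hit), replace = TRUE)
        mag <- stats::runif(length(hit), 8, 12)
        X[hit] <- mu[colIdx] + sgn * mag * sdv[colIdx]
      }
    }
    X[!mask] <- NA_real_
    DataBlock(X, mask)
  })
}

#' Assign synthetic diagnosis labels driven by one latent mode
#'
#' Emulates clinical labelling where the probability of carrying a diagnosis
#' (and the expected number of comorbid diagnoses) increases as the chosen
#' latent mode decreases: the diagnosis probability is
#' `plogis(qlogis(sum(baseRates)) - modeEffect * z)` with `z` the mode's
#' latent factor, so with `modeEffect = 0` per-category prevalences equal
#' `baseRates` exactly in expectation.
#'
#' @param truth a [SyntheticTruth-class].
#' @param baseRates named probability vector per diagnosis category,
#'   summing to <= 1 (remainder = "no diagnosis").
#' @param modeEffect finite real; > 0 means lower latent scores make
#'   diagnoses more likely.
#' @param modeIndex which latent factor drives the labels (default: factor 2
#'   when present, else 1).
#' @param meanExtra mean number of additional comorbid diagnoses for a
#'   diagnosed participant at `z = 0` (Poisson).
#' @param seed integer seed.
#' @return data.frame (`participant_id`, `primary_category`, `n_diagnoses`).
#' @export
assignDiagnoses <- function(truth,
                            baseRates = c(ADHD = 0.30, anxiety = 0.12,
                                          mood = 0.06, other = 0.05,
                                          otherND = 0.12),
                            modeEffect = 1, modeIndex = NULL,
                            meanExtra = 0.8, seed = 1) {
  stopIfNot(all(baseRates >= 0), "baseRates must be non-negative")
  total <- sum(baseRates)
  stopIfNot(total <= 1, "baseRates must sum to <= 1")
  stopIfNot(is.finite(modeEffect), "modeEffect must be finite")
  K <- ncol(truth@latentFactors)
  modeIndex <- modeIndex %||% min(2L, K)
  z <- truth@latentFactors[, modeIndex]
  n <- length(z)
  withSeed(seed, {
    p <- stats::plogis(stats::qlogis(total) - modeEffect * z)
    diagnosed <- stats::runif(n) < p
    cat <- rep("no diagnosis", n)
    nd <- sum(diagnosed)
    if (nd > 0) {
      cat[diagnosed] <- sample(names(baseRates), nd, replace = TRUE,
                               prob = baseRates / total)
    }
    lam <- meanExtra * exp(-modeEffect * z / 2)
    nDiag <- ifelse(diagnosed, 1L + stats::rpois(n, lam), 0L)
    data.frame(participant_id = rownames(truth@latentFactors) %||%
                 sprintf("sub-%04d", seq_len(n)),
               primary_category = cat, n_diagnoses = as.integer(nDiag),
               stringsAsFactors = FALSE)
  })
}
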