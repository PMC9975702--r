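#' @import methods
NULL

#' Participant-by-variable data block
#'
#' A numeric matrix of participants (rows) by variables (columns) together
#' with a logical missingness mask. Participant IDs are the rownames,
#' variable names the colnames; both must be unique. `mask[i, j]` is `TRUE`
#' iff `values[i, j]` is observed; unobserved cells hold `NA` in `values`.
#'
#' @slot values numeric matrix, participants x variables.
#' @slot mask logical matrix of identical shape; `TRUE` = observed.
#'
#' @export
setClass("DataBlock",
  representation(values = "matrix", mask = "matrix"),
  validity = function(object) {
    v <- object@values
    m <- object@mask
    msg <- character()
    if (!is.numeric(v)) msg <- c(msg, "'values' must be a numeric matrix")
    if (!is.logical(m)) msg <- c(msg, "'mask' must be a logical matrix")
    if (!identical(dim(v), dim(m))) msg <- c(msg, "'values' and 'mask' differ in shape")
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
      msg <- c(msg, "participant IDs (rownames) must be present and unique")
    if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
      msg <- c(msg, "variable names (colnames) must be present and unique")
    if (identical(dim(v), dim(m)) && is.numeric(v) && is.logical(m)) {
      if (any(is.na(m))) msg <- c(msg, "'mask' must not contain NA")
      else if (any(is.na(v[m]))) msg <- c(msg, "mask marks NA cells as observed")
      else if (any(!is.na(v[!m]))) msg <- c(msg, "unobserved cells must hold NA")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct a DataBlock
#'
#' @param values numeric matrix with unique rownames (participant IDs) and
#'   colnames (variable names). `NA` cells are taken as missing.
#' @param mask optional logical matrix; defaults to `!is.na(values)`.
#' @return A [DataBlock-class] object.
#' @examples
#' m <- matrix(rnorm(12), 4, 3,
#'   dimnames = list(paste0("p", 1:4), paste0("v", 1:3)))
#' DataBlock(m)
#' @export
DataBlock <- function(values, mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(mask)) mask <- !is.na(values)
  dimnames(mask) <- dimnames(values)
  values[!mask] <- NA_real_
  new("DataBlock", values = values, mask = mask)
}

#' Ground truth of a synthetic linked-block dataset
#'
#' Records the planted latent factors, loading matrices and generation
#' parameters so recovery of the planted modes can be scored exactly.
#'
#' @slot latentFactors participants x K matrix of shared latent factors
#'   (unit-variance scale).
#' @slot brainLatents,behavLatents participants x K side-specific latent
#'   scores (shared factor plus side noise, calibrated to `crossBlockCorr`).
#' @slot brainLoadings,behavLoadings variable loading matrices used to mix
#'   the latents into the observed blocks.
#' @slot crossBlockCorr per-mode target correlation between the two sides,
#'   each in [0, 1].
#' @slot noiseSdBrain,noiseSdBehav additive measurement-noise SDs.
#' @slot seed integer seed used for generation.
#' @export
setClass("SyntheticTruth",
  representation(
    latentFactors = "matrix", brainLatents = "matrix", behavLatents = "matrix",
    brainLoadings = "matrix", behavLoadings = "matrix",
    crossBlockCorr = "numeric", noiseSdBrain = "numeric",
    noiseSdBehav = "numeric", seed = "integer"
  ),
  validity = function(object) {
    r <- object@crossBlockCorr
    if (any(r < 0 | r > 1)) return("crossBlockCorr entries must lie in [0, 1]")
    if (ncol(object@latentFactors) != length(r))
      return("crossBlockCorr length must equal the number of latent factors")
    TRUE
  }
)

#' Principal component reduction of one block
#'
#' @slot basis variables x nComp matrix of orthonormal loadings (right
#'   singular vectors of the centered data).
#' @slot scores participants x nComp component scores (centered data times
#'   basis).
#' @slot explainedVariance variance of each component (non-increasing).
#' @slot center variable means removed before the decomposition.
#' @slot nComp number of components retained.
#' @export
setClass("PCAResult",
  representation(basis = "matrix", scores = "matrix",
                 explainedVariance = "numeric", center = "numeric",
                 nComp = "integer"))

#' Canonical correlation analysis of two score matrices
#'
#' @slot brainWeights,behavWeights weight matrices (input-dimension x K) on
#'   the PCA-score spaces; canonical variates have unit variance.
#' @slot U,V participants x K canonical variates for the brain and behaviour
#'   sides.
#' @slot canonicalCorrs the K canonical correlations, non-increasing in
#'   [0, 1].
#' @export
setClass("CCAResult",
  representation(brainWeights = "matrix", behavWeights = "matrix",
                 U = "matrix", V = "matrix", canonicalCorrs = "numeric"))

#' Fitted CCA-ICA mode decomposition
#'
#' The end product of the pipeline: an ICA rotation of the canonical variates
#' into interpretable modes, with composed projection matrices that map
#' de-confounded variables straight to participant mode loadings (the basis
#' of out-of-sample projection).
#'
#' @slot unmixing K x K ICA unmixing matrix estimated on the stacked
#'   canonical scores.
#' @slot brainModeLoadings,behavModeLoadings participants x K per-side
#'   participant mode loadings.
#' @slot modeCorrs per-mode Pearson correlation between the two sides,
#'   ordered non-increasing.
#' @slot brainProjection,behavProjection composed linear maps (variables x K)
#'   from centered de-confounded data to mode loadings.
#' @slot brainCenter,behavCenter training variable means subtracted before
#'   projection (near zero for residualised inputs).
#' @slot variableLoadings data.frame (variable, side, mode, loading):
#'   correlation of each original variable with its side's mode loadings.
#' @slot canonicalCorrs canonical correlations of the intermediate CCA.
#' @slot seed integer seed used for the ICA restarts.
#' @export
setClass("ModeSet",
  representation(
    unmixing = "matrix",
    brainModeLoadings = "matrix", behavModeLoadings = "matrix",
    modeCorrs = "numeric",
    brainProjection = "matrix", behavProjection = "matrix",
    brainCenter = "numeric", behavCenter = "numeric",
    variableLoadings = "data.frame",
    canonicalCorrs = "numeric",
    seed = "integer"
  ),
  validity = function(object) {
    K <- length(object@modeCorrs)
    if (!identical(dim(object@unmixing), c(K, K)))
      return("unmixing must be K x K")
    if (ncol(object@brainModeLoadings) != K || ncol(object@behavModeLoadings) != K)
      return("mode loading matrices must have K columns")
    if (is.unsorted(rev(object@modeCorrs), strictly = FALSE) &&
        is.unsorted(-object@modeCorrs))
      return("modeCorrs must be non-increasing")
    TRUE
  }
)

#' Report of the cleaning stage
#' @slot droppedVariables data.frame (name, reason).
#' @slot droppedParticipants data.frame (id, reason).
#' @slot cellsSetMissing count of cells blanked as extreme values.
#' @slot cellsImputed count of cells later filled by imputation (0 until the
#'   imputation stage updates it).
#' @export
setClass("CleaningReport",
  representation(droppedVariables = "data.frame",
                 droppedParticipants = "data.frame",
                 cellsSetMissing = "integer", cellsImputed = "integer"))

#' Permutation-test report with max-statistic FWE control
#' @slot statistic "cca" or "modes".
#' @slot observed observed per-component statistics.
#' @slot nullMax per-permutation maxima of the statistic.
#' @slot pFwe family-wise-error-corrected empirical p-values,
#'   `(1 + sum(nullMax >= observed)) / (1 + nPerm)`.
#' @slot nPerm,seed permutation count and seed.
#' @export
setClass("PermutationReport",
  representation(statistic = "character", observed = "numeric",
                 nullMax = "numeric", pFwe = "numeric",
                 nPerm = "integer", seed = "integer"))

#' Split-half reliability report
#' @slot candidates data.frame of candidate (pcaBrain, pcaBehav, K) triples.
#' @slot perSplit data.frame (candidate, split, mode, reliability).
#' @slot minReliability mean-over-splits min-over-modes reliability per
#'   candidate.
#' @slot chosen index (into `candidates`) of the selected dimensionality.
#' @slot nSplits,seed split count and seed.
#' @export
setClass("SplitHalfReport",
  representation(candidates = "data.frame", perSplit = "data.frame",
                 minReliability = "numeric", chosen = "integer",
                 nSplits = "integer", seed = "integer"))

#' Spin-permutation spatial-null report
#' @slot observedR observed Pearson correlation of the two maps.
#' @slot nullR per-spin correlations under the rotation null.
#' @slot pSpin two-sided empirical p, `(1 + sum(|nullR| >= |observedR|)) /
#'   (1 + nSpin)`.
#' @slot duplicates per-spin count of duplicated source parcels (always 0
#'   under the one-to-one matching default).
#' @slot nSpin,seed spin count and seed.
#' @export
setClass("SpinReport",
  representation(observedR = "numeric", nullR = "numeric", pSpin = "numeric",
                 duplicates = "integer", nSpin = "integer", seed = "integer"))

#' Bootstrap report for brain-loading vs phenotype correlations
#' @slot table data.frame (mode, phenotype, r, lower, upper, nExcluded).
#' @slot nBoot,seed bootstrap count and seed.
#' @export
setClass("BootstrapReport",
  representation(table = "data.frame", nBoot = "integer", seed = "integer"))
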