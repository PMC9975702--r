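#' @include AllClasses.R
NULL

#' Accessors for DataBlock and ModeSet objects
#'
#' `blockValues()` returns the participants x variables matrix,
#' `blockMask()` the logical observed-cell mask, `participantIds()` and
#' `variableNames()` the row and column identifiers. `nParticipants()` and
#' `nVariables()` give the block shape. For [ModeSet-class] objects,
#' `modeCorrs()`, `modeLoadings()`, `variableLoadings()` and
#' `nModes()` expose the fitted decomposition.
#'
#' @param x a [DataBlock-class] or [ModeSet-class] object.
#' @param side for `modeLoadings()`, `"brain"` or `"behaviour"`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("blockValues", function(x) standardGeneric("blockValues"))
#' @rdname accessors
#' @export
setGeneric("blockMask", function(x) standardGeneric("blockMask"))
#' @rdname accessors
#' @export
setGeneric("participantIds", function(x) standardGeneric("participantIds"))
#' @rdname accessors
#' @export
setGeneric("variableNames", function(x) standardGeneric("variableNames"))
#' @rdname accessors
#' @export
setGeneric("nParticipants", function(x) standardGeneric("nParticipants"))
#' @rdname accessors
#' @export
setGeneric("nVariables", function(x) standardGeneric("nVariables"))
#' @rdname accessors
#' @export
setGeneric("modeCorrs", function(x) standardGeneric("modeCorrs"))
#' @rdname accessors
#' @export
setGeneric("modeLoadings", function(x, side = c("brain", "behaviour"))
  standardGeneric("modeLoadings"))
#' @rdname accessors
#' @export
setGeneric("variableLoadings", function(x) standardGeneric("variableLoadings"))
#' @rdname accessors
#' @export
setGeneric("nModes", function(x) standardGeneric("nModes"))

#' @rdname accessors
setMethod("blockValues", "DataBlock", function(x) x@values)
#' @rdname accessors
setMethod("blockMask", "DataBlock", function(x) x@mask)
#' @rdname accessors
setMethod("participantIds", "DataBlock", function(x) rownames(x@values))
#' @rdname accessors
setMethod("variableNames", "DataBlock", function(x) colnames(x@values))
#' @rdname accessors
setMethod("nParticipants", "DataBlock", function(x) nrow(x@values))
#' @rdname accessors
setMethod("nVariables", "DataBlock", function(x) ncol(x@values))
#' @rdname accessors
setMethod("dim", "DataBlock", function(x) dim(x@values))

#' @rdname accessors
setMethod("modeCorrs", "ModeSet", function(x) x@modeCorrs)
#' @rdname accessors
setMethod("modeLoadings", "ModeSet", function(x, side = c("brain", "behaviour")) {
  side <- match.arg(side)
  if (side == "brain") x@brainModeLoadings else x@behavModeLoadings
})
#' @rdname accessors
setMethod("variableLoadings", "ModeSet", function(x) x@variableLoadings)
#' @rdname accessors
setMethod("nModes", "ModeSet", function(x) length(x@modeCorrs))

setMethod("show", "DataBlock", function(object) {
  nm <- sum(!object@mask)
  cat(sprintf("DataBlock: %d participants x %d variables (%d missing cells, %.2f%%)\n",
              nrow(object@values), ncol(object@values), nm,
              100 * nm / max(1, length(object@mask))))
})

setMethod("show", "ModeSet", function(object) {
  cat(sprintf("ModeSet with %d mode(s)\n", length(object@modeCorrs)))
  cat("  mode correlations:",
      paste(sprintf("%.3f", object@modeCorrs), collapse = ", "), "\n")
  cat(sprintf("  projections: brain %d x %d, behaviour %d x %d\n",
              nrow(object@brainProjection), ncol(object@brainProjection),
              nrow(object@behavProjection), ncol(object@behavProjection)))
})

setMethod("show", "PermutationReport", function(object) {
  cat(sprintf("PermutationReport (%s statistic, %d permutations)\n",
              object@statistic, object@nPerm))
  print(data.frame(component = seq_along(object@observed),
                   observed = round(object@observed, 4),
                   pFWE = round(object@pFwe, 5)), row.names = FALSE)
})

setMethod("show", "SpinReport", function(object) {
  cat(sprintf("SpinReport: r = %.3f, p_spin = %.4f (%d spins)\n",
              object@observedR, object@pSpin, object@nSpin))
})

setMethod("show", "SplitHalfReport", function(object) {
  cat(sprintf("SplitHalfReport: %d candidate(s), %d split(s)\n",
              nrow(object@candidates), object@nSplits))
  tab <- cbind(object@candidates, minReliability = round(object@minReliability, 3))
  print(tab, row.names = FALSE)
  cat("chosen:", object@chosen, "\n")
})

setMethod("show", "BootstrapReport", function(object) {
  cat(sprintf("BootstrapReport (%d bootstraps)\n", object@nBoot))
  print(object@table, row.names = FALSE)
})
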