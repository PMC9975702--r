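#' Read / write the tab-separated block format
#'
#' Blocks are exchanged as TSV with a `participant_id` first column and one
#' column per variable; missing cells are empty strings.
#'
#' @param block a [DataBlock-class].
#' @param path file path.
#' @return `writeDataBlock()` returns `path` invisibly; `readDataBlock()`
#'   returns a [DataBlock-class].
#' @export
writeDataBlock <- function(block, path) {
  X <- blockValues(block)
  df <- data.frame(participant_id = participantIds(block), X,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname writeDataBlock
#' @export
readDataBlock <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = "",
                          stringsAsFactors = FALSE)
  stopIfNot("participant_id" %in% names(df),
            "block file lacks a participant_id column")
  ids <- as.character(df$participant_id)
  X <- as.matrix(df[, setdiff(names(df), "participant_id"), drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- ids
  DataBlock(X)
}

#' Read / write confound tables
#'
#' Tab-separated with a `participant_id` column; character columns are kept
#' as categorical covariates.
#' @param confounds a confound data.frame.
#' @param path file path.
#' @export
writeConfoundTable <- function(confounds, path) {
  utils::write.table(confounds, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' @rdname writeConfoundTable
#' @export
readConfoundTable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = "",
                          stringsAsFactors = FALSE)
  stopIfNot("participant_id" %in% names(df),
            "confound file lacks a participant_id column")
  df$participant_id <- as.character(df$participant_id)
  df
}

#' Save synthetic ground truth as a JSON sidecar
#' @param truth a [SyntheticTruth-class].
#' @param path JSON path.
#' @export
writeSyntheticTruth <- function(truth, path) {
  jsonlite::write_json(list(
    latent_factors = truth@latentFactors,
    brain_latents = truth@brainLatents,
    behav_latents = truth@behavLatents,
    brain_loadings = truth@brainLoadings,
    behav_loadings = truth@behavLoadings,
    cross_block_corr = truth@crossBlockCorr,
    noise_sd_brain = truth@noiseSdBrain,
    noise_sd_behav = truth@noiseSdBehav,
    seed = truth@seed), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Serialize a fitted ModeSet to a directory
#'
#' Writes `variable_loadings.tsv`, `participant_loadings.tsv`,
#' `projection_brain.tsv`, `projection_behav.tsv` and `summary.json`.
#'
#' @param modes a [ModeSet-class].
#' @param dir output directory (created if needed).
#' @export
writeModeSet <- function(modes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(modes@variableLoadings,
                     file.path(dir, "variable_loadings.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  K <- nModes(modes)
  pl <- rbind(
    data.frame(id = rownames(modes@brainModeLoadings), side = "brain",
               mode = rep(seq_len(K), each = nrow(modes@brainModeLoadings)),
               loading = as.vector(modes@brainModeLoadings)),
    data.frame(id = rownames(modes@behavModeLoadings), side = "behaviour",
               mode = rep(seq_len(K), each = nrow(modes@behavModeLoadings)),
               loading = as.vector(modes@behavModeLoadings)))
  utils::write.table(pl, file.path(dir, "participant_loadings.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  writeProj <- function(P, ctr, f) {
    df <- data.frame(variable = rownames(P), center = ctr, P,
                     check.names = FALSE)
    utils::write.table(df, file.path(dir, f), sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  writeProj(modes@brainProjection, modes@brainCenter, "projection_brain.tsv")
  writeProj(modes@behavProjection, modes@behavCenter, "projection_behav.tsv")
  jsonlite::write_json(list(mode_corrs = modes@modeCorrs,
                            canonical_corrs = modes@canonicalCorrs,
                            unmixing = modes@unmixing,
                            seed = modes@seed),
                       file.path(dir, "summary.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a serialized ModeSet directory
#' @param dir directory written by [writeModeSet()].
#' @return a [ModeSet-class].
#' @export
readModeSet <- function(dir) {
  vl <- utils::read.delim(file.path(dir, "variable_loadings.tsv"),
                          stringsAsFactors = FALSE)
  pl <- utils::read.delim(file.path(dir, "participant_loadings.tsv"),
                          stringsAsFactors = FALSE)
  smry <- jsonlite::read_json(file.path(dir, "summary.json"),
                              simplifyVector = TRUE)
  readProj <- function(f) {
    df <- utils::read.delim(file.path(dir, f), check.names = FALSE,
                            stringsAsFactors = FALSE)
    P <- as.matrix(df[, setdiff(names(df), c("variable", "center")),
                      drop = FALSE])
    rownames(P) <- df$variable
    list(P = P, center = df$center)
  }
  pb <- readProj("projection_brain.tsv")
  py <- readProj("projection_behav.tsv")
  K <- length(smry$mode_corrs)
  sideMat <- function(sideName) {
    sub <- pl[pl$side == sideName, ]
    m <- matrix(sub$loading, ncol = K)
    rownames(m) <- sub$id[sub$mode == 1]
    colnames(m) <- paste0("mode", seq_len(K))
    m
  }
  new("ModeSet",
      unmixing = matrix(as.numeric(smry$unmixing), K, K),
      brainModeLoadings = sideMat("brain"),
      behavModeLoadings = sideMat("behaviour"),
      modeCorrs = as.numeric(smry$mode_corrs),
      brainProjection = pb$P, behavProjection = py$P,
      brainCenter = pb$center, behavCenter = py$center,
      variableLoadings = vl,
      canonicalCorrs = as.numeric(smry$canonical_corrs),
      seed = as.integer(smry$seed))
}

#' Read / write parcel geometry CSV (`parcel,hemi,x,y,z,is_surface`)
#' @param geometry geometry data.frame from [parcelGeometry()].
#' @param path CSV path.
#' @export
writeParcelGeometry <- function(geometry, path) {
  utils::write.csv(geometry, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeParcelGeometry
#' @export
readParcelGeometry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  parcelGeometry(df$parcel, df$hemi, df$x, df$y, df$z, as.logical(df$is_surface))
}

#' Write a permutation / spin / bootstrap report as JSON
#' @param report a report object.
#' @param path JSON path.
#' @export
writeReport <- function(report, path) {
  lst <- if (is(report, "PermutationReport")) {
    list(statistic = report@statistic, observed = report@observed,
         p_fwe = report@pFwe, n_perm = report@nPerm,
         null_max = report@nullMax, seed = report@seed)
  } else if (is(report, "SpinReport")) {
    list(observed_r = report@observedR, p_spin = report@pSpin,
         n_spin = report@nSpin, null_r = report@nullR, seed = report@seed)
  } else if (is(report, "BootstrapReport")) {
    list(table = report@table, n_boot = report@nBoot, seed = report@seed)
  } else if (is(report, "SplitHalfReport")) {
    list(candidates = report@candidates, per_split = report@perSplit,
         min_reliability = report@minReliability, chosen = report@chosen,
         n_splits = report@nSplits, seed = report@seed)
  } else stop("unsupported report class")
  jsonlite::write_json(lst, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}
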