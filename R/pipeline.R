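#' Default run configuration
#'
#' A nested list of every stage parameter with its default, serializable to
#' and from YAML. Stage blocks: `simulate` (only used when no input files
#' are given), `preprocess`, `decompose`, `splithalf`, `permtest`,
#' `project`, `associate`, plus top-level `seed` and `out_dir`.
#'
#' @return nested configuration list.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    out_dir = "ccamodes-run",
    inputs = list(imaging = NULL, behaviour = NULL, confounds = NULL),
    simulate = list(n = 500L, p_brain = 120L, p_behav = 200L, k_true = 2L,
                    rho = c(0.9, 0.7), noise_sd = 1, missing_rate = 0.02,
                    extreme_rate = 0.005, paper_scale = FALSE),
    preprocess = list(z_extreme = 4, max_var_missing = 0.5,
                      max_participant_missing = 0.5, k_impute = 1L,
                      int_variant = "blom",
                      residualise = c("site", "sequence"),
                      volumetric_vars = character(),
                      global_covariate = "etiv"),
    decompose = list(pca_brain = NULL, pca_behav = NULL, k = 2L,
                     n_restarts = 5L),
    splithalf = list(enabled = FALSE, candidates = list(), n_splits = 10L),
    permtest = list(enabled = TRUE, n_perm = 1000L, stat = "modes",
                    ica_in_null = TRUE),
    project = list(enabled = FALSE, imaging = NULL, phenotypes = NULL,
                   geometry = NULL, n_spin = 1000L, n_boot = 1000L),
    associate = list(enabled = FALSE, diagnosis = NULL)
  )
}

#' Read and validate a YAML run configuration
#'
#' Values in the file override the defaults from [defaultRunConfig()];
#' schema violations are rejected before any computation.
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  validateRunConfig(mergeConfig(defaultRunConfig(), user))
}

mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- mergeConfig(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' @rdname readRunConfig
#' @param config configuration list to validate.
#' @export
validateRunConfig <- function(config) {
  known <- names(defaultRunConfig())
  extra <- setdiff(names(config), known)
  stopIfNot(!length(extra),
            paste("unknown config keys:", paste(extra, collapse = ", ")))
  stopIfNot(is.numeric(config$seed) && length(config$seed) == 1,
            "seed must be a single integer")
  config$seed <- as.integer(config$seed)
  config$permtest$n_perm <- as.integer(config$permtest$n_perm)
  config$decompose$k <- as.integer(config$decompose$k)
  config$simulate$n <- as.integer(config$simulate$n)
  config$splithalf$n_splits <- as.integer(config$splithalf$n_splits)
  stopIfNot(config$permtest$n_perm >= 100,
            "permtest$n_perm must be >= 100 (empirical p-value resolution)")
  stopIfNot(config$decompose$k >= 1, "decompose$k must be >= 1")
  stopIfNot(config$preprocess$z_extreme > 0, "z_extreme must be positive")
  stopIfNot(config$simulate$missing_rate >= 0 && config$simulate$missing_rate < 0.5,
            "simulate$missing_rate must lie in [0, 0.5)")
  stopIfNot(config$permtest$stat %in% c("modes", "cca"),
            "permtest$stat must be 'modes' or 'cca'")
  if (isTRUE(config$project$enabled))
    stopIfNot(config$project$n_boot >= 100, "project$n_boot must be >= 100")
  config
}

#' Run the full pipeline into a run directory
#'
#' Executes simulate (when no input files are configured) or load,
#' preprocess, optional split-half dimensionality selection, decomposition,
#' permutation testing and the optional projection and association stages,
#' writing every output plus a `manifest.json` (MD5 per file) and a
#' `config.yaml` echo into `config$out_dir`. Inputs on disk are never
#' modified.
#'
#' @param config configuration list (see [defaultRunConfig()] /
#'   [readRunConfig()]).
#' @return invisibly, the run directory path.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  config <- validateRunConfig(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  logLines <- character()
  logIt <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    logLines <<- c(logLines, line)
    message(line)
  }

  # ---- inputs ----
  if (is.null(config$inputs$imaging)) {
    sc <- config$simulate
    if (isTRUE(sc$paper_scale)) { sc$n <- 1732L; sc$p_behav <- 793L; sc$p_brain <- 447L }
    logIt("simulate: n=%d pBrain=%d pBehav=%d k=%d rho=%s seed=%d",
          sc$n, sc$p_brain, sc$p_behav, sc$k_true,
          paste(sc$rho, collapse = ","), seed)
    sim <- generateLinkedBlocks(sc$n, sc$p_brain, sc$p_behav, sc$k_true,
                                sc$rho, sc$noise_sd, seed = seed)
    conf <- generateConfoundTable(sim$imaging, seed = childSeed(seed, 11))
    imaging <- injectConfoundsAndNoise(sim$imaging, conf,
                                       effects = list(site = c(siteB = 0.5)),
                                       missingRate = sc$missing_rate,
                                       extremeRate = sc$extreme_rate,
                                       seed = childSeed(seed, 12))
    behaviour <- injectConfoundsAndNoise(sim$behaviour, conf,
                                         missingRate = sc$missing_rate,
                                         extremeRate = sc$extreme_rate,
                                         seed = childSeed(seed, 13))
    writeDataBlock(imaging, file.path(out, "imaging_raw.tsv"))
    writeDataBlock(behaviour, file.path(out, "behaviour_raw.tsv"))
    writeConfoundTable(conf, file.path(out, "confounds.tsv"))
    writeSyntheticTruth(sim$truth, file.path(out, "truth.json"))
  } else {
    imaging <- readDataBlock(config$inputs$imaging)
    behaviour <- readDataBlock(config$inputs$behaviour)
    conf <- if (!is.null(config$inputs$confounds))
      readConfoundTable(config$inputs$confounds) else NULL
    logIt("loaded inputs: imaging %s, behaviour %s",
          config$inputs$imaging, config$inputs$behaviour)
  }

  # ---- preprocess ----
  pc <- config$preprocess
  resSpec <- intersect(pc$residualise, names(conf) %||% character())
  prepOne <- function(block, label) {
    pr <- preprocessBlock(block, conf, confoundSpec = resSpec,
                          volumetricVars = pc$volumetric_vars,
                          globalCovariate = pc$global_covariate,
                          zExtreme = pc$z_extreme,
                          maxVarMissing = pc$max_var_missing,
                          maxParticipantMissing = pc$max_participant_missing,
                          k = pc$k_impute, variant = pc$int_variant)
    logIt("preprocess(%s): %d extreme cells blanked, %d imputed, %d vars / %d participants dropped",
          label, pr$report@cellsSetMissing, pr$report@cellsImputed,
          nrow(pr$report@droppedVariables), nrow(pr$report@droppedParticipants))
    pr
  }
  prX <- tryCatch(prepOne(imaging, "imaging"),
                  error = function(e) stop("preprocess(imaging): ",
                                           conditionMessage(e), call. = FALSE))
  prY <- tryCatch(prepOne(behaviour, "behaviour"),
                  error = function(e) stop("preprocess(behaviour): ",
                                           conditionMessage(e), call. = FALSE))
  shared <- intersect(participantIds(prX$block), participantIds(prY$block))
  subsetBlock <- function(b) DataBlock(blockValues(b)[shared, , drop = FALSE])
  X <- subsetBlock(prX$block); Y <- subsetBlock(prY$block)
  if (!is.null(conf)) conf <- conf[match(shared, conf$participant_id), , drop = FALSE]
  writeDataBlock(X, file.path(out, "imaging_preprocessed.tsv"))
  writeDataBlock(Y, file.path(out, "behaviour_preprocessed.tsv"))

  # ---- dimensionality ----
  dc <- config$decompose
  dims <- c(dc$pca_brain %||% min(length(shared) - 1, nVariables(X), 100),
            dc$pca_behav %||% min(length(shared) - 1, nVariables(Y), 100),
            dc$k)
  if (isTRUE(config$splithalf$enabled) && length(config$splithalf$candidates)) {
    sel <- selectDimensionality(X, Y, config$splithalf$candidates,
                                nSplits = config$splithalf$n_splits,
                                seed = childSeed(seed, 2),
                                site = conf$site)
    writeReport(sel$report, file.path(out, "splithalf.json"))
    dims <- sel$chosen
    logIt("splithalf: chose dims (%d, %d, %d)", dims[1], dims[2], dims[3])
  }

  # ---- decompose ----
  modes <- runFullDecomposition(X, Y, nCompBrain = dims[1],
                                nCompBehav = dims[2], K = dims[3],
                                seed = childSeed(seed, 3),
                                nRestarts = dc$n_restarts)
  writeModeSet(modes, file.path(out, "modes"))
  logIt("decompose: mode correlations %s",
        paste(sprintf("%.3f", modeCorrs(modes)), collapse = ", "))

  # ---- permutation inference ----
  if (isTRUE(config$permtest$enabled)) {
    tc <- config$permtest
    rep <- if (tc$stat == "modes")
      permutationTestModes(X, Y, K = dims[3], nCompBrain = dims[1],
                           nCompBehav = dims[2], nPerm = tc$n_perm,
                           seed = childSeed(seed, 4),
                           icaInNull = isTRUE(tc$ica_in_null))
    else
      permutationTestCCA(X, Y, K = dims[3], nCompBrain = dims[1],
                         nCompBehav = dims[2], nPerm = tc$n_perm,
                         seed = childSeed(seed, 4))
    writeReport(rep, file.path(out, "permtest.json"))
    logIt("permtest(%s): p_fwe %s", tc$stat,
          paste(sprintf("%.4g", rep@pFwe), collapse = ", "))
  }

  # ---- associate (optional; uses synthetic labels when simulated) ----
  if (isTRUE(config$associate$enabled) && !is.null(config$associate$diagnosis)) {
    dg <- config$associate$diagnosis
    if (is.character(dg) && length(dg) == 1) dg <- utils::read.delim(dg)
    dg <- dg[match(shared, dg$participant_id), ]
    for (k in seq_len(nModes(modes))) {
      ct <- diagnosisContrasts(modes@behavModeLoadings[, k],
                               dg$primary_category, conf)
      utils::write.table(ct, file.path(out, sprintf("contrasts_mode%d.tsv", k)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    logIt("associate: contrast tables written")
  }

  # ---- manifest ----
  writeLines(logLines, file.path(out, "run.log"))
  yaml::write_yaml(config, file.path(out, "config.yaml"))
  files <- setdiff(list.files(out, recursive = TRUE), "manifest.json")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out, files))),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(out)
}
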