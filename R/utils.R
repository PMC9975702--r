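# internal helpers shared across modules

# run expr with a local RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a child seed deterministically, kept below 2^31
childSeed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# coerce DataBlock or matrix to a plain numeric matrix
asValues <- function(x) {
  if (is(x, "DataBlock")) x@values else as.matrix(x)
}

# check two blocks (or a block and a confound table) share row order
checkAligned <- function(a, b, what = "blocks") {
  ia <- if (is(a, "DataBlock")) participantIds(a) else rownames(a)
  ib <- if (is(b, "DataBlock")) participantIds(b) else b$participant_id %||% rownames(b)
  if (is.null(ia) || is.null(ib) || !identical(as.character(ia), as.character(ib)))
    stop(sprintf("%s are not row-aligned: participant IDs differ or are missing", what),
         call. = FALSE)
  invisible(TRUE)
}

# robust z-scores per column (median / MAD); columns with MAD 0 fall back to
# mean/sd so genuinely extreme cells are still detectable
robustZ <- function(x) {
  med <- apply(x, 2, stats::median, na.rm = TRUE)
  s <- apply(x, 2, stats::mad, na.rm = TRUE)
  alt <- apply(x, 2, stats::sd, na.rm = TRUE)
  s[s == 0 | is.na(s)] <- alt[s == 0 | is.na(s)]
  s[s == 0 | is.na(s)] <- Inf # constant column: nothing is extreme
  sweep(sweep(x, 2, med, "-"), 2, s, "/")
}

# column-center a matrix, returning the matrix and the centers
centerColumns <- function(x) {
  mu <- colMeans(x)
  list(x = sweep(x, 2, mu, "-"), center = mu)
}

# empirical FWE p-values from a max-statistic null
fwePValues <- function(observed, nullMax) {
  vapply(observed, function(o) (1 + sum(nullMax >= o)) / (1 + length(nullMax)),
         numeric(1))
}

# Pearson correlation that returns NA (not an error) for constant input
safeCor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
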