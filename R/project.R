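#' Parcel geometry for spin tests
#'
#' Builds and validates the parcel-centroid table used by the spin
#' permutation null: one row per parcel with hemisphere membership and a
#' unit-sphere centroid for surface parcels. Non-surface features
#' (subcortical volumes, global summaries) carry `is_surface = FALSE` and no
#' meaningful centroid.
#'
#' @param parcel character vector of unique parcel names.
#' @param hemi `"left"`, `"right"` or `"none"` per parcel.
#' @param x,y,z centroid coordinates (normalised to unit length for surface
#'   parcels).
#' @param is_surface logical per parcel (default: `hemi != "none"`).
#' @return data.frame with columns `parcel`, `hemi`, `x`, `y`, `z`,
#'   `is_surface`.
#' @export
parcelGeometry <- function(parcel, hemi, x, y, z, is_surface = NULL) {
  stopIfNot(!anyDuplicated(parcel), "parcel names must be unique")
  stopIfNot(all(hemi %in% c("left", "right", "none")),
            "hemi must be 'left', 'right' or 'none'")
  is_surface <- is_surface %||% (hemi != "none")
  g <- data.frame(parcel = as.character(parcel), hemi = hemi,
                  x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                  is_surface = as.logical(is_surface),
                  stringsAsFactors = FALSE)
  nrm <- sqrt(g$x^2 + g$y^2 + g$z^2)
  surf <- g$is_surface
  stopIfNot(all(nrm[surf] > 0), "surface parcels need non-zero centroids")
  g$x[surf] <- g$x[surf] / nrm[surf]
  g$y[surf] <- g$y[surf] / nrm[surf]
  g$z[surf] <- g$z[surf] / nrm[surf]
  g
}

#' Synthetic spherical parcel geometry
#'
#' Places `nPerHemi` parcels per hemisphere at quasi-uniform points on the
#' unit sphere (Fibonacci lattice, mirrored across the midsagittal plane),
#' for testing spin permutations without an atlas.
#'
#' @param nPerHemi surface parcels per hemisphere (default 34, matching a
#'   Desikan-Killiany-sized parcellation).
#' @param nOther additional non-surface features.
#' @return geometry data.frame as in [parcelGeometry()].
#' @export
syntheticGeometry <- function(nPerHemi = 34, nOther = 0) {
  i <- seq_len(nPerHemi) - 0.5
  phi <- acos(1 - 2 * i / nPerHemi)
  theta <- pi * (1 + sqrt(5)) * i
  pts <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  pts[, 1] <- abs(pts[, 1]) # keep left-hemisphere x positive pre-mirror
  parcelGeometry(
    parcel = c(sprintf("lh_parcel%02d", seq_len(nPerHemi)),
               sprintf("rh_parcel%02d", seq_len(nPerHemi)),
               if (nOther > 0) sprintf("other%02d", seq_len(nOther))),
    hemi = c(rep("left", nPerHemi), rep("right", nPerHemi),
             rep("none", nOther)),
    x = c(pts[, 1], -pts[, 1], rep(0, nOther)),
    y = c(pts[, 2], pts[, 2], rep(0, nOther)),
    z = c(pts[, 3], pts[, 3], rep(0, nOther)))
}

#' Project mode weights onto a new cohort
#'
#' Applies the imaging-side projection matrix of a fitted [ModeSet-class] to
#' a new, independently preprocessed imaging block: `loadings = (X - center)
#' %*% brainProjection`, with variables matched by name (order-independent).
#' Training variables absent from the new block are an error — never
#' silently zero-filled. The training center is near zero whenever the
#' training data were residualised, making the map effectively linear.
#'
#' @param newImaging preprocessed [DataBlock-class] (or matrix) for the new
#'   cohort.
#' @param modes fitted [ModeSet-class] with variable-space projections.
#' @param aliases optional named character vector mapping training variable
#'   names to the new cohort's names (`c(train_name = "new_name")`), for
#'   harmonised-protocol scenarios.
#' @return participants x K matrix of projected brain mode loadings.
#' @export
projectOutOfSample <- function(newImaging, modes, aliases = NULL) {
  X <- asValues(newImaging)
  trainVars <- rownames(modes@brainProjection)
  stopIfNot(!is.null(trainVars), "ModeSet lacks variable-space projections")
  lookup <- trainVars
  if (!is.null(aliases)) {
    hit <- trainVars %in% names(aliases)
    lookup[hit] <- aliases[trainVars[hit]]
  }
  missingVars <- setdiff(lookup, colnames(X))
  if (length(missingVars))
    stop(paste("training variables missing from the new block:",
               paste(missingVars, collapse = ", ")), call. = FALSE)
  Xm <- X[, lookup, drop = FALSE]
  ctr <- if (length(modes@brainCenter)) modes@brainCenter else
    rep(0, ncol(Xm))
  out <- sweep(Xm, 2, ctr, "-") %*% modes@brainProjection
  rownames(out) <- rownames(X)
  out
}

# uniform random rotation in SO(3): QR of a Gaussian matrix with the sign
# convention R_ii > 0, det flipped to +1 if needed
randomRotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qrd)
  d <- sign(diag(qr.R(qrd)))
  Q <- Q %*% diag(d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# one-to-one greedy nearest matching between rotated and original centroids;
# returns for each target parcel the index of the source parcel whose
# rotated centroid is nearest among those still unassigned
greedyAssign <- function(orig, rotated) {
  m <- nrow(orig)
  D <- 2 - 2 * tcrossprod(orig, rotated) # squared chord distance on sphere
  ord <- order(D)
  srcFor <- integer(m); usedSrc <- logical(m); usedTgt <- logical(m)
  left <- m
  for (e in ord) {
    tgt <- (e - 1L) %% m + 1L
    src <- (e - 1L) %/% m + 1L
    if (usedTgt[tgt] || usedSrc[src]) next
    srcFor[tgt] <- src; usedTgt[tgt] <- TRUE; usedSrc[src] <- TRUE
    left <- left - 1
    if (!left) break
  }
  srcFor
}

#' Spatial-map correlation with a spin-permutation null
#'
#' Correlates two per-parcel weight maps and tests the correlation against a
#' spatial null that preserves each map's spatial autocorrelation: for each
#' spin a uniform random rotation of the sphere is applied to the left
#' hemisphere's centroids and its midsagittal mirror to the right
#' hemisphere's, parcels are reassigned to the rotated positions, and map A
#' is recomputed under the reassignment. Non-surface features are freely
#' permuted among themselves within each spin. The default one-to-one
#' matching makes every spin a permutation of the map values (value multiset
#' preserved); `oneToOne = FALSE` uses plain nearest-centroid reassignment,
#' which may duplicate source parcels (duplicates are counted per spin).
#'
#' @param mapA,mapB named numeric vectors of per-parcel weights, aligned to
#'   `geometry$parcel`.
#' @param geometry parcel table from [parcelGeometry()].
#' @param nSpin number of spins (>= 100 recommended; the reference analysis
#'   used 1000).
#' @param seed integer seed.
#' @param oneToOne use one-to-one greedy matching (default `TRUE`).
#' @return a [SpinReport-class]; the p-value is two-sided on |r|.
#' @export
spatialMapCorrelation <- function(mapA, mapB, geometry, nSpin = 1000,
                                  seed = 1, oneToOne = TRUE) {
  stopIfNot(length(mapA) == nrow(geometry) && length(mapB) == nrow(geometry),
            "maps must align with the geometry")
  if (!is.null(names(mapA)))
    stopIfNot(identical(names(mapA), geometry$parcel),
              "mapA names do not match the geometry parcels")
  if (stats::sd(mapA) == 0 || stats::sd(mapB) == 0)
    stop("constant map: correlation undefined", call. = FALSE)
  hemis <- c("left", "right")
  surfIdx <- lapply(hemis, function(h) which(geometry$is_surface & geometry$hemi == h))
  names(surfIdx) <- hemis
  stopIfNot(all(vapply(surfIdx, length, integer(1)) >= 10) ||
              sum(geometry$is_surface) == 0,
            "need >= 10 surface parcels per hemisphere")
  otherIdx <- which(!geometry$is_surface)
  coords <- as.matrix(geometry[, c("x", "y", "z")])
  mirror <- diag(c(-1, 1, 1))

  observed <- stats::cor(mapA, mapB)
  nullR <- numeric(nSpin); dups <- integer(nSpin)
  withSeed(seed, {
    for (s in seq_len(nSpin)) {
      spun <- mapA
      R0 <- randomRotation()
      for (h in hemis) {
        idx <- surfIdx[[h]]
        if (!length(idx)) next
        Rh <- if (h == "left") R0 else mirror %*% R0 %*% mirror
        rot <- coords[idx, , drop = FALSE] %*% t(Rh)
        if (oneToOne) {
          src <- greedyAssign(coords[idx, , drop = FALSE], rot)
        } else {
          D <- 2 - 2 * tcrossprod(coords[idx, , drop = FALSE], rot)
          src <- apply(D, 1, which.min)
          dups[s] <- dups[s] + sum(duplicated(src))
        }
        spun[idx] <- mapA[idx][src]
      }
      if (length(otherIdx) > 1)
        spun[otherIdx] <- mapA[otherIdx][sample(length(otherIdx))]
      nullR[s] <- stats::cor(spun, mapB)
    }
  })
  new("SpinReport", observedR = observed, nullR = nullR,
      pSpin = (1 + sum(abs(nullR) >= abs(observed))) / (1 + nSpin),
      duplicates = dups, nSpin = as.integer(nSpin), seed = as.integer(seed))
}

#' Bootstrap CIs for projected brain loadings vs phenotypes
#'
#' For each bootstrap resample (participants drawn with replacement) the new
#' cohort's imaging block is projected through the training mode weights and
#' the resulting brain loadings are correlated with each phenotype,
#' optionally partialling out covariates (both sides residualised). The 2.5
#' and 97.5 percentiles of the bootstrap distribution give the 95% CI.
#' Resamples where a phenotype or loading is constant are excluded from that
#' entry's distribution, with the exclusion count reported.
#'
#' @param newImaging preprocessed [DataBlock-class] for the cohort.
#' @param modes fitted [ModeSet-class].
#' @param phenotypes data.frame of numeric phenotype columns, row-aligned
#'   with the block (a `participant_id` column, if present, is checked and
#'   dropped).
#' @param nBoot number of bootstrap resamples (>= 100; the reference
#'   analysis used 1000).
#' @param seed integer seed.
#' @param partialCovariates optional data.frame of covariates to partial out
#'   (e.g. age), row-aligned.
#' @return a [BootstrapReport-class].
#' @export
bootstrapPhenotypeCorrelations <- function(newImaging, modes, phenotypes,
                                           nBoot = 1000, seed = 1,
                                           partialCovariates = NULL) {
  stopIfNot(nBoot >= 100, "nBoot must be >= 100")
  if ("participant_id" %in% names(phenotypes)) {
    checkAligned(newImaging, phenotypes, "block and phenotype table")
    phenotypes <- phenotypes[, setdiff(names(phenotypes), "participant_id"),
                             drop = FALSE]
  }
  X <- asValues(newImaging)
  n <- nrow(X)
  stopIfNot(nrow(phenotypes) == n, "phenotypes must align with the block")
  L <- projectOutOfSample(newImaging, modes)
  K <- ncol(L)
  P <- as.matrix(phenotypes)

  corOnce <- function(rows) {
    Lb <- L[rows, , drop = FALSE]; Pb <- P[rows, , drop = FALSE]
    if (!is.null(partialCovariates)) {
      cv <- partialCovariates[rows, , drop = FALSE]
      Lb <- residCovariates(Lb, cv)
      Pb <- residCovariates(Pb, cv)
    }
    out <- matrix(NA_real_, K, ncol(P))
    for (k in seq_len(K)) for (j in seq_len(ncol(P)))
      out[k, j] <- safeCor(Lb[, k], Pb[, j])
    out
  }
  point <- corOnce(seq_len(n))
  draws <- withSeed(seed, {
    arr <- array(NA_real_, c(nBoot, K, ncol(P)))
    for (b in seq_len(nBoot)) arr[b, , ] <- corOnce(sample(n, replace = TRUE))
    arr
  })
  rows <- list()
  for (k in seq_len(K)) for (j in seq_len(ncol(P))) {
    d <- draws[, k, j]
    ok <- !is.na(d)
    q <- stats::quantile(d[ok], c(0.025, 0.975), names = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      mode = k, phenotype = colnames(P)[j], r = point[k, j],
      lower = q[1], upper = q[2], nExcluded = sum(!ok))
  }
  new("BootstrapReport", table = do.call(rbind, rows),
      nBoot = as.integer(nBoot), seed = as.integer(seed))
}
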