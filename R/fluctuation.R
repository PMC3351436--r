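.subsetRange <- function(traj, range) {
  stopifnot(is(traj, "Trajectory"))
  if (length(range) != 2L || range[1] > range[2])
    stop("range must be c(first, last) with first <= last")
  wanted <- seq.int(range[1], range[2])
  missing <- setdiff(wanted, traj@residueIds)
  if (length(missing))
    stop("range residues missing from trajectory: ",
         paste(missing, collapse = ", "))
  idx <- match(wanted, traj@residueIds)
  list(coords = traj@coords[, idx, , drop = FALSE], ids = as.integer(wanted))
}

# per-frame condensed distance vector; two-pass statistics keep the variance
# numerically clean at the 1e-10 tolerances the matrices are tested to
.pairDistances <- function(coords, f) {
  stats::dist(coords[f, , ])
}

#' Distance-fluctuation matrix of a trajectory
#'
#' Computes DF(i,j) = <(d_ij - <d_ij>)^2> over frames for every residue pair
#' in `range`, where d_ij is the representative-atom distance. The statistic
#' is the population (1/N) variance of d_ij, matching "mean squared
#' fluctuations" literally (not the 1/(N-1) sample variance); the difference
#' cancels in apo/holo comparisons. Being built purely from internal
#' distances, DF is invariant under per-frame rigid-body motion, so no prior
#' superposition is needed. Two-pass accumulation (mean first, then squared
#' deviations) is used for numerical accuracy.
#'
#' The analysis window is a required argument with no default: disordered
#' termini should be excluded by the caller (for FGF2-sized inputs the
#' generator's convention is ids 25-155).
#'
#' @param traj a [Trajectory-class] with at least 2 frames.
#' @param range `c(first, last)` inclusive author residue ids; every id in the
#'   range must be present in the trajectory.
#' @return a [DistanceFluctuation-class] (Angstrom^2).
#' @export
distanceFluctuation <- function(traj, range) {
  s <- .subsetRange(traj, range)
  nf <- dim(s$coords)[1]
  dbar <- .pairDistances(s$coords, 1)
  for (f in 2:nf) dbar <- dbar + .pairDistances(s$coords, f)
  dbar <- dbar / nf
  acc <- 0
  for (f in seq_len(nf)) {
    dev <- .pairDistances(s$coords, f) - dbar
    acc <- acc + dev * dev
  }
  acc <- acc / nf
  v <- matrix(0, length(s$ids), length(s$ids),
              dimnames = list(s$ids, s$ids))
  v[lower.tri(v)] <- as.vector(acc)
  v <- v + t(v)
  new("DistanceFluctuation", values = v, nFrames = as.integer(nf),
      atomName = traj@atomName)
}

#' Holo-minus-apo fluctuation difference matrix
#'
#' Entrywise `values(holo) - values(apo)`. Negative entries flag residue pairs
#' whose distance fluctuation is quenched upon ligand binding, positive
#' entries pairs whose conformational freedom is enhanced. The operation is
#' antisymmetric in its arguments: `differenceMatrix(a, b)` equals
#' `-differenceMatrix(b, a)`.
#'
#' @param holo,apo [DistanceFluctuation-class] objects over the same residue
#'   range.
#' @return a [FluctuationDifference-class].
#' @export
differenceMatrix <- function(holo, apo) {
  stopifnot(is(holo, "DistanceFluctuation"), is(apo, "DistanceFluctuation"))
  if (!identical(rownames(holo@values), rownames(apo@values)))
    stop("residue ranges of the two matrices differ")
  new("FluctuationDifference", values = holo@values - apo@values,
      nFramesHolo = holo@nFrames, nFramesApo = apo@nFrames)
}

# Shared region-calling core. scores: named per-residue signed score (NA =
# residue had no significant evidence). Returns a data.frame of contiguous
# (in residue id) same-direction segments of length >= minLen.
.segmentCalls <- function(ids, direction, score, minLen) {
  calls <- data.frame(first = integer(), last = integer(),
                      direction = character(), score = numeric())
  n <- length(ids)
  i <- 1L
  while (i <= n) {
    if (is.na(direction[i])) { i <- i + 1L; next }
    j <- i
    while (j < n && !is.na(direction[j + 1L]) &&
           direction[j + 1L] == direction[i] &&
           ids[j + 1L] == ids[j] + 1L) j <- j + 1L
    if (j - i + 1L >= minLen)
      calls <- rbind(calls, data.frame(
        first = ids[i], last = ids[j], direction = direction[i],
        score = mean(score[i:j])))
    i <- j + 1L
  }
  calls[order(calls$first), , drop = FALSE]
}

#' Call quenched/enhanced residue regions from a difference matrix
#'
#' Makes the visual reading of a holo-minus-apo fluctuation difference matrix
#' algorithmic, in two thresholding levels. Entry level: an off-diagonal
#' entry is significant when its magnitude exceeds `mean + k * SD` of all
#' off-diagonal magnitudes. Residue level: each residue's score is the sum
#' of the significant entries in its row divided by the row length, so a
#' residue whose whole row is perturbed scores high while a residue that
#' merely faces a perturbed block in a few columns scores low; residues
#' whose absolute score exceeds `mean + k * SD` of all absolute scores are
#' called. A called residue's direction is `"quenched"` (negative) or
#' `"enhanced"` (positive); when its significant entries are mixed in sign
#' it takes the sign of the sign-group with the larger mean magnitude.
#' Contiguous runs (consecutive residue ids) of at least `minLen`
#' same-direction residues become calls; each call's score is the mean
#' significant-entry magnitude over its residues. An all-zero matrix yields
#' no calls.
#'
#' @param diff a [FluctuationDifference-class].
#' @param k significance threshold multiplier (> 0); default 1.
#' @param minLen minimum segment length in residues (>= 1); default 3, the
#'   shortest region scale of interest.
#' @return data.frame with columns `first`, `last`, `direction`
#'   (`"quenched"`/`"enhanced"`), `score` (mean significant |Delta|,
#'   Angstrom^2); zero rows when nothing is significant.
#' @export
callPerturbedRegions <- function(diff, k = 1, minLen = 3) {
  stopifnot(is(diff, "FluctuationDifference"), k > 0, minLen >= 1)
  v <- diff@values
  ids <- as.integer(rownames(v))
  off <- abs(v[upper.tri(v)])
  thr <- mean(off) + k * stats::sd(off)
  sig <- abs(v) > thr
  diag(sig) <- FALSE
  n <- length(ids)
  rowScore <- rowSums(v * sig) / (n - 1)
  resThr <- mean(abs(rowScore)) + k * stats::sd(abs(rowScore))
  direction <- rep(NA_character_, n)
  score <- rep(NA_real_, n)
  for (i in which(abs(rowScore) > resThr)) {
    e <- v[i, sig[i, ]]
    if (!length(e)) next
    pos <- e[e > 0]; neg <- e[e < 0]
    mp <- if (length(pos)) mean(pos) else 0
    mn <- if (length(neg)) mean(neg) else 0
    direction[i] <- if (abs(mp) >= abs(mn)) "enhanced" else "quenched"
    score[i] <- mean(abs(e))
  }
  .segmentCalls(ids, direction, score, minLen)
}
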