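.meanDistanceMatrix <- function(coords, ids) {
  nf <- dim(coords)[1]
  dbar <- .pairDistances(coords, 1)
  for (f in 2:nf) dbar <- dbar + .pairDistances(coords, f)
  m <- as.matrix(dbar / nf)
  dimnames(m) <- list(ids, ids)
  m
}

#' Residue neighborhood map from the time-averaged structure
#'
#' j is a neighbor of i iff the time-averaged representative-atom distance
#' `<d_ij>` is at most `cutoff` (and i != j). Fixing the neighborhood from the
#' time average (rather than per frame) makes geometric strain measure the
#' deformation of one fixed local contact network. The 8 Angstrom default is
#' the standard Calpha residue-contact scale.
#'
#' @param traj a [Trajectory-class].
#' @param cutoff neighbor distance cutoff in Angstrom (> 0); default 8.
#' @param range `c(first, last)` inclusive analysis window.
#' @return a [NeighborMap-class]; residues with no neighbor are isolated.
#' @export
neighborMap <- function(traj, cutoff = 8, range) {
  stopifnot(cutoff > 0)
  s <- .subsetRange(traj, range)
  mbar <- .meanDistanceMatrix(s$coords, s$ids)
  adj <- mbar <= cutoff
  diag(adj) <- FALSE
  new("NeighborMap", adjacency = adj, cutoff = cutoff, meanDistances = mbar)
}

#' Isolated residues of a neighbor map
#'
#' @param nmap a [NeighborMap-class].
#' @return integer ids of residues with no neighbor at the map's cutoff.
#' @export
isolatedResidues <- function(nmap) {
  stopifnot(is(nmap, "NeighborMap"))
  residueIds(nmap)[rowSums(nmap@adjacency) == 0]
}

#' Time-resolved geometric strain
#'
#' For each residue i and frame t the instantaneous strain is
#' `s_i(t) = (1/|N(i)|) * sum_{j in N(i)} (d_ij(t) - <d_ij>)^2`
#' (Angstrom^2): the squared deviation of i's distances to its fixed
#' neighbors from their time averages, averaged over the neighborhood so that
#' surface and core residues are comparable (`normalized = FALSE` gives the
#' unnormalized sum instead). Frames are then averaged within consecutive
#' non-overlapping windows of `window` frames; leftover frames beyond the
#' last full window are dropped. Isolated residues propagate as NA, never 0.
#'
#' @param traj the [Trajectory-class] the map was built from.
#' @param nmap a [NeighborMap-class] over the same residues.
#' @param window window length in frames (>= 1, <= number of frames);
#'   default 50.
#' @param normalized divide by the neighbor count (default TRUE).
#' @return a [StrainSeries-class], residues x `floor(nFrames/window)` windows.
#' @export
strainSeries <- function(traj, nmap, window = 50, normalized = TRUE) {
  stopifnot(is(nmap, "NeighborMap"), window >= 1)
  ids <- residueIds(nmap)
  s <- .subsetRange(traj, c(min(ids), max(ids)))
  if (!identical(s$ids, ids))
    stop("neighbor map residues do not match the trajectory range")
  nf <- dim(s$coords)[1]
  window <- as.integer(window)
  if (window > nf) stop("window (", window, ") exceeds frame count (", nf, ")")
  mbar <- nmap@meanDistances
  deg <- rowSums(nmap@adjacency)
  adj <- nmap@adjacency
  perFrame <- matrix(NA_real_, length(ids), nf)
  for (f in seq_len(nf)) {
    dev2 <- (as.matrix(.pairDistances(s$coords, f)) - mbar)^2
    tot <- rowSums(dev2 * adj)
    perFrame[, f] <- if (normalized) ifelse(deg > 0, tot / deg, NA_real_)
                     else ifelse(deg > 0, tot, NA_real_)
  }
  nw <- nf %/% window
  v <- matrix(NA_real_, length(ids), nw, dimnames = list(ids, seq_len(nw)))
  for (w in seq_len(nw))
    v[, w] <- rowMeans(perFrame[, ((w - 1L) * window + 1L):(w * window),
                                drop = FALSE])
  new("StrainSeries", values = v, window = window, normalized = normalized)
}

#' Average strain profile over the whole simulation
#'
#' Row means of a strain series, ignoring missing windows; the per-residue
#' average strain over the simulation time.
#'
#' @param series a [StrainSeries-class].
#' @return a [StrainProfile-class] (Angstrom^2).
#' @export
averageStrainProfile <- function(series) {
  stopifnot(is(series, "StrainSeries"))
  v <- rowMeans(series@values, na.rm = TRUE)
  v[is.nan(v)] <- NA_real_
  names(v) <- rownames(series@values)
  new("StrainProfile", values = v)
}

#' Call strain hotspots from paired apo/holo profiles
#'
#' Per residue, `Delta_s = holo - apo` average strain. Residues whose
#' `|Delta_s|` exceeds `mean + k * SD` of all `|Delta_s|` are significant;
#' contiguous same-direction runs of at least `minLen` residues become calls
#' (direction `"enhanced"` for increased strain upon binding, `"quenched"`
#' for decreased). Residues missing in either profile are skipped.
#'
#' @param apo,holo [StrainProfile-class] objects over the same residues.
#' @param k threshold multiplier (> 0); default 1.
#' @param minLen minimum segment length; default 3.
#' @return data.frame with columns `first`, `last`, `direction`, `score`
#'   (mean |Delta_s| over the segment, Angstrom^2).
#' @export
strainHotspots <- function(apo, holo, k = 1, minLen = 3) {
  stopifnot(is(apo, "StrainProfile"), is(holo, "StrainProfile"),
            k > 0, minLen >= 1)
  if (!identical(names(apo@values), names(holo@values)))
    stop("profiles cover different residues")
  delta <- holo@values - apo@values
  ok <- !is.na(delta)
  thr <- mean(abs(delta[ok])) + k * stats::sd(abs(delta[ok]))
  ids <- as.integer(names(delta))
  direction <- ifelse(ok & abs(delta) > thr,
                      ifelse(delta > 0, "enhanced", "quenched"), NA_character_)
  score <- ifelse(!is.na(direction), abs(delta), NA_real_)
  .segmentCalls(ids, direction, score, minLen)
}
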