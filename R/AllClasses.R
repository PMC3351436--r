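#' @import methods
NULL

#' Trajectory of one representative atom per residue
#'
#' Holds the coordinates (in Angstrom) of one representative atom per residue
#' (default C-alpha) over an ordered set of frames. Residues keep their author
#' numbering throughout: no analysis in this package renumbers from zero.
#' All implemented observables are internal-distance based, so trajectories
#' need not (and should not) be superposed beforehand.
#'
#' @slot coords numeric array, frames x residues x 3, in Angstrom.
#' @slot residueIds integer vector of author residue numbers, one per residue
#'   column, strictly increasing.
#' @slot atomName name of the representative atom (e.g. `"CA"`).
#' @slot frameTimes optional frame times in ns (`numeric(0)` when absent).
#' @exportClass Trajectory
setClass("Trajectory",
  representation(coords = "array", residueIds = "integer",
                 atomName = "character", frameTimes = "numeric"),
  prototype(atomName = "CA", frameTimes = numeric(0)))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L)
    return("coords must be a frames x residues x 3 array")
  if (d[1] < 2L) return("a trajectory needs at least 2 frames")
  if (d[2] != length(object@residueIds))
    return("residueIds length must match the residue dimension of coords")
  if (anyDuplicated(object@residueIds)) return("residue ids must be unique")
  if (is.unsorted(object@residueIds)) return("residue ids must be increasing")
  if (!all(is.finite(object@coords))) return("coordinates must be finite")
  if (length(object@frameTimes) && length(object@frameTimes) != d[1])
    return("frameTimes length must equal the number of frames")
  TRUE
})

#' Mean-squared fluctuations of all pairwise inter-residue distances
#'
#' Symmetric matrix DF(i,j) = <(d_ij - <d_ij>)^2> over frames, in Angstrom^2,
#' where d_ij is the distance between the representative atoms of residues i
#' and j and <.> is the mean over frames (population, 1/N, variance: see
#' [distanceFluctuation()]). Row/column names are author residue ids.
#'
#' @slot values symmetric numeric matrix (Angstrom^2), zero diagonal,
#'   dimnames = residue ids.
#' @slot nFrames number of frames the statistic was computed over.
#' @slot atomName representative atom used.
#' @exportClass DistanceFluctuation
setClass("DistanceFluctuation",
  representation(values = "matrix", nFrames = "integer", atomName = "character"))

setValidity("DistanceFluctuation", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("values must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    return("values must carry identical residue-id row and column names")
  if (!isTRUE(all.equal(v, t(v), tolerance = 1e-12))) return("values must be symmetric")
  if (any(diag(v) != 0)) return("diagonal must be exactly zero")
  if (any(v < 0)) return("fluctuations must be non-negative")
  TRUE
})

#' Holo-minus-apo difference of distance-fluctuation matrices
#'
#' Entrywise DF_holo - DF_apo in Angstrom^2. Sign convention: negative entries
#' mean the pair's distance fluctuation is quenched upon binding; positive
#' entries mean it is enhanced. Swapping the two input states flips every sign.
#'
#' @slot values symmetric numeric matrix (Angstrom^2), zero diagonal.
#' @slot nFramesHolo,nFramesApo frame counts of the two inputs.
#' @exportClass FluctuationDifference
setClass("FluctuationDifference",
  representation(values = "matrix", nFramesHolo = "integer", nFramesApo = "integer"))

setValidity("FluctuationDifference", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("values must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    return("values must carry identical residue-id row and column names")
  if (!isTRUE(all.equal(v, t(v), tolerance = 1e-12))) return("values must be symmetric")
  TRUE
})

#' Residue neighborhood map from the time-averaged structure
#'
#' j is a neighbor of i iff the time-averaged distance <d_ij> is at most the
#' cutoff and i != j. The map is fixed from the time-averaged structure so that
#' geometric strain measures deformation of a fixed local contact network.
#' Residues with no neighbor are flagged isolated and propagate as missing
#' through strain calculations.
#'
#' @slot adjacency symmetric logical matrix, FALSE diagonal.
#' @slot cutoff distance cutoff in Angstrom.
#' @slot meanDistances time-averaged distance matrix (Angstrom) the map was
#'   built from.
#' @exportClass NeighborMap
setClass("NeighborMap",
  representation(adjacency = "matrix", cutoff = "numeric", meanDistances = "matrix"))

setValidity("NeighborMap", function(object) {
  a <- object@adjacency
  if (!is.logical(a)) return("adjacency must be logical")
  if (!identical(a, t(a))) return("adjacency must be symmetric")
  if (any(diag(a))) return("a residue cannot neighbor itself")
  if (length(object@cutoff) != 1L || object@cutoff <= 0) return("cutoff must be > 0")
  TRUE
})

#' Time-resolved geometric strain
#'
#' Per-residue, per-time-window geometric strain s_i(t) in Angstrom^2:
#' the mean over neighbors j of (d_ij(t) - <d_ij>)^2, averaged within
#' consecutive non-overlapping windows of `window` frames. Isolated residues
#' are NA.
#'
#' @slot values residues x windows numeric matrix (Angstrom^2), rownames =
#'   residue ids.
#' @slot window window length in frames.
#' @slot normalized TRUE when strain is the mean (not the sum) over neighbors.
#' @exportClass StrainSeries
setClass("StrainSeries",
  representation(values = "matrix", window = "integer", normalized = "logical"))

setValidity("StrainSeries", function(object) {
  v <- object@values
  if (is.null(rownames(v))) return("values must carry residue-id rownames")
  if (any(v < 0, na.rm = TRUE)) return("strain must be non-negative")
  if (object@window < 1L) return("window must be >= 1")
  TRUE
})

#' Residue profile of average geometric strain
#'
#' Mean strain per residue over all time windows (Angstrom^2); the row means
#' of a [StrainSeries].
#'
#' @slot values named numeric vector (names = residue ids), NA for isolated
#'   residues.
#' @exportClass StrainProfile
setClass("StrainProfile", representation(values = "numeric"))

setValidity("StrainProfile", function(object) {
  if (is.null(names(object@values))) return("values must be named by residue id")
  if (any(object@values < 0, na.rm = TRUE)) return("strain must be non-negative")
  TRUE
})

#' NMR peak table (one spectrum)
#'
#' Per-residue amide peak positions and intensities from one 2-D spectrum
#' (HSQC or ePHOGSY plane). Overlapped or exchange-broadened peaks are kept as
#' NA, never as zero.
#'
#' @slot data data.frame with columns `residue` (integer), `dH` (ppm),
#'   `dN` (ppm), `intensity` (arbitrary units, >= 0 or NA), `sidechain`
#'   (logical; TRUE for Asn/Gln/Arg side-chain N-H peaks).
#' @exportClass PeakTable
setClass("PeakTable", representation(data = "data.frame"))

setValidity("PeakTable", function(object) {
  d <- object@data
  need <- c("residue", "dH", "dN", "intensity", "sidechain")
  if (!all(need %in% names(d)))
    return(paste("data must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(d[c("residue", "sidechain")]))
    return("residue ids must be unique within a table")
  if (any(d$intensity < 0, na.rm = TRUE))
    return("intensities must be >= 0 or NA")
  TRUE
})

#' 15N relaxation dataset at one field
#'
#' Per-residue longitudinal (R1), transverse (R2), rotating-frame (R1rho)
#' relaxation rates in 1/s and the heteronuclear 1H-15N NOE (dimensionless),
#' with their uncertainties, measured at a single spectrometer field.
#'
#' @slot data data.frame with columns `residue`, `R1`, `R2`, `NOE`, `R1rho`,
#'   `eR1`, `eR2`, `eNOE`, `eR1rho` (NA where not measured).
#' @slot fieldMHz spectrometer 1H frequency in MHz.
#' @slot truth data.frame of generating dynamics parameters when the dataset
#'   is synthetic (0 rows otherwise).
#' @exportClass RelaxationDataset
setClass("RelaxationDataset",
  representation(data = "data.frame", fieldMHz = "numeric", truth = "data.frame"),
  prototype(truth = data.frame()))

setValidity("RelaxationDataset", function(object) {
  d <- object@data
  need <- c("residue", "R1", "R2", "NOE", "R1rho", "eR1", "eR2", "eNOE", "eR1rho")
  if (!all(need %in% names(d)))
    return(paste("data must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(d$residue)) return("residue ids must be unique")
  if (any(d$R1 <= 0, na.rm = TRUE) || any(d$R2 <= 0, na.rm = TRUE))
    return("R1 and R2 must be > 0 where present")
  if (any(d[c("eR1", "eR2", "eNOE", "eR1rho")] <= 0, na.rm = TRUE))
    return("errors must be > 0 where present")
  if (length(object@fieldMHz) != 1L || object@fieldMHz <= 0)
    return("exactly one positive field strength per dataset")
  TRUE
})

#' Lipari-Szabo model-free fit of a relaxation dataset
#'
#' Per-residue chosen model (M1-M5) with fitted parameters and uncertainties,
#' plus the global correlation time and order-parameter summary over the
#' analysis range.
#'
#' @slot residues data.frame: residue, model, s2, te (ps), rex (1/s), sf2,
#'   chi2, aic, se.s2, se.te, se.rex, converged.
#' @slot tm global rotational correlation time (ns).
#' @slot diffusion `"isotropic"` or `"axial"`.
#' @slot summary list: range, n, meanS2, sdS2, flexThreshold (mean - 2 SD),
#'   flexibleResidues.
#' @exportClass ModelFreeFit
setClass("ModelFreeFit",
  representation(residues = "data.frame", tm = "numeric",
                 diffusion = "character", summary = "list"))

#' Combined apo/holo perturbation report
#'
#' Per-residue classification across all executed stages (CSP, intensity,
#' exchange, order parameters, distance-fluctuation regions, strain hotspots,
#' hydration) and the cross-technique consensus set: residues flagged by at
#' least `consensusMin` independent stages.
#'
#' @slot residueTable per-residue data.frame of stage classifications.
#' @slot consensus integer vector of consensus residue ids.
#' @slot parameters list of the parameters each stage ran with.
#' @slot provenance list: input file md5 hashes and package version.
#' @exportClass PerturbationReport
setClass("PerturbationReport",
  representation(residueTable = "data.frame", consensus = "integer",
                 parameters = "list", provenance = "list"))
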