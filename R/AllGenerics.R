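#' Residue ids carried by an object
#'
#' Author residue numbering is preserved by every container in the package;
#' this accessor returns it.
#'
#' @param x a package object.
#' @return integer vector of author residue ids.
#' @export
setGeneric("residueIds", function(x) standardGeneric("residueIds"))

#' Number of trajectory frames underlying an object
#' @param x a package object.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Numeric payload of a result object
#'
#' Returns the matrix (fluctuation/difference/strain series) or named vector
#' (strain profile) a result object wraps.
#'
#' @param x a package object.
#' @return numeric matrix or named numeric vector.
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' Per-residue table of a tabular container
#' @param x a `PeakTable`, `RelaxationDataset`, `ModelFreeFit` or
#'   `PerturbationReport`.
#' @return data.frame, one row per residue (per peak for `PeakTable`).
#' @export
setGeneric("residueData", function(x) standardGeneric("residueData"))

#' @rdname residueIds
#' @export
setMethod("residueIds", "Trajectory", function(x) x@residueIds)
#' @rdname residueIds
#' @export
setMethod("residueIds", "DistanceFluctuation",
  function(x) as.integer(rownames(x@values)))
#' @rdname residueIds
#' @export
setMethod("residueIds", "FluctuationDifference",
  function(x) as.integer(rownames(x@values)))
#' @rdname residueIds
#' @export
setMethod("residueIds", "NeighborMap", function(x) as.integer(rownames(x@adjacency)))
#' @rdname residueIds
#' @export
setMethod("residueIds", "StrainSeries", function(x) as.integer(rownames(x@values)))
#' @rdname residueIds
#' @export
setMethod("residueIds", "StrainProfile", function(x) as.integer(names(x@values)))
#' @rdname residueIds
#' @export
setMethod("residueIds", "PeakTable", function(x) x@data$residue)
#' @rdname residueIds
#' @export
setMethod("residueIds", "RelaxationDataset", function(x) x@data$residue)

#' @rdname nFrames
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[1])
#' @rdname nFrames
#' @export
setMethod("nFrames", "DistanceFluctuation", function(x) x@nFrames)

#' @rdname values
#' @export
setMethod("values", "DistanceFluctuation", function(x) x@values)
#' @rdname values
#' @export
setMethod("values", "FluctuationDifference", function(x) x@values)
#' @rdname values
#' @export
setMethod("values", "StrainSeries", function(x) x@values)
#' @rdname values
#' @export
setMethod("values", "StrainProfile", function(x) x@values)

#' @rdname residueData
#' @export
setMethod("residueData", "PeakTable", function(x) x@data)
#' @rdname residueData
#' @export
setMethod("residueData", "RelaxationDataset", function(x) x@data)
#' @rdname residueData
#' @export
setMethod("residueData", "ModelFreeFit", function(x) x@residues)
#' @rdname residueData
#' @export
setMethod("residueData", "PerturbationReport", function(x) x@residueTable)

#' Spectrometer field of a relaxation dataset
#' @param x a `RelaxationDataset`.
#' @return 1H frequency in MHz.
#' @export
fieldMHz <- function(x) {
  stopifnot(is(x, "RelaxationDataset"))
  x@fieldMHz
}

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@coords)
  cat(sprintf("Trajectory: %d frames x %d residues (%s), ids %d-%d\n",
              d[1], d[2], object@atomName,
              min(object@residueIds), max(object@residueIds)))
})

setMethod("show", "DistanceFluctuation", function(object) {
  ids <- residueIds(object)
  cat(sprintf(
    "DistanceFluctuation: %d residues (ids %d-%d), %d frames; DF range %.4g-%.4g A^2\n",
    length(ids), min(ids), max(ids), object@nFrames,
    min(object@values[upper.tri(object@values)]),
    max(object@values)))
})

setMethod("show", "FluctuationDifference", function(object) {
  ids <- residueIds(object)
  off <- object@values[upper.tri(object@values)]
  cat(sprintf(
    "FluctuationDifference (holo - apo): %d residues (ids %d-%d); range %+.4g to %+.4g A^2\n",
    length(ids), min(ids), max(ids), min(off), max(off)))
})

setMethod("show", "NeighborMap", function(object) {
  deg <- rowSums(object@adjacency)
  cat(sprintf("NeighborMap: %d residues, cutoff %.2f A, mean degree %.1f, %d isolated\n",
              nrow(object@adjacency), object@cutoff, mean(deg), sum(deg == 0)))
})

setMethod("show", "StrainSeries", function(object) {
  cat(sprintf("StrainSeries: %d residues x %d windows (window = %d frames)\n",
              nrow(object@values), ncol(object@values), object@window))
})

setMethod("show", "StrainProfile", function(object) {
  cat(sprintf("StrainProfile: %d residues, mean strain %.4g A^2\n",
              length(object@values), mean(object@values, na.rm = TRUE)))
})

setMethod("show", "PeakTable", function(object) {
  cat(sprintf("PeakTable: %d peaks (%d backbone, %d side-chain), %d missing intensities\n",
              nrow(object@data), sum(!object@data$sidechain),
              sum(object@data$sidechain), sum(is.na(object@data$intensity))))
})

setMethod("show", "RelaxationDataset", function(object) {
  cat(sprintf("RelaxationDataset: %d residues at %.0f MHz (R1rho %s)%s\n",
              nrow(object@data), object@fieldMHz,
              if (all(is.na(object@data$R1rho))) "absent" else "present",
              if (nrow(object@truth)) ", synthetic (truth attached)" else ""))
})

setMethod("show", "ModelFreeFit", function(object) {
  s <- object@summary
  cat(sprintf(
    "ModelFreeFit: %d residues, tm = %.2f ns (%s diffusion)\n  S2 = %.2f +/- %.2f over ids %d-%d; flexibility threshold %.2f (%d residues below)\n",
    nrow(object@residues), object@tm, object@diffusion,
    s$meanS2, s$sdS2, s$range[1], s$range[2],
    s$flexThreshold, length(s$flexibleResidues)))
})

setMethod("show", "PerturbationReport", function(object) {
  cat(sprintf("PerturbationReport: %d residues, stages [%s], consensus (>=%d stages): %s\n",
              nrow(object@residueTable),
              paste(object@parameters$stages, collapse = ", "),
              object@parameters$consensusMin,
              if (length(object@consensus)) paste(object@consensus, collapse = ", ")
              else "none"))
})
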