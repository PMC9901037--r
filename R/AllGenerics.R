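#' Atom table of a structure or trajectory topology
#' @param x a \linkS4class{StructureModel} or \linkS4class{Trajectory}.
#' @return data.frame.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "StructureModel", function(x) x@atoms)

#' @rdname atoms
#' @export
setMethod("atoms", "Trajectory", function(x) x@topology)

#' Per-chain full polymer sequences
#' @param x a \linkS4class{StructureModel}.
#' @return named list of data.frames with columns resno, resid.
#' @export
chainSequences <- function(x) {
  stopifnot(is(x, "StructureModel"))
  x@chainSeq
}

#' Coordinates as an n x 3 matrix
#' @param x object holding coordinates.
#' @param frame frame index for trajectories.
#' @param ... unused.
#' @return numeric matrix n x 3.
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "StructureModel", function(x, ...) {
  m <- as.matrix(x@atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
})

#' @rdname coords
#' @export
setMethod("coords", "Trajectory", function(x, frame = 1L, ...) {
  matrix(x@coords[frame, , ], ncol = 3)
})

#' Number of frames in a trajectory
#' @param x a \linkS4class{Trajectory}.
#' @export
nFrames <- function(x) {
  stopifnot(is(x, "Trajectory"))
  dim(x@coords)[1]
}

#' Frame times in ps
#' @param x a \linkS4class{Trajectory} or \linkS4class{AngleSeries}.
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "Trajectory", function(x) x@times)

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "AngleSeries", function(x) x@times)

#' Angle values in degrees
#' @param x an \linkS4class{AngleSeries}.
#' @export
angleValues <- function(x) {
  stopifnot(is(x, "AngleSeries"))
  x@values
}

#' Is the series wrapped into (-180, 180]?
#' @param x an \linkS4class{AngleSeries}.
#' @export
isWrapped <- function(x) {
  stopifnot(is(x, "AngleSeries"))
  x@wrapped
}

#' InteractionSeries as a data.frame
#' @param x an \linkS4class{InteractionSeries}.
#' @return data.frame with time_ps, distance, angle.
#' @export
interactionTable <- function(x) {
  stopifnot(is(x, "InteractionSeries"))
  data.frame(time_ps = x@times, distance = x@distance, angle = x@angle)
}

#' RMSF values as a data.frame
#' @param x an \linkS4class{RMSFProfile}.
#' @export
rmsfValues <- function(x) {
  stopifnot(is(x, "RMSFProfile"))
  x@profile
}

#' Peak location of a binned distribution
#' @param x a \linkS4class{BinnedDistribution}.
#' @return numeric, center of the maximal-density bin.
#' @export
peakLocation <- function(x) {
  stopifnot(is(x, "BinnedDistribution"))
  x@peak
}

#' Melting temperature accessor
#' @param x a \linkS4class{MeltResult}.
#' @export
tmValue <- function(x) {
  stopifnot(is(x, "MeltResult"))
  x@tm
}

#' Resolve a P-position label to an author residue number
#' @param map a \linkS4class{PeptidePositionMap}.
#' @param label e.g. "P1", "P7", "P-1".
#' @return integer residue number.
#' @export
positionResno <- function(map, label) {
  stopifnot(is(map, "PeptidePositionMap"))
  i <- match(label, map@labels)
  if (is.na(i)) stop("no position '", label, "' in map (have: ",
                     paste(map@labels, collapse = ", "), ")")
  map@resno[i]
}

#' @describeIn positionResno all labels in N- to C-terminal order
#' @export
positionLabels <- function(map) {
  stopifnot(is(map, "PeptidePositionMap"))
  stats::setNames(map@resno, map@labels)
}

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  ch <- unique(a$chain)
  cat("StructureModel:", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resno))), "residues,",
      length(ch), "chain(s)", if (length(ch)) paste0("[", paste(ch, collapse = ","), "]"),
      "\n")
  if (length(object@chainSeq))
    cat("  sequence records for chain(s):",
        paste(names(object@chainSeq), collapse = ","), "\n")
})

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@coords)
  cat("Trajectory:", d[1], "frames x", d[2], "atoms;",
      "t =", object@times[1], "...", object@times[length(object@times)], "ps\n")
})

setMethod("show", "AngleSeries", function(object) {
  cat("AngleSeries (", if (object@wrapped) "wrapped" else "unwrapped", "): ",
      length(object@values), " samples, range [",
      round(min(object@values), 1), ", ", round(max(object@values), 1),
      "] deg\n", sep = "")
})

setMethod("show", "InteractionSeries", function(object) {
  cat("InteractionSeries [", object@definition, "]: ", length(object@times),
      " frames, distance ", round(min(object@distance), 2), "-",
      round(max(object@distance), 2), " A\n", sep = "")
})

setMethod("show", "BinnedDistribution", function(object) {
  cat("BinnedDistribution:", length(object@density), "bins, peak at",
      round(object@peak, 3), ", FWHM", round(object@fwhm, 3), "\n")
})

setMethod("show", "SuperpositionResult", function(object) {
  cat("SuperpositionResult: rmsd", round(object@rmsd, 4), "A over",
      object@nAtomsFit, "atoms\n")
})

setMethod("show", "RMSFProfile", function(object) {
  p <- object@profile
  cat("RMSFProfile:", nrow(p), "residues; rmsf",
      round(min(p$rmsf), 3), "-", round(max(p$rmsf), 3), "A\n")
})

setMethod("show", "MeltResult", function(object) {
  cat("MeltResult: Tm =", round(object@tm, 2), "C (",
      object@extremum, "of dF/dT )\n")
})

setMethod("show", "PeptidePositionMap", function(object) {
  cat("PeptidePositionMap chain", object@pepChain, ":",
      paste(object@labels, object@resno, sep = "=", collapse = " "), "\n")
})

setMethod("show", "MeltCurve", function(object) {
  cat("MeltCurve:", length(object@temperature), "points,",
      ncol(object@fluorescence), "replicate(s),",
      object@temperature[1], "-",
      object@temperature[length(object@temperature)], "C\n")
})
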