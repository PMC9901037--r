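#' @import methods
NULL

#' StructureModel: a parsed macromolecular structure
#'
#' Holds the atom table of a crystal structure or single coordinate frame
#' together with the per-chain full polymer sequence (from the sequence
#' record when the file carries one). Residue numbers are author numbering
#' throughout; the package never renumbers, so groove residues can be
#' addressed as Ile52, Tyr59, Cys76 etc. exactly as crystallographers name
#' them.
#'
#' @slot atoms data.frame with columns \code{chain}, \code{resno} (integer,
#'   author numbering), \code{resid} (3-letter code), \code{elety} (atom
#'   name), \code{x}, \code{y}, \code{z} (Angstrom), \code{occ} (occupancy).
#'   Alternate locations have already been resolved to a single conformer.
#' @slot chainSeq named list; one entry per chain with a sequence record,
#'   each a data.frame with columns \code{resno}, \code{resid} giving the
#'   full construct sequence (modeled or not).
#'
#' @seealso [readStructure()], [detectUnmodeledRegions()], [selectAtoms()]
#' @export
setClass("StructureModel",
  representation(atoms = "data.frame", chainSeq = "list"),
  prototype(atoms = data.frame(), chainSeq = list()))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z", "occ")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a)) {
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      return("non-finite atom coordinates")
    key <- paste(a$chain, a$resno, a$elety)
    if (anyDuplicated(key))
      return("duplicate (chain, resno, atom name) keys after altloc resolution")
  }
  TRUE
})

#' PeptidePositionMap: P-position labels for a bound peptide
#'
#' Maps canonical peptide position labels (... P-2, P-1, P1 ... P8) onto
#' author residue numbers of the peptide chain. P7 is the cysteine
#' disulfide-bonded to heavy-chain Cys76 (the engineered anchor of the
#' disulfide-trap design); P1 sits six chain positions N-terminal to it,
#' and residues before P1 are extension positions P-1, P-2, ...
#'
#' @slot pepChain chain identifier of the peptide.
#' @slot labels character vector of P labels, N- to C-terminal.
#' @slot resno integer vector of author residue numbers, parallel to
#'   \code{labels}.
#' @export
setClass("PeptidePositionMap",
  representation(pepChain = "character", labels = "character",
                 resno = "integer"))

setValidity("PeptidePositionMap", function(object) {
  if (length(object@labels) != length(object@resno))
    return("labels and resno must be parallel")
  if (!"P1" %in% object@labels) return("map must contain P1")
  if (anyDuplicated(object@labels)) return("duplicate position labels")
  TRUE
})

#' Trajectory: multi-frame coordinates over a fixed topology
#'
#' @slot coords numeric array frames x atoms x 3, Angstrom.
#' @slot times numeric, per-frame time in ps, strictly increasing.
#' @slot topology data.frame mapping atom index to \code{chain},
#'   \code{resno}, \code{resid}, \code{elety}.
#' @seealso [readTrajectory()], [superposeFrames()], [rmsfProfile()]
#' @export
setClass("Trajectory",
  representation(coords = "array", times = "numeric", topology = "data.frame"))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3 || d[3] != 3)
    return("coords must be a frames x atoms x 3 array")
  if (d[1] != length(object@times))
    return("times length must equal frame count")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (d[2] != nrow(object@topology))
    return("topology rows must equal atom count")
  if (!all(is.finite(object@coords)))
    return("non-finite coordinates")
  TRUE
})

#' AngleSeries: a time-stamped angle trace with wrap state
#'
#' Houses the terminal-amino-group dihedral omega and its unwrapped and
#' smoothed forms. Wrapped values live in (-180, 180]; unwrapped values are
#' unbounded but every consecutive difference is below 180 degrees in
#' magnitude.
#'
#' @slot times numeric, ps.
#' @slot values numeric, degrees.
#' @slot wrapped logical scalar.
#' @seealso [unwrapAngles()], [smoothAngles()], [detectRotation()]
#' @export
setClass("AngleSeries",
  representation(times = "numeric", values = "numeric", wrapped = "logical"))

setValidity("AngleSeries", function(object) {
  if (length(object@times) != length(object@values))
    return("times and values must be parallel")
  if (length(object@wrapped) != 1) return("wrapped must be a scalar")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (isTRUE(object@wrapped) && length(object@values) &&
      (any(object@values <= -180 - 1e-9) || any(object@values > 180 + 1e-9)))
    return("wrapped values must lie in (-180, 180]")
  if (identical(object@wrapped, FALSE) && length(object@values) > 1 &&
      any(abs(diff(object@values)) >= 180 + 1e-9))
    return("unwrapped series must have |delta| < 180 between frames")
  TRUE
})

#' InteractionSeries: per-frame distance/orientation between two residues
#'
#' One row per trajectory frame carrying the inter-residue distance and,
#' for aromatic/aromatic pairs, the ring normal-normal angle. The
#' \code{definition} tag records which atom-pair rule produced the series
#' (ring center to ring center, Cbeta to ring center, ring center to
#' Ile52 Cdelta, or Cbeta to Cdelta).
#'
#' @slot times numeric, ps.
#' @slot distance numeric, Angstrom.
#' @slot angle numeric, degrees in [0, 180]; all NA when the pair has no
#'   orientation (non-aromatic P1).
#' @slot definition character tag.
#' @export
setClass("InteractionSeries",
  representation(times = "numeric", distance = "numeric", angle = "numeric",
                 definition = "character"))

setValidity("InteractionSeries", function(object) {
  n <- length(object@times)
  if (length(object@distance) != n || length(object@angle) != n)
    return("times, distance and angle must be parallel")
  if (n && any(object@distance <= 0))
    return("distances must be positive")
  ang <- object@angle[!is.na(object@angle)]
  if (length(ang) && (any(ang < -1e-9) || any(ang > 180 + 1e-9)))
    return("angles must lie in [0, 180]")
  TRUE
})

#' BinnedDistribution: a density-normalized histogram with peak and width
#'
#' @slot breaks numeric bin edges.
#' @slot density numeric, one per bin, integrates to 1 over the support.
#' @slot peak numeric, center of the maximal bin (ties broken toward the
#'   lowest value).
#' @slot fwhm numeric, full width at half maximum of the binned density.
#' @seealso [estimateDistribution()], [peakLocation()]
#' @export
setClass("BinnedDistribution",
  representation(breaks = "numeric", density = "numeric", peak = "numeric",
                 fwhm = "numeric"))

setValidity("BinnedDistribution", function(object) {
  if (length(object@breaks) != length(object@density) + 1)
    return("breaks must have one more element than density")
  if (any(object@density < 0)) return("density must be non-negative")
  mass <- sum(object@density * diff(object@breaks))
  if (length(object@density) && abs(mass - 1) > 1e-6)
    return("density must integrate to 1")
  TRUE
})

#' MeltCurve: thermal-denaturation fluorescence vs temperature
#'
#' @slot temperature numeric, degrees C, strictly increasing grid.
#' @slot fluorescence numeric matrix, points x replicates, arbitrary units.
#' @seealso [meltingTemperature()]
#' @export
setClass("MeltCurve",
  representation(temperature = "numeric", fluorescence = "matrix"))

setValidity("MeltCurve", function(object) {
  if (length(object@temperature) < 10)
    return("melt curve needs at least 10 points")
  if (any(diff(object@temperature) <= 0))
    return("temperature grid must be strictly increasing")
  if (nrow(object@fluorescence) != length(object@temperature))
    return("fluorescence rows must match temperature grid")
  TRUE
})

#' SuperpositionResult: a rigid-body least-squares fit
#'
#' Transform convention: mobile coordinates are mapped onto the reference
#' by \code{x' = R (x - centerMobile) + centerReference}.
#'
#' @slot rotation 3x3 proper orthonormal matrix.
#' @slot centerMobile,centerReference numeric length-3 centroids of the fit
#'   selections.
#' @slot rmsd numeric, Angstrom over the fit selection after transform.
#' @slot nAtomsFit integer.
#' @seealso [kabschSuperpose()], [applyTransform()]
#' @export
setClass("SuperpositionResult",
  representation(rotation = "matrix", centerMobile = "numeric",
                 centerReference = "numeric", rmsd = "numeric",
                 nAtomsFit = "integer"))

setValidity("SuperpositionResult", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    return("rotation must be orthonormal")
  if (abs(det(R) - 1) > 1e-6) return("rotation must be proper (det +1)")
  if (object@rmsd < 0) return("rmsd must be non-negative")
  TRUE
})

#' RMSFProfile: per-residue root mean square fluctuation
#'
#' @slot profile data.frame with columns \code{chain}, \code{resno},
#'   \code{rmsf} (Angstrom).
#' @slot fitSelection,measureSelection character descriptions of the atom
#'   sets used.
#' @seealso [rmsfProfile()]
#' @export
setClass("RMSFProfile",
  representation(profile = "data.frame", fitSelection = "character",
                 measureSelection = "character"))

setValidity("RMSFProfile", function(object) {
  if (!all(c("chain", "resno", "rmsf") %in% names(object@profile)))
    return("profile needs chain, resno, rmsf columns")
  if (nrow(object@profile) && any(object@profile$rmsf < 0))
    return("rmsf must be non-negative")
  TRUE
})

#' MeltResult: extracted melting temperature
#'
#' @slot tm numeric, degrees C, strictly inside the measured range.
#' @slot derivValue numeric, value of the first derivative at the extremum.
#' @slot window integer, smoothing window (points) used.
#' @slot extremum character, "minimum" or "maximum".
#' @slot tmAll numeric, temperatures of all interior local extrema of the
#'   derivative (multi-transition curves), global first.
#' @export
setClass("MeltResult",
  representation(tm = "numeric", derivValue = "numeric", window = "integer",
                 extremum = "character", tmAll = "numeric"))
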