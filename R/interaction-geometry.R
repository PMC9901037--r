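# six-membered aromatic ring atoms of PHE/TYR, in cyclic order
.ringAtoms <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")

# ordered ring coordinates of (chain, resno) in an atom table + xyz matrix
.ringCoords <- function(topo, xyz, chain, resno) {
  idx <- vapply(.ringAtoms, function(e) {
    w <- which(topo$chain == chain & topo$resno == resno & topo$elety == e)
    if (length(w)) w[1] else NA_integer_
  }, integer(1))
  idx <- idx[!is.na(idx)]
  if (length(idx) < 5)
    stop("fewer than 5 ring atoms for ", chain, ":", resno)
  xyz[idx, , drop = FALSE]
}

#' Geometric center of an aromatic ring
#'
#' Unweighted mean of the ring atom positions (CG, CD1, CE1, CZ, CE2, CD2
#' for PHE/TYR); at least 5 of the 6 must be present.
#'
#' @param x a \linkS4class{StructureModel} or \linkS4class{Trajectory}.
#' @param chain,resno residue carrying the ring.
#' @param frame frame index for trajectories.
#' @return numeric length-3 position, Angstrom.
#' @export
ringCenter <- function(x, chain, resno, frame = 1L) {
  xyz <- if (is(x, "Trajectory")) coords(x, frame) else coords(x)
  colMeans(.ringCoords(atoms(x), xyz, chain, resno))
}

# best-fit plane normal (SVD), sign fixed by the right-hand rule over the
# ordered atom cycle (Newell polygon normal)
.planeNormal <- function(rc) {
  ctr <- colMeans(rc)
  M <- sweep(rc, 2, ctr)
  s <- svd(M)
  if (s$d[2] < 1e-9) stop("ring atoms are collinear; no plane normal")
  n <- s$v[, 3]
  nn <- nrow(rc)
  newell <- c(0, 0, 0)
  for (i in seq_len(nn)) {
    a <- M[i, ]; b <- M[if (i == nn) 1 else i + 1, ]
    newell <- newell + c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  }
  if (sum(n * newell) < 0) n <- -n
  .unit(n)
}

#' Unit normal of an aromatic ring plane
#'
#' Normal of the best-fit plane through the ring atoms, oriented by the
#' right-hand rule over the ordered atom sequence so the sign is
#' reproducible.
#'
#' @inheritParams ringCenter
#' @return unit length-3 vector.
#' @export
ringNormal <- function(x, chain, resno, frame = 1L) {
  xyz <- if (is(x, "Trajectory")) coords(x, frame) else coords(x)
  .planeNormal(.ringCoords(atoms(x), xyz, chain, resno))
}

#' Per-frame ring-ring distance and orientation
#'
#' Distance between ring geometric centers and the normal-normal angle
#' (degrees, [0, 180], unfolded) for each frame.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param chainA,resnoA,chainB,resnoB the two ring-bearing residues.
#' @return an \linkS4class{InteractionSeries} tagged
#'   "ring_center-ring_center".
#' @export
ringRingSeries <- function(traj, chainA, resnoA, chainB, resnoB) {
  topo <- atoms(traj)
  nfr <- nFrames(traj)
  d <- ang <- numeric(nfr)
  for (f in seq_len(nfr)) {
    xyz <- coords(traj, f)
    ra <- .ringCoords(topo, xyz, chainA, resnoA)
    rb <- .ringCoords(topo, xyz, chainB, resnoB)
    d[f] <- .vnorm(colMeans(ra) - colMeans(rb))
    ang[f] <- .angleDeg(.planeNormal(ra), .planeNormal(rb))
  }
  new("InteractionSeries", times = traj@times, distance = d, angle = ang,
      definition = "ring_center-ring_center")
}

# single-atom position in a frame
.atomPos <- function(topo, xyz, chain, resno, elety) {
  for (e in elety) {
    w <- which(topo$chain == chain & topo$resno == resno & topo$elety == e)
    if (length(w)) return(xyz[w[1], ])
  }
  stop("atom ", chain, ":", resno, ":", paste(elety, collapse = "/"),
       " not found")
}

#' Interaction series between peptide P1 and a groove residue
#'
#' Implements the four atom-pair definitions used for P1 interactions with
#' the N-terminal groove residues:
#' \itemize{
#'  \item Phe P1 / Tyr59: distance between the ring geometric centers, plus
#'    the ring normal-normal angle;
#'  \item Ala P1 / Tyr59: P1 Cbeta to Tyr59 ring center;
#'  \item Phe P1 / Ile52: P1 ring center to Ile52 Cdelta;
#'  \item Ala P1 / Ile52: P1 Cbeta to Ile52 Cdelta.
#' }
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param positions a \linkS4class{PeptidePositionMap}.
#' @param partner "Tyr59" or "Ile52".
#' @param heavyChain heavy-chain id.
#' @param partnerResno residue number of the partner (default 59 or 52).
#' @return an \linkS4class{InteractionSeries}; angle is NA for Ala P1 or
#'   the Ile52 definitions.
#' @export
p1InteractionSeries <- function(traj, positions,
                                partner = c("Tyr59", "Ile52"),
                                heavyChain = "A", partnerResno = NULL) {
  partner <- match.arg(partner)
  topo <- atoms(traj)
  p1 <- positionResno(positions, "P1")
  pch <- positions@pepChain
  p1res <- unique(topo$resid[topo$chain == pch & topo$resno == p1])
  if (!length(p1res) || !p1res[1] %in% c("PHE", "ALA"))
    stop("P1 residue type '", paste(p1res, collapse = ","),
         "' unsupported; supported types: PHE, ALA")
  p1res <- p1res[1]
  if (is.null(partnerResno))
    partnerResno <- if (partner == "Tyr59") 59L else 52L
  nfr <- nFrames(traj)
  d <- numeric(nfr); ang <- rep(NA_real_, nfr)
  for (f in seq_len(nfr)) {
    xyz <- coords(traj, f)
    pPos <- if (p1res == "PHE")
      colMeans(.ringCoords(topo, xyz, pch, p1))
    else .atomPos(topo, xyz, pch, p1, "CB")
    if (partner == "Tyr59") {
      qr <- .ringCoords(topo, xyz, heavyChain, partnerResno)
      d[f] <- .vnorm(pPos - colMeans(qr))
      if (p1res == "PHE")
        ang[f] <- .angleDeg(.planeNormal(.ringCoords(topo, xyz, pch, p1)),
                            .planeNormal(qr))
    } else {
      qPos <- .atomPos(topo, xyz, heavyChain, partnerResno, c("CD1", "CD"))
      d[f] <- .vnorm(pPos - qPos)
    }
  }
  tag <- paste0(if (p1res == "PHE") "P1_ring" else "P1_CB", "-",
                if (partner == "Tyr59") "Tyr59_ring" else "Ile52_CD")
  new("InteractionSeries", times = traj@times, distance = d, angle = ang,
      definition = tag)
}

# three ideal methyl hydrogens on carbon `cd` whose heavy neighbor is `nb`:
# tetrahedral angle, 1.09 A bonds, arbitrary azimuth
.idealMethylH <- function(cd, nb) {
  axis <- .unit(cd - nb)
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .unit(ref - sum(ref * axis) * axis)
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  t(vapply(c(0, 2 * pi / 3, 4 * pi / 3), function(phi) {
    dirv <- cos(70.53 * pi / 180) * axis +
      sin(70.53 * pi / 180) * (cos(phi) * e1 + sin(phi) * e2)
    cd + 1.09 * dirv
  }, numeric(3)))
}

#' C-H-X angle of a CH-pi geometry
#'
#' Interior angle at the hydrogen between the H->C and H->ring-center
#' directions. A methyl carbon carries three hydrogens; the ring-facing one
#' (largest angle) is reported. When no hydrogen positions are supplied
#' (crystal structures), ideal tetrahedral hydrogens are constructed on the
#' carbon from its bonded heavy neighbor.
#'
#' @param carbon numeric length-3, the donor carbon (e.g. Ile52 Cdelta).
#' @param ringCenterPos numeric length-3, aromatic ring center.
#' @param hydrogens matrix of H positions bonded to the carbon, or NULL to
#'   construct ideal ones (requires \code{neighbor}).
#' @param neighbor heavy atom bonded to the carbon (e.g. Ile52 Cgamma1),
#'   needed only for construction.
#' @return angle in degrees, [0, 180].
#' @export
chPiAngle <- function(carbon, ringCenterPos, hydrogens = NULL,
                      neighbor = NULL) {
  if (is.null(hydrogens)) {
    if (is.null(neighbor))
      stop("no hydrogens given and no bonded neighbor to construct them from")
    hydrogens <- .idealMethylH(carbon, neighbor)
  }
  hydrogens <- matrix(hydrogens, ncol = 3)
  max(apply(hydrogens, 1, function(h)
    .angleDeg(carbon - h, ringCenterPos - h)))
}

#' Does a (distance, angle) pair satisfy the CH-pi criterion?
#'
#' TRUE iff distance <= \code{distMax} and angle >= \code{angleMin}.
#' Defaults (6.0 A ring-center-to-carbon, 120 degrees) follow the standard
#' literature criterion for CH-pi contacts; both are configurable.
#'
#' @param distance Angstrom (vectorized).
#' @param angle degrees (vectorized).
#' @param distMax,angleMin cutoffs.
#' @return logical vector.
#' @export
chPiSatisfied <- function(distance, angle, distMax = 6.0, angleMin = 120) {
  stopifnot(is.finite(distMax), is.finite(angleMin))
  is.finite(distance) & is.finite(angle) &
    distance <= distMax & angle >= angleMin
}

#' Classify pi-pi stacking configuration from ring-angle samples
#'
#' Folds each normal-normal angle onto the stacking deviation
#' s = min(theta, 180 - theta) in [0, 90], finds the peak of the s
#' distribution, and classifies: s >= \code{tShapedMin} degrees ->
#' "T-shaped"; s <= \code{parallelMax} -> "parallel-like"; otherwise
#' "intermediate". The fold makes the classification symmetric under
#' theta -> 180 - theta, so a 150-degree stacking peak classifies like a
#' 30-degree one.
#'
#' @param angles normal-normal angle samples, degrees.
#' @param tShapedMin,parallelMax class thresholds on s (defaults 60, 30).
#' @param binWidth histogram bin width for the peak, degrees.
#' @return list with elements \code{class}, \code{peakS} (degrees) and
#'   \code{s} (the folded samples).
#' @export
classifyPiPi <- function(angles, tShapedMin = 60, parallelMax = 30,
                         binWidth = 5) {
  if (!length(angles)) stop("no angle samples")
  s <- pmin(angles, 180 - angles)
  peakS <- if (length(s) > 1 && diff(range(s)) > 0) {
    d <- estimateDistribution(s, binWidth)
    # bin-center quantization can push a boundary peak across a class
    # threshold; refine with the median of samples in and adjacent to the
    # maximal bin
    ctr <- peakLocation(d)
    stats::median(s[abs(s - ctr) <= 1.5 * binWidth])
  } else s[1]
  # thresholds carry half-bin grace: a stacking peak sitting exactly on a
  # class boundary (e.g. a 150-degree ring angle, s = 30) classifies with
  # the boundary class rather than flipping on quantization noise
  grace <- binWidth / 2
  cls <- if (peakS >= tShapedMin - grace) "T-shaped"
         else if (peakS <= parallelMax + grace) "parallel-like"
         else "intermediate"
  list(class = cls, peakS = peakS, s = s)
}

#' Density-normalized histogram of samples
#'
#' @param samples numeric, >= 2 values (a degenerate all-equal sample is
#'   allowed and yields a single bin).
#' @param binWidth positive bin width in the sample units.
#' @return a \linkS4class{BinnedDistribution}; the peak is the center of
#'   the maximal bin (ties toward the lowest value) and fwhm the width of
#'   the region where density >= half its maximum.
#' @export
estimateDistribution <- function(samples, binWidth) {
  if (length(samples) < 2) stop("need at least 2 samples")
  if (!is.finite(binWidth) || binWidth <= 0)
    stop("bin width must be positive")
  lo <- floor(min(samples) / binWidth) * binWidth
  hi <- ceiling(max(samples) / binWidth) * binWidth
  if (hi <= lo) hi <- lo + binWidth
  breaks <- seq(lo, hi, by = binWidth)
  if (breaks[length(breaks)] < max(samples))
    breaks <- c(breaks, breaks[length(breaks)] + binWidth)
  h <- graphics::hist(samples, breaks = breaks, plot = FALSE)
  dens <- h$density
  peak <- h$mids[which.max(dens)]           # which.max takes the first tie
  above <- which(dens >= max(dens) / 2)
  fwhm <- breaks[max(above) + 1] - breaks[min(above)]
  new("BinnedDistribution", breaks = breaks, density = dens,
      peak = peak, fwhm = fwhm)
}

#' CH-pi interaction series between P1 and Ile52 along a trajectory
#'
#' Combines the Ile52 distance definition with the per-frame C-H-X angle
#' (explicit hydrogens when present in the topology, ideal construction
#' otherwise) and reports the fraction of frames satisfying the CH-pi
#' criterion.
#'
#' @inheritParams p1InteractionSeries
#' @param distMax,angleMin CH-pi cutoffs (see [chPiSatisfied()]).
#' @return list: \code{series} (the distance \linkS4class{InteractionSeries}),
#'   \code{angles} (C-H-X per frame), \code{satisfied} (logical per frame),
#'   \code{fraction}.
#' @export
chPiSeries <- function(traj, positions, heavyChain = "A",
                       partnerResno = 52L, distMax = 6.0, angleMin = 120) {
  ser <- p1InteractionSeries(traj, positions, "Ile52", heavyChain,
                             partnerResno)
  topo <- atoms(traj)
  p1 <- positionResno(positions, "P1")
  pch <- positions@pepChain
  hIdx <- which(topo$chain == heavyChain & topo$resno == partnerResno &
                  grepl("^HD", topo$elety))
  ang <- vapply(seq_len(nFrames(traj)), function(f) {
    xyz <- coords(traj, f)
    cd <- .atomPos(topo, xyz, heavyChain, partnerResno, c("CD1", "CD"))
    ctr <- colMeans(.ringCoords(topo, xyz, pch, p1))
    if (length(hIdx)) chPiAngle(cd, ctr, hydrogens = xyz[hIdx, , drop = FALSE])
    else {
      nb <- .atomPos(topo, xyz, heavyChain, partnerResno, c("CG1", "CG"))
      chPiAngle(cd, ctr, neighbor = nb)
    }
  }, numeric(1))
  sat <- chPiSatisfied(ser@distance, ang, distMax, angleMin)
  list(series = ser, angles = ang, satisfied = sat, fraction = mean(sat))
}
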