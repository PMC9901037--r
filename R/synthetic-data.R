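# run expr under a fixed seed without disturbing the caller's RNG stream;
# every generator is a pure function of (parameters, seed)
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(expr)
}

# ideal alpha-helical C-alpha trace: 100 deg/residue, 1.5 A rise, 2.3 A radius
.helixCA <- function(n) {
  i <- seq_len(n) - 1
  cbind(2.3 * cos(i * 100 * pi / 180),
        2.3 * sin(i * 100 * pi / 180),
        1.5 * i)
}

#' Synthetic trajectory with prescribed per-residue fluctuation
#'
#' A rigid helical C-alpha scaffold whose residue-i atom is displaced every
#' frame by i.i.d. isotropic Gaussian noise with per-coordinate standard
#' deviation \code{sigma[i]} (Angstrom). The expected RMSF of residue i is
#' \code{sigma[i] * sqrt(3)}, giving a closed-form ground truth for
#' fluctuation analysis. Optionally each frame additionally receives a
#' random global rigid motion, which frame superposition must remove.
#'
#' @param sigma numeric vector, per-residue per-coordinate amplitude (A);
#'   residue numbers are 1..length(sigma).
#' @param nFrames frame count (>= 2).
#' @param seed integer; fully determines the output.
#' @param chain chain id of the scaffold.
#' @param dtPs frame spacing, ps.
#' @param rigidMotion apply a random rigid motion per frame.
#' @return list: \code{trajectory} (a \linkS4class{Trajectory}) and
#'   \code{truth} (sigma and expected RMSF per residue).
#' @export
makeHarmonicTrajectory <- function(sigma, nFrames = 2000, seed = 1,
                                   chain = "A", dtPs = 20,
                                   rigidMotion = FALSE) {
  if (any(sigma < 0)) stop("amplitudes must be non-negative")
  if (nFrames < 2) stop("need at least 2 frames")
  n <- length(sigma)
  base <- .helixCA(n)
  co <- .withSeed(seed, {
    out <- array(NA_real_, c(nFrames, n, 3))
    for (f in seq_len(nFrames)) {
      xyz <- base + matrix(stats::rnorm(3 * n, sd = rep(sigma, 3)), ncol = 3)
      if (rigidMotion) {
        ax <- .unit(stats::rnorm(3)); th <- stats::runif(1, 0, 2 * pi)
        K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3)
        R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
        xyz <- xyz %*% t(R) + matrix(stats::rnorm(3, sd = 5), n, 3,
                                     byrow = TRUE)
      }
      out[f, , ] <- xyz
    }
    out
  })
  topo <- data.frame(chain = chain, resno = seq_len(n), resid = "ALA",
                     elety = "CA", stringsAsFactors = FALSE)
  list(trajectory = Trajectory(co, topo, times = (seq_len(nFrames) - 1) * dtPs),
       truth = list(sigma = sigma, expectedRmsf = sigma * sqrt(3)))
}

# hexagonal PHE/TYR-like ring, unit geometry, atoms in cyclic order,
# counterclockwise in its plane viewed from +normal
.hexRing <- function(radius = 1.39) {
  phi <- (seq_len(6) - 1) * 60 * pi / 180
  cbind(radius * cos(phi), radius * sin(phi), 0)
}

#' Synthetic aromatic ring pair at prescribed geometry
#'
#' Two six-membered rings: a PHE-like ring (chain P, residue 1) in the
#' xy-plane at the origin and a TYR-like ring (chain H, residue 59) whose
#' center sits \code{centerDist} Angstrom along +z and whose plane normal
#' is tilted by \code{normalAngle} degrees about x. Per-frame Gaussian
#' jitter of each atom position emulates thermal motion.
#'
#' @param centerDist ring-center separation, A (> 0).
#' @param normalAngle normal-normal angle, degrees in [0, 180].
#' @param jitter per-atom per-coordinate Gaussian sd, A.
#' @param nFrames frame count.
#' @param seed integer.
#' @param dtPs frame spacing, ps.
#' @return list: \code{trajectory} and \code{truth} (programmed distance
#'   and angle).
#' @export
makeRingPair <- function(centerDist, normalAngle, jitter = 0, nFrames = 1,
                         seed = 1, dtPs = 20) {
  stopifnot(centerDist > 0, normalAngle >= 0, normalAngle <= 180)
  ringA <- .hexRing()
  th <- normalAngle * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3)
  ringB <- .hexRing() %*% t(Rx)
  ringB[, 3] <- ringB[, 3] + centerDist
  base <- rbind(ringA, ringB)
  co <- .withSeed(seed, {
    out <- array(NA_real_, c(nFrames, 12, 3))
    for (f in seq_len(nFrames))
      out[f, , ] <- base + if (jitter > 0)
        matrix(stats::rnorm(36, sd = jitter), ncol = 3) else 0
    out
  })
  topo <- data.frame(
    chain = rep(c("P", "H"), each = 6),
    resno = rep(c(1L, 59L), each = 6),
    resid = rep(c("PHE", "TYR"), each = 6),
    elety = rep(.ringAtoms, 2), stringsAsFactors = FALSE)
  list(trajectory = Trajectory(co, topo, times = (seq_len(nFrames) - 1) * dtPs),
       truth = list(distance = centerDist, angle = normalAngle))
}

#' Synthetic wrapped dihedral trace with programmed rotation events
#'
#' The underlying smooth path starts at the first schedule value and makes
#' a sigmoidal transition to each subsequent value centered at its time;
#' Gaussian thermal noise is added and the result wrapped into
#' (-180, 180]. The programmed transition count is returned as ground
#' truth for event-detection tests.
#'
#' @param schedule data.frame with columns \code{timeNs}, \code{valueDeg}:
#'   row 1 is the initial level (its time marks the trace start), each
#'   later row a transition to a new level centered at its time. Values
#'   are on the unwrapped scale (e.g. an end level of -260 is the modulo
#'   equivalent of +100).
#' @param noiseSd Gaussian noise sd, degrees.
#' @param dtPs sampling interval, ps.
#' @param totalNs trace duration, ns.
#' @param seed integer.
#' @param widthNs transition width, ns; transitions closer than twice this
#'   are rejected as overlapping.
#' @return list: \code{series} (wrapped \linkS4class{AngleSeries}),
#'   \code{truth} (transition count and noiseless unwrapped path).
#' @export
makeRotationTrace <- function(schedule, noiseSd = 15, dtPs = 20,
                              totalNs = 300, seed = 1, widthNs = 10) {
  stopifnot(is.data.frame(schedule), nrow(schedule) >= 1,
            all(c("timeNs", "valueDeg") %in% names(schedule)))
  tk <- schedule$timeNs; vk <- schedule$valueDeg
  if (nrow(schedule) > 2 && any(diff(tk[-1]) < 2 * widthNs))
    stop("overlapping transitions: schedule times closer than 2x width")
  t <- seq(0, totalNs * 1000, by = dtPs)          # ps
  tNs <- t / 1000
  path <- rep(vk[1], length(t))
  if (length(vk) > 1) {
    for (k in 2:length(vk)) {
      step <- vk[k] - vk[k - 1]
      path <- path + step * stats::plogis((tNs - tk[k]) / (widthNs / 8))
    }
  }
  noisy <- .withSeed(seed, path + stats::rnorm(length(path), sd = noiseSd))
  wrapped <- wrapAngles(AngleSeries(t, noisy, wrapped = FALSE))
  list(series = wrapped,
       truth = list(nTransitions = length(vk) - 1L, path = path, times = t))
}

#' Synthetic gapped structure with engineered unmodeled ranges
#'
#' A poly-alanine helical backbone scaffold (N, CA, C, O per residue) with
#' the listed residue ranges omitted from the coordinate record but present
#' in the chain's sequence record - the signature of missing electron
#' density in a crystal structure.
#'
#' @param nRes construct length (residues 1..nRes).
#' @param missing list of c(first, last) ranges to leave unmodeled.
#' @param chain chain id.
#' @return a \linkS4class{StructureModel}.
#' @export
makeGappedStructure <- function(nRes = 180, missing = list(), chain = "A") {
  ca <- .helixCA(nRes)
  drop <- unlist(lapply(missing, function(r) seq.int(r[1], r[2])))
  keep <- setdiff(seq_len(nRes), drop)
  mk <- function(resno, off, elety) {
    data.frame(chain = chain, resno = resno, resid = "ALA", elety = elety,
               x = ca[resno, 1] + off[1], y = ca[resno, 2] + off[2],
               z = ca[resno, 3] + off[3], occ = 1, stringsAsFactors = FALSE)
  }
  rows <- lapply(keep, function(i) rbind(
    mk(i, c(-1.2, 0.5, -0.8), "N"), mk(i, c(0, 0, 0), "CA"),
    mk(i, c(1.2, 0.4, 0.7), "C"), mk(i, c(1.9, 1.4, 0.6), "O")))
  atoms <- do.call(rbind, rows)
  seqrec <- data.frame(resno = seq_len(nRes), resid = "ALA",
                       stringsAsFactors = FALSE)
  StructureModel(atoms, chainSeq = stats::setNames(list(seqrec), chain))
}

#' Synthetic thermal-denaturation curve
#'
#' A descending logistic in fluorescence with inflection at \code{tm} over
#' a 25-95 degree C grid in 0.1-degree steps, optionally with Gaussian
#' noise proportional to the curve amplitude.
#'
#' @param tm programmed inflection (melting) temperature, degrees C.
#' @param width logistic width parameter, degrees C.
#' @param noiseFrac noise sd as a fraction of the amplitude.
#' @param seed integer.
#' @param replicates number of replicate columns.
#' @param tMin,tMax,dT temperature grid.
#' @return list: \code{curve} (a \linkS4class{MeltCurve}) and \code{truth}
#'   (the programmed tm).
#' @export
makeMeltCurve <- function(tm, width = 3, noiseFrac = 0, seed = 1,
                          replicates = 1, tMin = 25, tMax = 95, dT = 0.1) {
  stopifnot(tm > tMin, tm < tMax, width > 0)
  tt <- seq(tMin, tMax, by = dT)
  amp <- 1000
  f0 <- amp / (1 + exp((tt - tm) / width)) + 100
  fl <- .withSeed(seed, {
    m <- matrix(rep(f0, replicates), ncol = replicates)
    if (noiseFrac > 0)
      m <- m + matrix(stats::rnorm(length(m), sd = noiseFrac * amp),
                      ncol = replicates)
    m
  })
  list(curve = MeltCurve(tt, fl), truth = list(tm = tm))
}
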