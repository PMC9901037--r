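#' Signed dihedral (torsion) angle of four points
#'
#' Standard IUPAC sign convention: looking down the p2->p3 bond, a
#' clockwise rotation of the far bond relative to the near bond is
#' positive. Result in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric length-3 positions, Angstrom.
#' @return degrees.
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (.vnorm(b1) < 1e-9 || .vnorm(b2) < 1e-9 || .vnorm(b3) < 1e-9)
    stop("coincident consecutive points; dihedral undefined")
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  if (.vnorm(n1) < 1e-9 || .vnorm(n2) < 1e-9)
    stop("collinear points; dihedral undefined")
  x <- sum(n1 * n2); y <- sum(cr(n1, n2) * .unit(b2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Construct an AngleSeries
#'
#' @param times ps, strictly increasing.
#' @param values degrees.
#' @param wrapped TRUE for values in (-180, 180].
#' @return an \linkS4class{AngleSeries}.
#' @export
AngleSeries <- function(times, values, wrapped = TRUE) {
  new("AngleSeries", times = as.numeric(times), values = as.numeric(values),
      wrapped = wrapped)
}

# atom index lookup for the omega dihedral:
# heavy Cys76 CA, peptide P7 CA, peptide P1 CA, peptide P1 N
.omegaAtomIdx <- function(topo, positions, heavyChain, heavyCysResno) {
  pch <- positions@pepChain
  pick <- function(ch, rn, el) {
    w <- which(topo$chain == ch & topo$resno == rn & topo$elety == el)
    if (!length(w)) stop("omega atom ", ch, ":", rn, ":", el, " not found")
    w[1]
  }
  c(pick(heavyChain, heavyCysResno, "CA"),
    pick(pch, positionResno(positions, "P7"), "CA"),
    pick(pch, positionResno(positions, "P1"), "CA"),
    pick(pch, positionResno(positions, "P1"), "N"))
}

#' Terminal-amino-group dihedral omega of a single structure
#'
#' The torsion over heavy-chain Cys76 CA, peptide P7 CA, P1 CA, P1 N.
#' Values near -100 degrees indicate the terminal amino group pointing up
#' out of the A pocket; values near +100 degrees the canonical
#' pointing-down state.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param positions a \linkS4class{PeptidePositionMap}.
#' @param heavyChain heavy-chain id.
#' @param heavyCysResno heavy-chain anchor cysteine (default 76).
#' @return degrees in (-180, 180].
#' @export
omegaDihedral <- function(model, positions, heavyChain = "A",
                          heavyCysResno = 76L) {
  xyz <- coords(model)
  i <- .omegaAtomIdx(atoms(model), positions, heavyChain, heavyCysResno)
  dihedralAngle(xyz[i[1], ], xyz[i[2], ], xyz[i[3], ], xyz[i[4], ])
}

#' Omega dihedral time series along a trajectory
#'
#' @param traj a \linkS4class{Trajectory}.
#' @inheritParams omegaDihedral
#' @return a wrapped \linkS4class{AngleSeries}.
#' @export
omegaSeries <- function(traj, positions, heavyChain = "A",
                        heavyCysResno = 76L) {
  i <- .omegaAtomIdx(atoms(traj), positions, heavyChain, heavyCysResno)
  vals <- vapply(seq_len(nFrames(traj)), function(f) {
    xyz <- coords(traj, f)
    dihedralAngle(xyz[i[1], ], xyz[i[2], ], xyz[i[3], ], xyz[i[4], ])
  }, numeric(1))
  AngleSeries(traj@times, vals, wrapped = TRUE)
}

#' Unwrap a wrapped angle series
#'
#' Requires the rotation between neighboring frames to be below 180
#' degrees: each value after the first is adjusted by the multiple of 360
#' degrees that makes |delta| < 180. A frame-to-frame change of exactly
#' 180 degrees is broken toward the smaller absolute adjustment and
#' flagged with a message. The output equals the input modulo 360 at every
#' sample.
#'
#' @param series a wrapped \linkS4class{AngleSeries}.
#' @return an unwrapped \linkS4class{AngleSeries}.
#' @export
unwrapAngles <- function(series) {
  stopifnot(is(series, "AngleSeries"))
  if (!isWrapped(series)) stop("series is already unwrapped")
  v <- series@values
  if (length(v) < 2) return(AngleSeries(series@times, v, wrapped = FALSE))
  d <- diff(v)
  if (any(abs(abs(d) - 180) < 1e-12))
    message("frame-to-frame change of exactly 180 degrees; ",
            "tie broken toward no adjustment")
  k <- floor((d + 180) / 360)            # |d - 360k| < 180; d = 180 -> k = 1
  k[abs(abs(d) - 180) < 1e-12] <- 0      # exact tie: smaller adjustment
  out <- v - c(0, cumsum(360 * k))
  AngleSeries(series@times, out, wrapped = FALSE)
}

#' Wrap an angle series into (-180, 180]
#'
#' @param series an \linkS4class{AngleSeries}.
#' @return a wrapped \linkS4class{AngleSeries}.
#' @export
wrapAngles <- function(series) {
  stopifnot(is(series, "AngleSeries"))
  v <- series@values
  w <- v - 360 * ceiling((v - 180) / 360)   # maps into (-180, 180]
  AngleSeries(series@times, w, wrapped = TRUE)
}

#' Sliding-window average of an unwrapped angle series
#'
#' Centered moving average over all samples within +/- window/2 in time;
#' truncated windows are used at the series edges. Smoothing a wrapped
#' series is refused (averaging across the branch cut is meaningless).
#'
#' @param series an unwrapped \linkS4class{AngleSeries}.
#' @param windowNs full window width in ns (default 10, suitable for
#'   suppressing thermal fluctuation in equilibrium traces).
#' @return an unwrapped-state \linkS4class{AngleSeries} (wrap invariant no
#'   longer enforced sample-to-sample; stored unwrapped).
#' @export
smoothAngles <- function(series, windowNs = 10) {
  stopifnot(is(series, "AngleSeries"))
  if (isWrapped(series)) stop("unwrap first: refusing to smooth wrapped angles")
  t <- series@times; v <- series@values
  if (windowNs * 1000 > (t[length(t)] - t[1]) + 1e-9)
    stop("window exceeds series duration")
  half <- windowNs * 1000 / 2            # ps
  cs <- c(0, cumsum(v))
  lo <- findInterval(t - half - 1e-9, t) + 1L
  hi <- findInterval(t + half + 1e-9, t)
  sm <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  AngleSeries(t, sm, wrapped = FALSE)
}

# circular distance in degrees between a value and a band center (mod 360)
.circDist <- function(v, center) {
  abs(((v - center + 180) %% 360) - 180)
}

#' Detect rotation events in a smoothed omega trace
#'
#' An event is recorded at the first time the series, having dwelt in the
#' start band for at least \code{dwellNs}, enters within tolerance of the
#' end value modulo 360 degrees (so an unwrapped excursion to -260 degrees
#' registers as reaching +100). After an event the detector re-arms only
#' once the series re-enters the start band, so multiple events can be
#' reported. Default bands -100 +/- 45 (amino group pointing up) and
#' +100 +/- 45 degrees (pointing down).
#'
#' @param series an unwrapped, smoothed \linkS4class{AngleSeries}.
#' @param startDeg,endDeg band centers, degrees.
#' @param tolDeg band half-width, degrees.
#' @param dwellNs minimum dwell in the start band before an event can
#'   register (rejects single-frame noise).
#' @return numeric vector of event times (ps); length 0 when no rotation.
#' @export
detectRotation <- function(series, startDeg = -100, endDeg = 100,
                           tolDeg = 45, dwellNs = 1) {
  stopifnot(is(series, "AngleSeries"))
  if (isWrapped(series)) stop("unwrap (and smooth) first")
  t <- series@times; v <- series@values
  inStart <- .circDist(v, startDeg) <= tolDeg
  inEnd <- .circDist(v, endDeg) <= tolDeg
  events <- numeric(0)
  armed <- FALSE
  dwell <- 0
  for (i in seq_along(v)) {
    if (inStart[i]) {
      dwell <- dwell + if (i > 1) (t[i] - t[i - 1]) else 0
      if (dwell >= dwellNs * 1000) armed <- TRUE
    } else if (!inEnd[i]) {
      dwell <- 0                        # in transit: keep armed state
    }
    if (armed && inEnd[i]) {
      events <- c(events, t[i])
      armed <- FALSE
      dwell <- 0
    }
  }
  events
}
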