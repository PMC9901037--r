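#' Construct a Trajectory
#'
#' @param coords frames x atoms x 3 array (a single n x 3 matrix is
#'   promoted to one frame).
#' @param topology data.frame with chain, resno, resid, elety.
#' @param times per-frame times in ps; default a 20-ps grid, the
#'   conformational sampling interval used for equilibrium ensembles here.
#' @return a \linkS4class{Trajectory}.
#' @export
Trajectory <- function(coords, topology, times = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(1, nrow(coords), 3))
  if (is.null(times)) times <- (seq_len(dim(coords)[1]) - 1) * 20
  topology$resno <- as.integer(topology$resno)
  new("Trajectory", coords = coords, times = as.numeric(times),
      topology = topology[, c("chain", "resno", "resid", "elety")])
}

#' Read a multi-model PDB file as a Trajectory
#'
#' Each MODEL block becomes one frame; a single-structure file yields a
#' one-frame trajectory. The atom order of the first model defines the
#' topology and every frame must match it.
#'
#' @param path multi-model PDB file.
#' @param dtPs frame spacing in ps used to stamp times (default 20).
#' @return a \linkS4class{Trajectory}.
#' @export
readTrajectory <- function(path, dtPs = 20) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("cannot parse ", path, ": ",
                                           conditionMessage(e)))
  a <- pdb$atom
  a <- a[!(a$resid %in% .solvent), , drop = FALSE]
  if (!nrow(a)) stop("no polymer atoms in ", path)
  keep <- !(pdb$atom$resid %in% .solvent)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  sel <- as.vector(rbind(3 * which(keep) - 2, 3 * which(keep) - 1,
                         3 * which(keep)))
  xyz <- xyz[, sel, drop = FALSE]
  nfr <- nrow(xyz); nat <- nrow(a)
  if (ncol(xyz) != 3 * nat)
    stop("atom-count mismatch between frames in ", path)
  co <- array(NA_real_, c(nfr, nat, 3))
  for (f in seq_len(nfr)) co[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  topo <- data.frame(chain = a$chain, resno = as.integer(a$resno),
                     resid = a$resid, elety = a$elety,
                     stringsAsFactors = FALSE)
  Trajectory(co, topo, times = (seq_len(nfr) - 1) * dtPs)
}

#' Write a Trajectory as a multi-model PDB file
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeTrajectory <- function(traj, path) {
  topo <- traj@topology
  n <- nrow(topo)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nFrames(traj))) {
    xyz <- coords(traj, f)
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(.pdbAtomLine(seq_len(n), topo$elety, topo$resid, topo$chain,
                            topo$resno, xyz[, 1], xyz[, 2], xyz[, 3], 1),
               con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Extract one frame as a StructureModel
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param frame frame index.
#' @return a \linkS4class{StructureModel}.
#' @export
frameModel <- function(traj, frame = 1L) {
  xyz <- coords(traj, frame)
  a <- traj@topology
  StructureModel(data.frame(a, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            occ = 1, stringsAsFactors = FALSE))
}

#' Superpose every frame onto a common reference
#'
#' Removes global rigid-body motion by least-squares fitting the selected
#' atoms of every frame onto a reference: either the first frame or (the
#' default for fluctuation analysis) the mean structure, computed by a
#' two-pass procedure - fit to the first frame, recompute the mean once,
#' refit.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param fitSel integer atom indices used for the fit (>= 3, non-collinear
#'   in every frame); default all C-alpha atoms.
#' @param reference "mean" (two-pass) or "first".
#' @return a new \linkS4class{Trajectory} with transformed coordinates.
#' @export
superposeFrames <- function(traj, fitSel = NULL,
                            reference = c("mean", "first")) {
  reference <- match.arg(reference)
  if (is.null(fitSel)) fitSel <- selectAtoms(traj, elety = "CA")
  if (length(fitSel) < 3) stop("fit selection must contain >= 3 atoms")
  fitOnce <- function(co, ref) {
    out <- co
    for (f in seq_len(dim(co)[1])) {
      xyz <- matrix(co[f, , ], ncol = 3)
      k <- kabschSuperpose(xyz[fitSel, , drop = FALSE], ref)
      out[f, , ] <- applyTransform(xyz, k)
    }
    out
  }
  ref <- matrix(traj@coords[1, fitSel, ], ncol = 3)
  co <- fitOnce(traj@coords, ref)
  if (reference == "mean") {
    ref <- apply(co[, fitSel, , drop = FALSE], c(2, 3), mean)
    co <- fitOnce(traj@coords, ref)
  }
  initialize(traj, coords = co)
}

#' Per-residue root mean square fluctuation
#'
#' After removing global motion, the RMSF of atom i is
#' sqrt(mean over frames of the squared deviation from its time-average
#' position); per-residue values are the mean over the residue's selected
#' atoms (C-alpha only by default).
#'
#' @param traj a \linkS4class{Trajectory} (>= 2 frames).
#' @param fitSel atom indices for the superposition fit; default all
#'   C-alpha atoms. Set NULL with \code{superpose = FALSE} if the
#'   trajectory is already aligned.
#' @param measureElety atom name(s) entering the per-residue mean
#'   (default "CA"; use NULL for all heavy atoms).
#' @param superpose superpose in-call (two-pass mean reference) first.
#' @return an \linkS4class{RMSFProfile}.
#' @export
rmsfProfile <- function(traj, fitSel = NULL, measureElety = "CA",
                        superpose = TRUE) {
  if (nFrames(traj) < 2) stop("RMSF undefined for a single frame")
  if (superpose) {
    if (is.null(fitSel)) fitSel <- selectAtoms(traj, elety = "CA")
    traj <- superposeFrames(traj, fitSel, reference = "mean")
  }
  msel <- if (is.null(measureElety)) seq_len(nrow(traj@topology))
          else selectAtoms(traj, elety = measureElety)
  co <- traj@coords[, msel, , drop = FALSE]
  mu <- apply(co, c(2, 3), mean)
  dev2 <- sweep(co, c(2, 3), mu)^2
  atomRmsf <- sqrt(apply(dev2, 2, mean) * 3)   # mean over frames & xyz, x3
  topo <- traj@topology[msel, , drop = FALSE]
  key <- paste(topo$chain, topo$resno)
  agg <- tapply(atomRmsf, key, mean)
  first <- !duplicated(key)
  prof <- data.frame(chain = topo$chain[first], resno = topo$resno[first],
                     rmsf = as.numeric(agg[key[first]]),
                     stringsAsFactors = FALSE)
  prof <- prof[order(prof$chain, prof$resno), ]
  rownames(prof) <- NULL
  new("RMSFProfile", profile = prof,
      fitSelection = if (superpose) paste(length(fitSel), "atoms") else "pre-aligned",
      measureSelection = if (is.null(measureElety)) "all"
                         else paste(measureElety, collapse = ","))
}
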