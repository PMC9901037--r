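.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

.writeTsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Manually construct a peptide position map
#'
#' Escape hatch for systems where the disulfide anchor cannot be detected
#' automatically (see [resolvePeptidePositions()]), and for synthetic
#' fixtures.
#'
#' @param pepChain peptide chain id.
#' @param labels character vector of P labels.
#' @param resno parallel integer author residue numbers.
#' @return a \linkS4class{PeptidePositionMap}.
#' @export
peptidePositionMap <- function(pepChain, labels, resno) {
  new("PeptidePositionMap", pepChain = pepChain, labels = labels,
      resno = as.integer(resno))
}

#' Structure comparison report
#'
#' Runs the crystal-structure stage end to end over a set of structures:
#' unmodeled-region detection on the heavy chain, the crystal-state
#' terminal-amino-group dihedral omega, peptide-heavy contact networks,
#' and per-P-position C-alpha shift tables for each structure pair.
#' All values are computed by the stage operations; the report only
#' tabulates them.
#'
#' @param structures named list of \linkS4class{StructureModel} objects or
#'   file paths.
#' @param outDir output directory (created if needed).
#' @param heavyChain,pepChain chain roles, identical across structures.
#' @param heavyCysResno disulfide anchor residue on the heavy chain.
#' @param fitResno heavy-chain residues defining the superposition frame
#'   (default 1:180, the alpha1/alpha2 domain).
#' @param pairs list of c(nameA, nameB) pairs to compare; default all
#'   unordered pairs.
#' @param criteria [contactCriteria()] for the contact stage.
#' @return invisibly, a list with the report tables (\code{missing},
#'   \code{omega}, \code{shifts}, \code{contacts}) and output paths.
#' @export
runStructureReport <- function(structures, outDir, heavyChain = "A",
                               pepChain = "C", heavyCysResno = 76L,
                               fitResno = 1:180, pairs = NULL,
                               criteria = contactCriteria()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  structures <- .stage("read", lapply(structures, function(s)
    if (is.character(s)) readStructure(s) else s))
  nm <- names(structures)
  if (is.null(nm)) stop("structures must be a named list")

  missing <- .stage("unmodeled-regions", do.call(rbind, lapply(nm, function(k) {
    d <- detectUnmodeledRegions(structures[[k]], heavyChain)
    if (nrow(d)) cbind(structure = k, d) else NULL
  })))
  if (is.null(missing))
    missing <- data.frame(structure = character(0), chain = character(0),
                          first = integer(0), last = integer(0),
                          length = integer(0))

  maps <- .stage("peptide-positions", lapply(structures, function(s)
    resolvePeptidePositions(s, pepChain, heavyChain, heavyCysResno)))

  omega <- .stage("omega-crystal", data.frame(
    structure = nm,
    omega_deg = vapply(nm, function(k)
      omegaDihedral(structures[[k]], maps[[k]], heavyChain, heavyCysResno),
      numeric(1)), row.names = NULL))

  contacts <- .stage("contacts", do.call(rbind, lapply(nm, function(k) {
    s <- structures[[k]]
    selP <- selectAtoms(s, chain = pepChain)
    selH <- selectAtoms(s, chain = heavyChain)
    cb <- rbind(findHBonds(s, selP, selH, criteria),
                findHydrophobicContacts(s, selP, selH, criteria))
    if (nrow(cb)) cbind(structure = k, cb) else NULL
  })))
  if (is.null(contacts)) contacts <- cbind(structure = character(0),
                                           .emptyContacts())

  if (is.null(pairs) && length(nm) > 1)
    pairs <- utils::combn(nm, 2, simplify = FALSE)
  shifts <- .stage("ca-shifts", do.call(rbind, lapply(pairs, function(pr) {
    a <- structures[[pr[1]]]; b <- structures[[pr[2]]]
    la <- positionLabels(maps[[pr[1]]]); lb <- positionLabels(maps[[pr[2]]])
    shared <- intersect(names(la), names(lb))
    # displacement is measured between identically labeled P positions;
    # author numbering may differ between constructs
    d <- vapply(shared, function(pl) {
      caDisplacement(a, b, list(c(pepChain, la[[pl]])), heavyChain,
                     fitResno)[[1]]
    }, numeric(1))
    data.frame(pair = paste(pr[1], "vs", pr[2]), position = shared,
               shift_A = round(d, 2), row.names = NULL)
  })))

  paths <- list(
    missing = .writeTsv(missing, file.path(outDir, "missing_regions.tsv")),
    omega = .writeTsv(omega, file.path(outDir, "omega_crystal.tsv")),
    contacts = .writeTsv(contacts, file.path(outDir, "contacts.tsv")),
    shifts = if (!is.null(shifts))
      .writeTsv(shifts, file.path(outDir, "ca_shifts.tsv")))
  invisible(list(missing = missing, omega = omega, shifts = shifts,
                 contacts = contacts, paths = paths))
}

#' Trajectory interaction report
#'
#' Runs the equilibrium-ensemble stage: per-residue RMSF of the heavy
#' chain, P1 interaction series against Tyr59 and Ile52, their distance
#' (and ring-angle) probability distributions with peak and width, the
#' pi-pi stacking classification, and the fraction of frames satisfying
#' the CH-pi criterion.
#'
#' @param traj a \linkS4class{Trajectory} or multi-model PDB path.
#' @param outDir output directory.
#' @param positions a \linkS4class{PeptidePositionMap}, or NULL to resolve
#'   from the first frame via the disulfide anchor.
#' @param heavyChain,pepChain,heavyCysResno chain roles.
#' @param partners which groove partners to analyze.
#' @param distBinWidth,angleBinWidth histogram bin widths (A, degrees).
#' @param chPiDistMax,chPiAngleMin CH-pi criterion cutoffs.
#' @return invisibly, a list with rmsf profile, series, distributions,
#'   pi-pi class, CH-pi fraction and output paths.
#' @export
runTrajectoryReport <- function(traj, outDir, positions = NULL,
                                heavyChain = "A", pepChain = "C",
                                heavyCysResno = 76L,
                                partners = c("Tyr59", "Ile52"),
                                distBinWidth = 0.25, angleBinWidth = 5,
                                chPiDistMax = 6.0, chPiAngleMin = 120) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(traj)) traj <- .stage("read", readTrajectory(traj))
  if (is.null(positions))
    positions <- .stage("peptide-positions",
      resolvePeptidePositions(frameModel(traj, 1), pepChain, heavyChain,
                              heavyCysResno))

  heavySel <- selectAtoms(traj, chain = heavyChain, elety = "CA")
  prof <- .stage("rmsf", if (length(heavySel) >= 3)
    rmsfProfile(traj, fitSel = heavySel)
  else rmsfProfile(traj, superpose = FALSE, measureElety = NULL))
  paths <- list(rmsf = .writeTsv(rmsfValues(prof),
                                 file.path(outDir, "rmsf.tsv")))

  summary <- list(n_frames = nFrames(traj))
  seriesOut <- list(); distOut <- list()
  for (p in partners) {
    ser <- .stage(paste0("interaction-", p),
                  p1InteractionSeries(traj, positions, p, heavyChain))
    seriesOut[[p]] <- ser
    tab <- interactionTable(ser)
    paths[[paste0("series_", p)]] <-
      .writeTsv(tab, file.path(outDir, paste0("interactions_", p, ".tsv")))
    dd <- estimateDistribution(ser@distance, distBinWidth)
    distOut[[p]] <- dd
    paths[[paste0("hist_", p)]] <- .writeTsv(
      data.frame(bin_mid = (dd@breaks[-1] + dd@breaks[-length(dd@breaks)]) / 2,
                 density = dd@density),
      file.path(outDir, paste0("dist_hist_", p, ".tsv")))
    summary[[paste0("distance_peak_", p)]] <- peakLocation(dd)
    summary[[paste0("distance_fwhm_", p)]] <- dd@fwhm
    if (p == "Tyr59" && !all(is.na(ser@angle))) {
      cls <- classifyPiPi(ser@angle)
      ad <- estimateDistribution(ser@angle, angleBinWidth)
      summary$pi_pi_class <- cls$class
      summary$angle_peak_Tyr59 <- peakLocation(ad)
    }
    if (p == "Ile52") {
      chpi <- .stage("ch-pi", chPiSeries(traj, positions, heavyChain,
                                         distMax = chPiDistMax,
                                         angleMin = chPiAngleMin))
      summary$ch_pi_fraction <- chpi$fraction
    }
  }
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  paths$summary <- file.path(outDir, "summary.json")
  invisible(list(rmsf = prof, series = seriesOut, distributions = distOut,
                 summary = summary, paths = paths))
}

#' Rotation (omega evolution) report over replicate trajectories
#'
#' For each replicate: the raw wrapped omega series, its unwrapped and
#' smoothed forms, and detected rotation events; plus the summary
#' "k of n replicates rotated".
#'
#' @param replicates list of wrapped \linkS4class{AngleSeries} (or
#'   \linkS4class{Trajectory} objects, requiring \code{positions}).
#' @param outDir output directory.
#' @param positions a \linkS4class{PeptidePositionMap} when trajectories
#'   are supplied.
#' @param heavyChain,heavyCysResno omega atom anchors for trajectories.
#' @param windowNs smoothing window, ns.
#' @param startDeg,endDeg,tolDeg,dwellNs event-detection bands.
#' @return invisibly, a list: per-replicate tables, \code{events},
#'   \code{nRotated} and the "k of n" \code{summary} string.
#' @export
runRotationReport <- function(replicates, outDir, positions = NULL,
                              heavyChain = "A", heavyCysResno = 76L,
                              windowNs = 10, startDeg = -100, endDeg = 100,
                              tolDeg = 45, dwellNs = 1) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  res <- lapply(seq_along(replicates), function(i) {
    r <- replicates[[i]]
    if (is(r, "Trajectory")) {
      if (is.null(positions))
        stop("positions required when replicates are trajectories")
      r <- omegaSeries(r, positions, heavyChain, heavyCysResno)
    }
    un <- unwrapAngles(r)
    sm <- smoothAngles(un, windowNs)
    ev <- detectRotation(sm, startDeg, endDeg, tolDeg, dwellNs)
    tab <- data.frame(time_ps = r@times, omega_raw = r@values,
                      omega_unwrapped = un@values, omega_smoothed = sm@values)
    .writeTsv(tab, file.path(outDir, sprintf("omega_rep%d.tsv", i)))
    list(table = tab, events = ev)
  })
  events <- lapply(res, `[[`, "events")
  nRot <- sum(vapply(events, function(e) length(e) > 0, logical(1)))
  summaryStr <- sprintf("%d of %d replicates rotated", nRot,
                        length(replicates))
  jsonlite::write_json(
    list(summary = summaryStr, n_rotated = nRot,
         n_replicates = length(replicates),
         events_ps = events),
    file.path(outDir, "rotation_summary.json"), auto_unbox = TRUE,
    digits = NA)
  invisible(list(replicates = res, events = events, nRotated = nRot,
                 summary = summaryStr))
}

#' Read and validate a pipeline run configuration
#'
#' YAML with top-level keys \code{outDir}, \code{seed} and any of the
#' stage blocks \code{structure}, \code{trajectory}, \code{rotation};
#' unknown top-level keys are rejected. Referenced files must exist.
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("outDir", "seed", "structure", "trajectory", "rotation")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (is.null(cfg$outDir)) stop("config needs outDir")
  for (blk in c("structure", "trajectory", "rotation")) {
    fls <- unlist(cfg[[blk]][["files"]] %||% cfg[[blk]][["file"]])
    for (f in fls) if (!file.exists(f)) stop("missing input file: ", f)
  }
  cfg
}

#' Run the configured pipeline stages
#'
#' Dispatches to [runStructureReport()], [runTrajectoryReport()] and
#' [runRotationReport()] for each stage block present in the config, and
#' echoes the effective configuration into the output directory.
#'
#' @param cfg config list from [readRunConfig()].
#' @return invisibly, a named list of stage results.
#' @export
runPipeline <- function(cfg) {
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(cfg$outDir, "effective_config.yaml"))
  out <- list()
  if (!is.null(cfg$structure)) {
    s <- cfg$structure
    out$structure <- runStructureReport(
      as.list(s$files), file.path(cfg$outDir, "structure"),
      heavyChain = s$heavyChain %||% "A", pepChain = s$pepChain %||% "C",
      heavyCysResno = s$heavyCys %||% 76L)
  }
  if (!is.null(cfg$trajectory)) {
    s <- cfg$trajectory
    out$trajectory <- runTrajectoryReport(
      s$file, file.path(cfg$outDir, "trajectory"),
      heavyChain = s$heavyChain %||% "A", pepChain = s$pepChain %||% "C",
      heavyCysResno = s$heavyCys %||% 76L)
  }
  if (!is.null(cfg$rotation)) {
    s <- cfg$rotation
    reps <- lapply(s$files, function(f) {
      d <- utils::read.table(f, header = TRUE, sep = "\t")
      AngleSeries(d[[1]], d[[2]], wrapped = TRUE)
    })
    out$rotation <- runRotationReport(
      reps, file.path(cfg$outDir, "rotation"),
      windowNs = s$window_ns %||% 10)
  }
  invisible(out)
}
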