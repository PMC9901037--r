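# donor/acceptor dictionary for the 20 standard residues.
# backbone N donates (except PRO), backbone O accepts; side-chain polar
# atoms listed explicitly. His N atoms can act as both.
.hbDonorAtoms <- list(
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
  TRP = "NE1", TYR = "OH", CYS = "SG")
.hbAcceptorAtoms <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH", MET = "SD")
.stdResidues <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

.isDonor <- function(resid, elety) {
  (elety == "N" & resid != "PRO") |
    mapply(function(r, e) e %in% (.hbDonorAtoms[[r]] %||% character(0)),
           resid, elety, USE.NAMES = FALSE)
}
.isAcceptor <- function(resid, elety) {
  (elety == "O") |
    mapply(function(r, e) e %in% (.hbAcceptorAtoms[[r]] %||% character(0)),
           resid, elety, USE.NAMES = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Contact detection criteria
#'
#' Numeric criteria for hydrogen-bond and hydrophobic contact detection.
#' Defaults are field-standard: donor-acceptor distance up to 3.5 A with a
#' donor-H-acceptor angle of at least 120 degrees when hydrogens are
#' present (crystal structures usually lack them, in which case the
#' distance criterion alone applies), and carbon-carbon distance up to
#' 4.5 A for hydrophobic contacts.
#'
#' @param hbondDistMax donor-acceptor maximum distance, Angstrom.
#' @param hbondAngleMin minimum D-H-A angle, degrees.
#' @param hydrophobicDistMax carbon-carbon maximum distance, Angstrom.
#' @return a list of class "ContactCriteria".
#' @export
contactCriteria <- function(hbondDistMax = 3.5, hbondAngleMin = 120,
                            hydrophobicDistMax = 4.5) {
  stopifnot(hbondDistMax > 0, hydrophobicDistMax > 0,
            hbondAngleMin > 0, hbondAngleMin <= 180)
  structure(list(hbondDistMax = hbondDistMax, hbondAngleMin = hbondAngleMin,
                 hydrophobicDistMax = hydrophobicDistMax),
            class = "ContactCriteria")
}

# all pairwise distances between two atom-table subsets
.pairTable <- function(a, ia, ib) {
  A <- a[ia, , drop = FALSE]; B <- a[ib, , drop = FALSE]
  g <- expand.grid(i = seq_len(nrow(A)), j = seq_len(nrow(B)))
  # drop self and intra-residue pairs
  sameAtom <- A$chain[g$i] == B$chain[g$j] & A$resno[g$i] == B$resno[g$j]
  g <- g[!sameAtom, , drop = FALSE]
  d <- sqrt((A$x[g$i] - B$x[g$j])^2 + (A$y[g$i] - B$y[g$j])^2 +
              (A$z[g$i] - B$z[g$j])^2)
  cbind(g, dist = d)
}

# canonical partner ordering so selector swap yields identical output
.canonContacts <- function(df) {
  if (!nrow(df)) return(df)
  keyA <- paste(df$chainA, sprintf("%06d", df$resnoA), df$atomA)
  keyB <- paste(df$chainB, sprintf("%06d", df$resnoB), df$atomB)
  swap <- keyA > keyB
  if (any(swap)) {
    tmp <- df[swap, c("chainA", "resnoA", "residA", "atomA")]
    df[swap, c("chainA", "resnoA", "residA", "atomA")] <-
      df[swap, c("chainB", "resnoB", "residB", "atomB")]
    df[swap, c("chainB", "resnoB", "residB", "atomB")] <- tmp
  }
  df <- df[order(df$dist), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Find hydrogen bonds between two selections
#'
#' Reports all donor-acceptor pairs across the two selections satisfying
#' the distance criterion and, when explicit hydrogens exist on the donor,
#' the D-H-A angle criterion. Donor/acceptor typing uses a fixed dictionary
#' covering the 20 standard residues; non-standard residues are skipped
#' with a warning.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param selA,selB integer atom index vectors (see [selectAtoms()]).
#' @param criteria a [contactCriteria()] list.
#' @return data.frame (kind, chainA, resnoA, residA, atomA, chainB, resnoB,
#'   residB, atomB, dist, angle) sorted by distance; angle is NA when no
#'   hydrogen was available.
#' @export
findHBonds <- function(model, selA, selB, criteria = contactCriteria()) {
  a <- atoms(model)
  nonstd <- unique(a$resid[c(selA, selB)][!a$resid[c(selA, selB)] %in%
                                            .stdResidues])
  if (length(nonstd))
    warning("skipping non-standard residue(s): ", paste(nonstd, collapse = ","))
  polar <- function(sel) {
    s <- a[sel, , drop = FALSE]
    ok <- s$resid %in% .stdResidues
    sel[ok & (.isDonor(s$resid, s$elety) | .isAcceptor(s$resid, s$elety))]
  }
  pa <- polar(selA); pb <- polar(selB)
  if (!length(pa) || !length(pb))
    return(.emptyContacts())
  pt <- .pairTable(a, pa, pb)
  pt <- pt[pt$dist <= criteria$hbondDistMax, , drop = FALSE]
  if (!nrow(pt)) return(.emptyContacts())
  A <- a[pa, , drop = FALSE]; B <- a[pb, , drop = FALSE]
  rows <- lapply(seq_len(nrow(pt)), function(k) {
    ra <- A[pt$i[k], ]; rb <- B[pt$j[k], ]
    dA <- .isDonor(ra$resid, ra$elety); aA <- .isAcceptor(ra$resid, ra$elety)
    dB <- .isDonor(rb$resid, rb$elety); aB <- .isAcceptor(rb$resid, rb$elety)
    if (!((dA && aB) || (dB && aA))) return(NULL)
    donor <- if (dA && aB) ra else rb
    accpt <- if (dA && aB) rb else ra
    ang <- .dhaAngle(a, donor, accpt)
    if (!is.na(ang) && ang < criteria$hbondAngleMin) return(NULL)
    data.frame(kind = "hbond",
               chainA = ra$chain, resnoA = ra$resno, residA = ra$resid,
               atomA = ra$elety,
               chainB = rb$chain, resnoB = rb$resno, residB = rb$resid,
               atomB = rb$elety, dist = pt$dist[k], angle = ang,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(.emptyContacts())
  .canonContacts(out)
}

.emptyContacts <- function() {
  data.frame(kind = character(0), chainA = character(0), resnoA = integer(0),
             residA = character(0), atomA = character(0),
             chainB = character(0), resnoB = integer(0),
             residB = character(0), atomB = character(0),
             dist = numeric(0), angle = numeric(0), stringsAsFactors = FALSE)
}

# D-H-A angle using the hydrogen bonded to the donor, when modeled;
# with several (e.g. NH2) the most favorable is used
.dhaAngle <- function(a, donor, accpt) {
  hs <- a[a$chain == donor$chain & a$resno == donor$resno &
            grepl("^H", a$elety), , drop = FALSE]
  if (!nrow(hs)) return(NA_real_)
  dpos <- as.numeric(donor[c("x", "y", "z")])
  apos <- as.numeric(accpt[c("x", "y", "z")])
  hx <- as.matrix(hs[, c("x", "y", "z")])
  bonded <- sqrt(rowSums(sweep(hx, 2, dpos)^2)) < 1.3
  if (!any(bonded)) return(NA_real_)
  max(apply(hx[bonded, , drop = FALSE], 1, function(h)
    .angleDeg(dpos - h, apos - h)))
}

#' Find hydrophobic carbon-carbon contacts between two selections
#'
#' Carbon-carbon pairs within the hydrophobic cutoff, deduplicated per
#' residue pair with the minimum distance retained.
#'
#' @inheritParams findHBonds
#' @return data.frame as in [findHBonds()] with kind "hydrophobic" and
#'   angle NA.
#' @export
findHydrophobicContacts <- function(model, selA, selB,
                                    criteria = contactCriteria()) {
  a <- atoms(model)
  carbons <- function(sel) {
    s <- a[sel, , drop = FALSE]
    sel[grepl("^C", s$elety) & !grepl("^CL", s$elety)]
  }
  ca <- carbons(selA); cb <- carbons(selB)
  if (!length(ca) || !length(cb)) return(.emptyContacts())
  pt <- .pairTable(a, ca, cb)
  pt <- pt[pt$dist <= criteria$hydrophobicDistMax, , drop = FALSE]
  if (!nrow(pt)) return(.emptyContacts())
  A <- a[ca, , drop = FALSE]; B <- a[cb, , drop = FALSE]
  out <- data.frame(kind = "hydrophobic",
                    chainA = A$chain[pt$i], resnoA = A$resno[pt$i],
                    residA = A$resid[pt$i], atomA = A$elety[pt$i],
                    chainB = B$chain[pt$j], resnoB = B$resno[pt$j],
                    residB = B$resid[pt$j], atomB = B$elety[pt$j],
                    dist = pt$dist, angle = NA_real_,
                    stringsAsFactors = FALSE)
  out <- .canonContacts(out)
  respair <- paste(out$chainA, out$resnoA, out$chainB, out$resnoB)
  out <- out[!duplicated(respair), , drop = FALSE]  # sorted by dist: min kept
  rownames(out) <- NULL
  out
}
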