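#' Construct a StructureModel from an atom table
#'
#' @param atoms data.frame with columns chain, resno, resid, elety, x, y, z
#'   and optionally occ (defaults to 1).
#' @param chainSeq optional named list of data.frames (resno, resid) giving
#'   each chain's full construct sequence.
#' @return a \linkS4class{StructureModel}.
#' @export
StructureModel <- function(atoms, chainSeq = list()) {
  if (is.null(atoms$occ)) atoms$occ <- 1
  atoms$resno <- as.integer(atoms$resno)
  atoms <- atoms[, c("chain", "resno", "resid", "elety", "x", "y", "z", "occ")]
  rownames(atoms) <- NULL
  new("StructureModel", atoms = atoms, chainSeq = chainSeq)
}

# residue names treated as solvent/ions, dropped on read
.solvent <- c("HOH", "WAT", "DOD", "NA", "CL", "K", "MG", "CA2", "ZN", "SO4",
              "PO4", "GOL", "EDO", "PEG", "ACT")

#' Read a structure file (PDB or mmCIF)
#'
#' Parses all polymer ATOM/HETATM records, resolves alternate locations to
#' the highest-occupancy conformer (ties broken by altloc identifier order),
#' and populates per-chain sequence records from SEQRES/entity_poly when
#' present, else from the observed residues.
#'
#' The sequence record of a PDB file carries no residue numbers; author
#' numbering is assumed to start at \code{seqStart} (default 1, the
#' convention for MHC class I heavy chains). If the modeled residues of a
#' chain fall outside that numbering the sequence record is dropped for
#' that chain with a warning and gap detection falls back to numeric gaps
#' only.
#'
#' @param path file path.
#' @param format "auto" (by extension), "pdb" or "cif".
#' @param seqStart assumed author residue number of the first sequence-record
#'   residue (per chain, recycled).
#' @return a \linkS4class{StructureModel}.
#' @export
readStructure <- function(path, format = c("auto", "pdb", "cif"),
                          seqStart = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") suppressWarnings(bio3d::read.cif(path,
                                                          verbose = FALSE))
    else bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("cannot parse ", path, " as ", format, ": ",
                             conditionMessage(e)))
  a <- pdb$atom
  a <- a[!(a$resid %in% .solvent), , drop = FALSE]
  if (!nrow(a)) stop("no polymer atoms in ", path)
  # altloc resolution: highest occupancy wins, ties by altloc order
  occ <- ifelse(is.na(a$o), 1, a$o)
  alt <- ifelse(is.na(a$alt), "", a$alt)
  ord <- order(a$chain, a$resno, a$elety, -occ, alt)
  a <- a[ord, , drop = FALSE]
  occ <- occ[ord]
  key <- paste(a$chain, a$resno, a$elety)
  keep <- !duplicated(key)
  a <- a[keep, , drop = FALSE]
  occ <- occ[keep]
  # restore file order among kept atoms
  fo <- order(as.integer(rownames(a)))
  a <- a[fo, , drop = FALSE]
  occ <- occ[fo]
  atoms <- data.frame(chain = a$chain, resno = as.integer(a$resno),
                      resid = a$resid, elety = a$elety,
                      x = a$x, y = a$y, z = a$z, occ = occ,
                      stringsAsFactors = FALSE)
  chainSeq <- list()
  sr <- pdb$seqres
  if (!is.null(sr) && length(sr)) {
    for (ch in unique(names(sr))) {
      res <- unname(sr[names(sr) == ch])
      n <- length(res)
      rng <- seq.int(seqStart, seqStart + n - 1L)
      modeled <- unique(atoms$resno[atoms$chain == ch])
      if (length(modeled) && (min(modeled) < seqStart ||
                              max(modeled) > seqStart + n - 1L)) {
        warning("chain ", ch, ": modeled residue numbers fall outside the ",
                "assumed sequence-record numbering; dropping its sequence record")
        next
      }
      chainSeq[[ch]] <- data.frame(resno = as.integer(rng), resid = res,
                                   stringsAsFactors = FALSE)
    }
  }
  StructureModel(atoms, chainSeq)
}

# fixed-width PDB ATOM line; name < 4 chars starts in column 14
.pdbAtomLine <- function(serial, elety, resid, chain, resno, x, y, z, occ) {
  name4 <- ifelse(nchar(elety) < 4, sprintf(" %-3s", elety),
                  sprintf("%-4s", elety))
  elem <- sub("^([A-Za-z]).*", "\\1", gsub("[0-9]", "", elety))
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name4, resid, chain, resno, x, y, z, occ, 0, elem)
}

.seqresLines <- function(chainSeq) {
  out <- character(0)
  for (ch in names(chainSeq)) {
    res <- chainSeq[[ch]]$resid
    n <- length(res)
    chunks <- split(res, ceiling(seq_along(res) / 13))
    for (i in seq_along(chunks)) {
      out <- c(out, sprintf("SEQRES %3d %1s %4d  %s", i, ch, n,
                            paste(sprintf("%-3s", chunks[[i]]), collapse = " ")))
    }
  }
  out
}

#' Write a StructureModel as a PDB file
#'
#' Emits SEQRES records for chains carrying a sequence record, then ATOM
#' records in table order. Coordinates round-trip at the format's printed
#' precision (0.001 Angstrom).
#'
#' @param model a \linkS4class{StructureModel}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeStructure <- function(model, path) {
  a <- atoms(model)
  lines <- c(.seqresLines(model@chainSeq),
             .pdbAtomLine(seq_len(nrow(a)), a$elety, a$resid, a$chain,
                          a$resno, a$x, a$y, a$z, a$occ),
             "END")
  writeLines(lines, path)
  invisible(path)
}

#' Select atoms from a structure or trajectory topology
#'
#' Resolution is deterministic and order-stable: the returned indices follow
#' the atom-table order of the model.
#'
#' @param x a \linkS4class{StructureModel} or \linkS4class{Trajectory}.
#' @param chain chain id(s), or NULL for any.
#' @param resno residue number(s), or NULL for any.
#' @param elety atom name(s), or NULL for any.
#' @param resid residue name filter, or NULL.
#' @return integer atom indices.
#' @export
selectAtoms <- function(x, chain = NULL, resno = NULL, elety = NULL,
                        resid = NULL) {
  a <- atoms(x)
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  which(keep)
}

#' Parse a compact selection string
#'
#' Syntax \code{"CHAIN:RESRANGE:ATOM"}, e.g. \code{"H:1-180:CA"},
#' \code{"P:*:*"}, \code{"H:52:CD1"}. \code{*} is a wildcard; the residue
#' field accepts \code{a-b} ranges and comma lists.
#'
#' @param x model or trajectory to resolve against.
#' @param spec selection string.
#' @return integer atom indices.
#' @export
parseSelection <- function(x, spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3) stop("selection must be CHAIN:RES:ATOM, got '",
                               spec, "'")
  chain <- if (parts[1] == "*") NULL else parts[1]
  resno <- if (parts[2] == "*") NULL else {
    unlist(lapply(strsplit(parts[2], ",")[[1]], function(tok) {
      if (grepl("-", tok)) {
        ab <- as.integer(strsplit(tok, "-")[[1]])
        seq.int(ab[1], ab[2])
      } else as.integer(tok)
    }))
  }
  elety <- if (parts[3] == "*") NULL else strsplit(parts[3], ",")[[1]]
  selectAtoms(x, chain = chain, resno = resno, elety = elety)
}

# collapse a sorted integer vector into maximal runs
.runs <- function(v) {
  if (!length(v)) return(data.frame(first = integer(0), last = integer(0)))
  v <- sort(unique(v))
  brk <- c(0, which(diff(v) > 1), length(v))
  data.frame(first = v[brk[-length(brk)] + 1], last = v[brk[-1]])
}

#' Detect unmodeled (missing-density) residue ranges
#'
#' Returns the maximal runs of residues absent from the coordinate record of
#' a chain, found from (a) gaps in author numbering between consecutive
#' modeled residues and (b) sequence-record residues never modeled (terminal
#' disorder), when a sequence record exists. Residues with any modeled atom
#' count as modeled; side-chain-only disorder is not reported.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param chain chain id.
#' @return data.frame with columns chain, first, last, length, sorted by
#'   first residue; zero rows when the chain is fully modeled.
#' @export
detectUnmodeledRegions <- function(model, chain) {
  a <- atoms(model)
  if (!chain %in% a$chain) stop("chain '", chain, "' not present in model")
  modeled <- sort(unique(a$resno[a$chain == chain]))
  expected <- if (!is.null(model@chainSeq[[chain]]))
    model@chainSeq[[chain]]$resno
  else seq.int(min(modeled), max(modeled))
  miss <- setdiff(expected, modeled)
  r <- .runs(miss)
  data.frame(chain = rep(chain, nrow(r)), first = r$first, last = r$last,
             length = r$last - r$first + 1L, stringsAsFactors = FALSE)
}

#' Map peptide residues to canonical P positions
#'
#' Locates the peptide cysteine whose Sgamma lies within disulfide distance
#' of the heavy-chain Cys76 Sgamma (the engineered disulfide trap), labels
#' it P7, sets P1 six chain positions N-terminal to it, and labels modeled
#' residues before P1 as extensions P-1, P-2, ... and after P7 as P8, ...
#'
#' @param model a \linkS4class{StructureModel}.
#' @param pepChain peptide chain id.
#' @param heavyChain heavy-chain id.
#' @param heavyCysResno heavy-chain cysteine residue number (default 76).
#' @param sgCutoff Sgamma-Sgamma disulfide cutoff in Angstrom (default 2.5).
#' @return a \linkS4class{PeptidePositionMap}.
#' @export
resolvePeptidePositions <- function(model, pepChain, heavyChain,
                                    heavyCysResno = 76L, sgCutoff = 2.5) {
  a <- atoms(model)
  hs <- a[a$chain == heavyChain & a$resno == heavyCysResno &
            a$elety == "SG", , drop = FALSE]
  if (nrow(hs) != 1)
    stop("no Sgamma found for heavy-chain Cys", heavyCysResno,
         "; specify the P7 anchor manually")
  ps <- a[a$chain == pepChain & a$resid == "CYS" & a$elety == "SG", ,
          drop = FALSE]
  if (!nrow(ps))
    stop("peptide chain ", pepChain, " has no cysteine Sgamma; ",
         "cannot locate the P7 disulfide anchor - specify positions manually")
  d <- sqrt((ps$x - hs$x)^2 + (ps$y - hs$y)^2 + (ps$z - hs$z)^2)
  hit <- which(d <= sgCutoff)
  if (!length(hit))
    stop("no peptide cysteine within ", sgCutoff,
         " A of heavy-chain Cys", heavyCysResno,
         " Sgamma (closest ", round(min(d), 2),
         " A); specify positions manually")
  p7 <- ps$resno[hit[which.min(d[hit])]]
  resnos <- sort(unique(a$resno[a$chain == pepChain]))
  i7 <- match(p7, resnos)
  i1 <- i7 - 6L
  if (i1 < 1)
    stop("peptide has fewer than 6 modeled residues N-terminal to P7 Cys")
  off <- seq_along(resnos) - i1 + 1L          # P-number of each residue
  labels <- ifelse(off >= 1, paste0("P", off), paste0("P-", 1L - off))
  new("PeptidePositionMap", pepChain = pepChain, labels = labels,
      resno = as.integer(resnos))
}
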