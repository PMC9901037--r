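# vector helpers shared across geometry code
.vnorm <- function(v) sqrt(sum(v * v))
.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("zero-length vector")
  v / n
}
.angleDeg <- function(u, v) {
  c <- sum(.unit(u) * .unit(v))
  acos(max(-1, min(1, c))) * 180 / pi
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' paired coordinate sets, via SVD of the covariance matrix with the
#' determinant sign correction that excludes reflections.
#'
#' @param mobile,reference n x 3 matrices of paired coordinates, n >= 3
#'   non-collinear points.
#' @return a \linkS4class{SuperpositionResult}; the transform maps mobile
#'   onto reference as \code{x' = R (x - centerMobile) + centerReference}.
#' @export
kabschSuperpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3)
    stop("mobile and reference must be equal-size n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3) stop("superposition needs at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  M <- sweep(mobile, 2, cm); R0 <- sweep(reference, 2, cr)
  # collinearity check: centered points must span a plane
  if (sum(svd(M)$d > 1e-9) < 2 || sum(svd(R0)$d > 1e-9) < 2)
    stop("degenerate (collinear) geometry; superposition undefined")
  H <- crossprod(M, R0)                      # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)   # proper rotation
  fitted <- M %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - R0)^2)))
  new("SuperpositionResult", rotation = R, centerMobile = cm,
      centerReference = cr, rmsd = rmsd, nAtomsFit = as.integer(n))
}

#' Apply a superposition transform to coordinates
#'
#' @param coordinates n x 3 matrix.
#' @param fit a \linkS4class{SuperpositionResult}.
#' @return transformed n x 3 matrix.
#' @export
applyTransform <- function(coordinates, fit) {
  stopifnot(is(fit, "SuperpositionResult"))
  sweep(sweep(as.matrix(coordinates), 2, fit@centerMobile) %*%
          t(fit@rotation), 2, fit@centerReference, "+")
}

#' RMSD accessor
#' @param x a \linkS4class{SuperpositionResult}.
#' @export
rmsdValue <- function(x) {
  stopifnot(is(x, "SuperpositionResult"))
  x@rmsd
}

#' C-alpha displacement of a target residue between two structures
#'
#' Superposes structure \code{b} onto structure \code{a} on the C-alpha
#' atoms of the fit selection (restricted to residues modeled in both
#' structures) and returns the Euclidean distance between the target
#' C-alpha positions. The default fit frame is the heavy-chain alpha1/alpha2
#' domain (residues 1-180), the conventional peptide-MHC reference frame.
#'
#' @param modelA,modelB \linkS4class{StructureModel} objects.
#' @param target list or data.frame of (chain, resno) targets; a single
#'   target may be given as \code{c(chain, resno)}.
#' @param fitChain chain used for the fit (default "A"-style heavy chain
#'   must be supplied by the caller).
#' @param fitResno residue numbers of the fit selection (default 1:180).
#' @return named numeric vector of displacements (Angstrom, one per
#'   target), names "chain:resno".
#' @export
caDisplacement <- function(modelA, modelB, target, fitChain,
                           fitResno = 1:180) {
  aA <- atoms(modelA); aB <- atoms(modelB)
  caA <- aA[aA$chain == fitChain & aA$elety == "CA" &
              aA$resno %in% fitResno, , drop = FALSE]
  caB <- aB[aB$chain == fitChain & aB$elety == "CA" &
              aB$resno %in% fitResno, , drop = FALSE]
  shared <- intersect(caA$resno, caB$resno)
  if (length(shared) < 3)
    stop("fit selection shares fewer than 3 modeled C-alpha atoms")
  caA <- caA[match(shared, caA$resno), ]
  caB <- caB[match(shared, caB$resno), ]
  fit <- kabschSuperpose(as.matrix(caB[, c("x", "y", "z")]),
                         as.matrix(caA[, c("x", "y", "z")]))
  if (!is.list(target) && !is.data.frame(target))
    target <- list(target)
  if (is.data.frame(target))
    target <- split(target, seq_len(nrow(target)))
  out <- vapply(target, function(tg) {
    ch <- as.character(tg[[1]]); rn <- as.integer(tg[[2]])
    pa <- aA[aA$chain == ch & aA$resno == rn & aA$elety == "CA", , drop = FALSE]
    pb <- aB[aB$chain == ch & aB$resno == rn & aB$elety == "CA", , drop = FALSE]
    if (nrow(pa) != 1 || nrow(pb) != 1)
      stop("target C-alpha ", ch, ":", rn, " missing in one of the models")
    pbt <- applyTransform(as.matrix(pb[, c("x", "y", "z")]), fit)
    .vnorm(pbt - as.numeric(pa[, c("x", "y", "z")]))
  }, numeric(1))
  names(out) <- vapply(target, function(tg)
    paste0(as.character(tg[[1]]), ":", as.integer(tg[[2]])), character(1))
  out
}
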