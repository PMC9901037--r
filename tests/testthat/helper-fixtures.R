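# geometry helpers and in-code fixtures shared across tests

rotationMatrix <- function(axis, angleDeg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

applyRigid <- function(xyz, R, tr) {
  sweep(xyz %*% t(R), 2, tr, "+")
}

randomRigid <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3)
  list(R = rotationMatrix(ax, runif(1, 0, 360)), tr = rnorm(3, sd = 10))
}

# regular hexagon with given center and in-plane rotation; atoms in cyclic
# order, counterclockwise viewed from +z before any rotation is applied
hexagonXY <- function(radius = 1, center = c(0, 0, 0)) {
  phi <- (0:5) * 60 * pi / 180
  sweep(cbind(radius * cos(phi), radius * sin(phi), 0), 2, center, "+")
}

# independent superposition oracle: minimize rmsd over rotations
# parameterized by unit quaternions - coarse grid then Nelder-Mead polish
bruteForceRmsd <- function(mobile, reference) {
  M <- sweep(mobile, 2, colMeans(mobile))
  R0 <- sweep(reference, 2, colMeans(reference))
  quatToRot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
             2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
             2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
           3)
  }
  obj <- function(q) {
    if (sum(q^2) < 1e-12) return(1e9)
    sqrt(mean(rowSums((M %*% t(quatToRot(q)) - R0)^2)))
  }
  set.seed(42)
  grid <- matrix(rnorm(4 * 4000), ncol = 4)
  vals <- apply(grid, 1, obj)
  best <- grid[which.min(vals), ]
  for (k in 1:4) {
    o <- optim(best, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-15))
    best <- o$par
  }
  o$value
}

# minimal disulfide-trapped peptide-MHC fixture: helical heavy chain "A"
# (CA 1..90 plus Cys76 SG, Tyr59 ring, Ile52 CD1/CG1, Asn63 ND2) and an
# 8mer peptide chain "C" with Phe P1 (ring) and Cys P7 anchored to Cys76
makeComplexFixture <- function(omegaTargetPerturb = 0) {
  ca <- GrooveFlex:::.helixCA(90)
  heavy <- data.frame(chain = "A", resno = 1:90, resid = "ALA", elety = "CA",
                      x = ca[, 1], y = ca[, 2], z = ca[, 3], occ = 1,
                      stringsAsFactors = FALSE)
  heavy$resid[heavy$resno == 76] <- "CYS"
  heavy$resid[heavy$resno == 59] <- "TYR"
  heavy$resid[heavy$resno == 52] <- "ILE"
  heavy$resid[heavy$resno == 63] <- "ASN"
  addAtom <- function(df, resno, resid, elety, pos) {
    rbind(df, data.frame(chain = "A", resno = resno, resid = resid,
                         elety = elety, x = pos[1], y = pos[2], z = pos[3],
                         occ = 1, stringsAsFactors = FALSE))
  }
  sg76 <- ca[76, ] + c(2, 0, 0)
  heavy <- addAtom(heavy, 76, "CYS", "SG", sg76)
  ring59 <- sweep(hexagonXY(1.39), 2, ca[59, ] + c(3, 1, 0), "+")
  for (i in 1:6) heavy <- addAtom(heavy, 59, "TYR",
                                  GrooveFlex:::.ringAtoms[i], ring59[i, ])
  heavy <- addAtom(heavy, 52, "ILE", "CG1", ca[52, ] + c(1.0, 1.0, 0))
  heavy <- addAtom(heavy, 52, "ILE", "CD1", ca[52, ] + c(1.8, 1.8, 0.5))
  heavy <- addAtom(heavy, 63, "ASN", "ND2", ca[63, ] + c(2.5, 0, 0))

  # peptide: 8 residues spaced 3.8 A along x, offset from the heavy chain
  base <- c(30, 0, 0)
  pep <- do.call(rbind, lapply(1:8, function(i) {
    p <- base + c(3.8 * (i - 1), 0, 0)
    data.frame(chain = "C", resno = i,
               resid = c("PHE", rep("ALA", 5), "CYS", "LEU")[i],
               elety = "CA", x = p[1], y = p[2], z = p[3], occ = 1,
               stringsAsFactors = FALSE)
  }))
  addPep <- function(df, resno, resid, elety, pos) {
    rbind(df, data.frame(chain = "C", resno = resno, resid = resid,
                         elety = elety, x = pos[1], y = pos[2], z = pos[3],
                         occ = 1, stringsAsFactors = FALSE))
  }
  # P7 SG 2.0 A from heavy Cys76 SG
  pep <- addPep(pep, 7, "CYS", "SG", sg76 + c(0, 2.0, 0))
  # P1 amide N off-axis so the omega dihedral is non-degenerate
  p1 <- base
  pep <- addPep(pep, 1, "PHE", "N",
                p1 + c(-1.0, 1.0, 0.5 + omegaTargetPerturb))
  ringP1 <- sweep(hexagonXY(1.39), 2, p1 + c(0, 2.5, 1.5), "+")
  for (i in 1:6) pep <- addPep(pep, 1, "PHE",
                               GrooveFlex:::.ringAtoms[i], ringP1[i, ])
  StructureModel(rbind(heavy, pep))
}
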