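# a one-frame trajectory holding a single PHE-like ring at given coords
ringTraj <- function(xyz, chain = "P", resno = 1L, resid = "PHE") {
  topo <- data.frame(chain = chain, resno = resno, resid = resid,
                     elety = GrooveFlex:::.ringAtoms,
                     stringsAsFactors = FALSE)
  Trajectory(xyz, topo)
}

test_that("ring center is the unweighted atom mean", {
  t0 <- ringTraj(hexagonXY(1))
  expect_equal(ringCenter(t0, "P", 1), c(0, 0, 0), tolerance = 1e-12)
  t1 <- ringTraj(sweep(hexagonXY(1), 2, c(3, 4, 0), "+"))
  expect_equal(ringCenter(t1, "P", 1), c(3, 4, 0), tolerance = 1e-12)
  set.seed(71)
  pts <- matrix(rnorm(18), 6)
  expect_equal(ringCenter(ringTraj(pts), "P", 1), colSums(pts) / 6,
               tolerance = 1e-12)
})

test_that("fewer than five ring atoms is an error", {
  xyz <- hexagonXY(1)[1:4, ]
  topo <- data.frame(chain = "P", resno = 1L, resid = "PHE",
                     elety = GrooveFlex:::.ringAtoms[1:4])
  expect_error(ringCenter(Trajectory(xyz, topo), "P", 1), "5 ring atoms")
})

test_that("ring normal sign follows the atom ordering", {
  ccw <- ringTraj(hexagonXY(1))
  expect_equal(ringNormal(ccw, "P", 1), c(0, 0, 1), tolerance = 1e-9)
  cw <- ringTraj(hexagonXY(1)[6:1, ])
  expect_equal(ringNormal(cw, "P", 1), c(0, 0, -1), tolerance = 1e-9)
})

test_that("plane fit tolerates out-of-plane noise and rigid motion", {
  set.seed(72)
  noisy <- hexagonXY(1.39)
  noisy[, 3] <- rnorm(6, sd = 0.1)
  n <- ringNormal(ringTraj(noisy), "P", 1)
  # within 5 degrees of the noiseless normal, via the SVD fit
  expect_lt(acos(abs(sum(n * c(0, 0, 1)))) * 180 / pi, 5)
  # reproducible on a rotated copy
  rr <- randomRigid(88)
  moved <- ringTraj(applyRigid(noisy, rr$R, rr$tr))
  n2 <- ringNormal(moved, "P", 1)
  expect_equal(.angle <- acos(pmin(1, sum((rr$R %*% n) * n2))) * 180 / pi, 0,
               tolerance = 1e-6)
  expect_error(ringNormal(ringTraj(cbind(1:6, 0, 0)), "P", 1), "collinear")
})

test_that("programmed ring-pair geometry is measured exactly at zero jitter", {
  for (case in list(c(6, 90), c(5, 0), c(6, 150), c(7.5, 45))) {
    rp <- makeRingPair(case[1], case[2], jitter = 0, nFrames = 1)
    ser <- ringRingSeries(rp$trajectory, "P", 1, "H", 59)
    expect_equal(ser@distance, case[1], tolerance = 1e-9)
    expect_equal(ser@angle, case[2], tolerance = 1e-9)
  }
})

test_that("angles and distances are invariant under whole-frame rigid motion", {
  rp <- makeRingPair(6, 110, jitter = 0.05, nFrames = 3, seed = 4)
  ser <- ringRingSeries(rp$trajectory, "P", 1, "H", 59)
  rr <- randomRigid(91)
  co <- rp$trajectory@coords
  for (f in 1:3) co[f, , ] <- applyRigid(matrix(co[f, , ], ncol = 3),
                                         rr$R, rr$tr)
  moved <- Trajectory(co, atoms(rp$trajectory))
  ser2 <- ringRingSeries(moved, "P", 1, "H", 59)
  expect_equal(ser2@distance, ser@distance, tolerance = 1e-9)
  expect_equal(ser2@angle, ser@angle, tolerance = 1e-6)
})

test_that("P1 interaction definitions follow the residue types", {
  # Phe P1 vs Tyr59: ring centers + normal angle
  rp <- makeRingPair(5, 0, jitter = 0, nFrames = 1)
  pos <- peptidePositionMap("P", "P1", 1L)
  ser <- p1InteractionSeries(rp$trajectory, pos, "Tyr59", heavyChain = "H")
  expect_equal(ser@distance, 5, tolerance = 1e-9)
  expect_equal(ser@angle, 0, tolerance = 1e-9)
  perp <- makeRingPair(6, 90, jitter = 0, nFrames = 1)
  expect_equal(p1InteractionSeries(perp$trajectory, pos, "Tyr59",
                                   heavyChain = "H")@angle, 90,
               tolerance = 1e-9)

  # Ala P1 vs Tyr59: Cbeta to ring center, no angle
  topo <- data.frame(
    chain = c("P", rep("H", 6)), resno = c(1L, rep(59L, 6)),
    resid = c("ALA", rep("TYR", 6)),
    elety = c("CB", GrooveFlex:::.ringAtoms), stringsAsFactors = FALSE)
  xyz <- rbind(c(0, 0, 7), hexagonXY(1.39))
  serA <- p1InteractionSeries(Trajectory(xyz, topo), pos, "Tyr59",
                              heavyChain = "H")
  expect_equal(serA@distance, 7, tolerance = 1e-9)
  expect_true(is.na(serA@angle))

  # unsupported P1 type
  topo$resid[1] <- "TRP"
  expect_error(p1InteractionSeries(Trajectory(xyz, topo), pos, "Tyr59",
                                   heavyChain = "H"),
               "supported types: PHE, ALA")
})

test_that("P1-Ile52 distances use the Cdelta definitions", {
  # Phe P1 ring center to Ile52 CD1
  topo <- data.frame(
    chain = c(rep("P", 6), "H", "H"), resno = c(rep(1L, 6), 52L, 52L),
    resid = c(rep("PHE", 6), "ILE", "ILE"),
    elety = c(GrooveFlex:::.ringAtoms, "CG1", "CD1"),
    stringsAsFactors = FALSE)
  xyz <- rbind(hexagonXY(1.39), c(0, 0, 3.5), c(0, 0, 5))
  pos <- peptidePositionMap("P", "P1", 1L)
  ser <- p1InteractionSeries(Trajectory(xyz, topo), pos, "Ile52",
                             heavyChain = "H")
  expect_equal(ser@distance, 5, tolerance = 1e-9)
  expect_equal(ser@definition, "P1_ring-Ile52_CD")

  # Ala P1 Cbeta to Cdelta
  topoA <- data.frame(chain = c("P", "H"), resno = c(1L, 52L),
                      resid = c("ALA", "ILE"), elety = c("CB", "CD1"))
  serA <- p1InteractionSeries(Trajectory(rbind(c(0, 0, 0), c(3, 4, 0)),
                                         topoA), pos, "Ile52",
                              heavyChain = "H")
  expect_equal(serA@distance, 5, tolerance = 1e-9)
  expect_equal(serA@definition, "P1_CB-Ile52_CD")
})

test_that("the C-H-X angle spans collinear to right-angle geometry", {
  cd <- c(0, 0, 0); h <- c(0, 0, 1.09)
  expect_equal(chPiAngle(cd, c(0, 0, 5), hydrogens = rbind(h)), 180,
               tolerance = 1e-9)
  expect_equal(chPiAngle(cd, c(4, 0, 1.09), hydrogens = rbind(h)), 90,
               tolerance = 1e-9)
  # ideal construction with the ring on the methyl symmetry axis: every
  # tetrahedral H makes the same closed-form angle with the axis point
  ang <- chPiAngle(cd, c(0, 0, 5), neighbor = c(0, 0, -1.5))
  th <- 70.53 * pi / 180
  hpos <- 1.09 * c(sin(th), 0, cos(th))
  expected <- acos(sum((cd - hpos) * (c(0, 0, 5) - hpos)) /
                     (sqrt(sum((cd - hpos)^2)) *
                        sqrt(sum((c(0, 0, 5) - hpos)^2)))) * 180 / pi
  expect_equal(ang, expected, tolerance = 1e-6)
  expect_error(chPiAngle(cd, c(0, 0, 5)), "no bonded neighbor")
})

test_that("the CH-pi criterion is a monotone conjunction", {
  expect_true(chPiSatisfied(5.0, 135))
  expect_false(chPiSatisfied(10.0, 140))
  expect_false(chPiSatisfied(4.0, 90))
  # loosening either cutoff never flips TRUE -> FALSE
  set.seed(73)
  d <- runif(200, 2, 12); a <- runif(200, 60, 180)
  base <- chPiSatisfied(d, a, distMax = 6, angleMin = 120)
  looserD <- chPiSatisfied(d, a, distMax = 7.5, angleMin = 120)
  looserA <- chPiSatisfied(d, a, distMax = 6, angleMin = 100)
  expect_true(all(looserD[base]))
  expect_true(all(looserA[base]))
})

test_that("pi-pi classification folds and classifies by the s peak", {
  set.seed(74)
  tShape <- classifyPiPi(rnorm(500, 90, 3))
  expect_equal(tShape$class, "T-shaped")
  par150 <- classifyPiPi(rnorm(500, 150, 3))
  expect_equal(par150$class, "parallel-like")   # s = 30
  par0 <- classifyPiPi(abs(rnorm(500, 0, 3)))
  expect_equal(par0$class, "parallel-like")
  mid <- classifyPiPi(rnorm(500, 135, 3))       # s = 45
  expect_equal(mid$class, "intermediate")
  # fold symmetry: theta and 180 - theta classify identically
  th <- runif(300, 0, 180)
  expect_equal(classifyPiPi(th)$class, classifyPiPi(180 - th)$class)
  expect_error(classifyPiPi(numeric(0)), "no angle samples")
})

test_that("histograms normalize, locate peaks and handle edge cases", {
  d <- estimateDistribution(rep(5, 100), 0.25)
  expect_lte(abs(peakLocation(d) - 5), 0.125)
  expect_equal(sum(d@density * diff(d@breaks)), 1, tolerance = 1e-9)

  set.seed(75)
  g <- estimateDistribution(rnorm(1e4, 6, 0.8), 0.25)
  expect_lte(abs(peakLocation(g) - 6), 0.25)

  u <- estimateDistribution(runif(1e5), 0.05)
  expect_lt(max(abs(u@density - 1)), 0.1)

  expect_error(estimateDistribution(rnorm(10), 0), "positive")
  expect_error(estimateDistribution(rnorm(10), -1), "positive")
  expect_error(estimateDistribution(5, 0.1), "at least 2")
})

test_that("ring-pair ensembles reproduce programmed angle distributions", {
  rp <- makeRingPair(6, 150, jitter = 0.1, nFrames = 500, seed = 19)
  ser <- ringRingSeries(rp$trajectory, "P", 1, "H", 59)
  ad <- estimateDistribution(ser@angle, 5)
  expect_lte(abs(peakLocation(ad) - 150), 5)
  dd <- estimateDistribution(ser@distance, 0.25)
  expect_lte(abs(peakLocation(dd) - 6), 0.5)
})

test_that("CH-pi series on MD-like geometry reports the satisfied fraction", {
  # build frames with the ring center ~5 A from CD1 and explicit HD1
  # hydrogens pointing toward the ring: the 20mer-like geometry band
  n <- 50
  co <- array(NA_real_, c(n, 9, 3))
  set.seed(76)
  for (f in 1:n) {
    ring <- sweep(hexagonXY(1.39), 2, c(0, 0, 5 + rnorm(1, 0, 0.1)), "+")
    cd <- c(0, 0, 0)
    h <- c(0.25, 0, 1.05) + rnorm(3, 0, 0.02)   # points near the ring axis
    cg <- c(0, 0, -1.53)
    co[f, , ] <- rbind(ring, cd, h, cg)
  }
  topo <- data.frame(
    chain = c(rep("P", 6), "H", "H", "H"),
    resno = c(rep(1L, 6), 52L, 52L, 52L),
    resid = c(rep("PHE", 6), "ILE", "ILE", "ILE"),
    elety = c(GrooveFlex:::.ringAtoms, "CD1", "HD11", "CG1"),
    stringsAsFactors = FALSE)
  pos <- peptidePositionMap("P", "P1", 1L)
  res <- chPiSeries(Trajectory(co, topo), pos, heavyChain = "H")
  expect_true(all(res$angles > 120 & res$angles < 180))
  expect_equal(res$fraction, 1)
})
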