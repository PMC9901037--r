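test_that("dihedral reproduces trans/cis and standard sign convention", {
  # planar zigzag (trans)
  expect_equal(dihedralAngle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                             c(1, -1, 0)), 180, tolerance = 1e-9)
  # eclipsed planar (cis)
  expect_equal(dihedralAngle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                             c(1, 1, 0)), 0, tolerance = 1e-9)
  # +60 gauche by the IUPAC convention, cross-checked independently
  p <- list(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
            c(1, cos(60 * pi / 180), sin(60 * pi / 180)))
  ref <- bio3d::torsion.xyz(as.vector(t(do.call(rbind, p))))
  expect_equal(dihedralAngle(p[[1]], p[[2]], p[[3]], p[[4]]),
               as.numeric(ref), tolerance = 1e-6)
})

test_that("dihedral agrees with an independent oracle on random geometry", {
  set.seed(81)
  for (i in 1:20) {
    p <- matrix(rnorm(12, sd = 3), 4)
    mine <- dihedralAngle(p[1, ], p[2, ], p[3, ], p[4, ])
    ref <- as.numeric(bio3d::torsion.xyz(as.vector(t(p))))
    expect_equal(mine, ref, tolerance = 1e-6)
  }
})

test_that("dihedral is rigid-motion invariant and mirror-antisymmetric", {
  set.seed(82)
  p <- matrix(rnorm(12, sd = 3), 4)
  d0 <- dihedralAngle(p[1, ], p[2, ], p[3, ], p[4, ])
  rr <- randomRigid(83)
  q <- applyRigid(p, rr$R, rr$tr)
  expect_equal(dihedralAngle(q[1, ], q[2, ], q[3, ], q[4, ]), d0,
               tolerance = 1e-9)
  m <- p; m[, 1] <- -m[, 1]   # reflection
  expect_equal(dihedralAngle(m[1, ], m[2, ], m[3, ], m[4, ]), -d0,
               tolerance = 1e-9)
  expect_error(dihedralAngle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0),
                             c(1, 1, 0)), "coincident")
  expect_error(dihedralAngle(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0),
                             c(2, 0, 0)), "collinear")
})

test_that("omega is computed over Cys76:CA-P7:CA-P1:CA-P1:N", {
  m <- makeComplexFixture()
  map <- resolvePeptidePositions(m, "C", "A")
  om <- omegaDihedral(m, map, heavyChain = "A")
  a <- atoms(m)
  pick <- function(ch, rn, el) as.numeric(
    a[a$chain == ch & a$resno == rn & a$elety == el, c("x", "y", "z")])
  direct <- dihedralAngle(pick("A", 76, "CA"), pick("C", 7, "CA"),
                          pick("C", 1, "CA"), pick("C", 1, "N"))
  expect_equal(om, direct, tolerance = 1e-12)
})

test_that("unwrapping applies the closest-multiple-of-360 rule", {
  s <- AngleSeries(c(0, 1), c(170, -170))
  expect_equal(angleValues(unwrapAngles(s)), c(170, 190))
  s2 <- AngleSeries(0:3, c(-70, -150, 130, 60))
  u2 <- unwrapAngles(s2)
  expect_equal(angleValues(u2), c(-70, -150, -230, -300))
  # output is congruent to input mod 360 at every sample
  expect_equal((angleValues(u2) - angleValues(s2)) %% 360, rep(0, 4))
  # already-smooth series are unchanged
  s3 <- AngleSeries(0:4, c(-10, 20, 50, 90, 120))
  expect_equal(angleValues(unwrapAngles(s3)), angleValues(s3))
  expect_false(isWrapped(unwrapAngles(s3)))
  expect_error(unwrapAngles(unwrapAngles(s3)), "already unwrapped")
})

test_that("an exact 180-degree jump is tie-broken toward no adjustment", {
  s <- AngleSeries(c(0, 1), c(0, 180))
  expect_message(u <- unwrapAngles(s), "exactly 180")
  expect_equal(angleValues(u), c(0, 180))
})

test_that("unwrap/wrap round trips on random seeded series", {
  for (seed in 1:25) {
    set.seed(seed)
    # random walk with |delta| < 180, then wrapped
    steps <- runif(200, -170, 170)
    path <- cumsum(c(runif(1, -180, 180), steps))
    w <- wrapAngles(AngleSeries(seq_along(path), path, wrapped = FALSE))
    u <- unwrapAngles(w)
    # unwrap recovers the path up to a global 360 multiple
    expect_equal(diff(angleValues(u)), diff(path), tolerance = 1e-9)
    expect_equal((angleValues(u) - angleValues(w)) %% 360,
                 rep(0, length(path)), tolerance = 1e-9)
    # unwrap of an already-smooth wrapped-range series is the identity
    sm <- wrapAngles(AngleSeries(1:50, cumsum(runif(50, -3, 3)),
                                 wrapped = FALSE))
    expect_equal(angleValues(unwrapAngles(wrapAngles(
      AngleSeries(1:50, angleValues(unwrapAngles(sm)), FALSE)))),
      angleValues(unwrapAngles(sm)), tolerance = 1e-9)
  }
})

test_that("smoothing averages a centered time window with truncated edges", {
  tt <- seq(0, 100000, by = 1000)  # ps
  const <- AngleSeries(tt, rep(42, length(tt)), wrapped = FALSE)
  expect_equal(angleValues(smoothAngles(const, 10)), rep(42, length(tt)))

  ramp <- AngleSeries(tt, 0.01 * tt, wrapped = FALSE)
  sm <- angleValues(smoothAngles(ramp, 10))
  interior <- tt >= 5000 & tt <= 95000
  expect_equal(sm[interior], (0.01 * tt)[interior], tolerance = 1e-9)

  step <- AngleSeries(tt, ifelse(tt < 50000, -80, 80), wrapped = FALSE)
  sms <- angleValues(smoothAngles(step, 20))
  expect_true(all(diff(sms) >= -1e-9))           # monotone through the step
  # closed-form window average at the step midpoint: (11*80 - 10*80)/21
  expect_equal(sms[which(tt == 50000)], 80 / 21, tolerance = 1e-9)

  expect_error(smoothAngles(wrapAngles(const), 10), "unwrap first")
  expect_error(smoothAngles(const, 1000), "exceeds series duration")
})

test_that("rotation events are detected with dwell and modulo equivalence", {
  mk <- function(schedule, seed = 1, noise = 15) {
    tr <- makeRotationTrace(schedule, noiseSd = noise, totalNs = 300,
                            seed = seed)
    smoothAngles(unwrapAngles(tr$series), 10)
  }
  # programmed -100 -> +100
  one <- mk(data.frame(timeNs = c(0, 150), valueDeg = c(-100, 100)))
  expect_equal(length(detectRotation(one)), 1)
  # -70 -> -260: end band reached via -260 = 100 mod 360
  mod <- mk(data.frame(timeNs = c(0, 150), valueDeg = c(-70, -260)))
  ev <- detectRotation(mod)
  expect_equal(length(ev), 1)
  expect_gt(ev, 100000)  # after the transition onset (ps)
  # flat trace
  flat <- mk(data.frame(timeNs = 0, valueDeg = -100))
  expect_equal(length(detectRotation(flat)), 0)
  # two programmed round trips give two forward events
  two <- mk(data.frame(timeNs = c(0, 80, 160, 240),
                       valueDeg = c(-100, 100, -100, 100)))
  expect_equal(length(detectRotation(two)), 2)
})

test_that("event counts match programmed transitions across seeds", {
  hits <- 0L
  for (seed in 1:30) {
    tr <- makeRotationTrace(data.frame(timeNs = c(0, 150),
                                       valueDeg = c(-100, 100)),
                            noiseSd = 20, totalNs = 300, seed = seed)
    sm <- smoothAngles(unwrapAngles(tr$series), 10)
    hits <- hits + (length(detectRotation(sm)) == tr$truth$nTransitions)
  }
  expect_equal(hits, 30L)
})
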