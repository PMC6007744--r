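test_that("base frames are planar-consistent and rotation-equivariant", {
  g4 <- buildIdealG4(1, 30, 3.4, ions = FALSE)
  res <- g4hydro:::residueAtoms(g4, "A", 1)
  fr <- baseFrame(res)
  # builder bases lie exactly in the z = 0 plane
  expect_lt(acos(abs(sum(fr$z * c(0, 0, 1)))), 1e-6)
  expect_lt(fr$rmsd, 1e-6)
  # axes orthonormal and right-handed
  R <- fr$rotation
  expect_equal(crossprod(R), diag(3), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(det(R), 1, tolerance = 1e-9)
  # equivariance: rotating the residue rotates the frame axes identically
  rot <- randomRotation(31)
  res2 <- rotateResidue(res, axis = c(0, 0, 1), origin = c(0, 0, 0), 0)
  xyz <- as.matrix(res2[, c("x", "y", "z")]) %*% t(rot)
  res2$x <- xyz[, 1]; res2$y <- xyz[, 2]; res2$z <- xyz[, 3]
  fr2 <- baseFrame(res2)
  expect_equal(fr2$z, as.numeric(rot %*% fr$z), tolerance = 1e-9)
  expect_equal(fr2$x, as.numeric(rot %*% fr$x), tolerance = 1e-9)
  expect_equal(fr2$origin, as.numeric(rot %*% fr$origin), tolerance = 1e-9)
  # missing ring atom is an error
  expect_error(baseFrame(res[res$elety != "N9", ]), "N9")
})

test_that("tetrad detection finds constructed tetrads and nothing else", {
  for (n in c(1, 3)) {
    g4 <- buildIdealG4(n, 30, 3.4, ions = FALSE)
    expect_length(detectTetrads(g4), n)
  }
  # negative control: uniformly dilated structure breaks the H-bond grid
  g1 <- buildIdealG4(1, 30, 3.4, ions = FALSE)
  a <- atoms(g1)
  a$x <- 2 * a$x; a$y <- 2 * a$y; a$z <- 2 * a$z
  far <- methods::new("AtomicStructure", atoms = a)
  expect_length(detectTetrads(far), 0L)
})

test_that("tetrad detection is invariant to rigid motion and file order", {
  g4 <- buildIdealG4(3, 30, 3.4, ions = TRUE)
  ref <- detectTetrads(g4)
  moved <- rigidMotion(g4, randomRotation(17), c(25, -40, 7))
  tm <- detectTetrads(moved)
  expect_length(tm, length(ref))
  expect_equal(lapply(tm, function(t) t@residues),
               lapply(ref, function(t) t@residues))
  expect_equal(lapply(tm, function(t) t@pairParams),
               lapply(ref, function(t) t@pairParams), tolerance = 1e-6)
  # shuffled atom order
  set.seed(8)
  ash <- atoms(g4)[sample(nrow(atoms(g4))), ]
  shuffled <- methods::new("AtomicStructure", atoms = ash)
  ts <- detectTetrads(shuffled)
  expect_equal(lapply(ts, function(t) t@residues),
               lapply(ref, function(t) t@residues))
})

test_that("simple pair parameters follow constructed rotations and displacements", {
  g4 <- buildIdealG4(1, 30, 3.4, ions = FALSE)
  rA <- g4hydro:::residueAtoms(g4, "A", 1)
  rB <- g4hydro:::residueAtoms(g4, "B", 1)
  # coplanar parallel bases: identity case
  pp <- simplePairParams(rA, rB)
  expect_equal(unlist(pp), c(buckle = 0, propeller = 0, stagger = 0),
               tolerance = 1e-9)
  # rotating B by +10 degrees about the C1'-C1' axis is pure propeller
  c1a <- g4hydro:::.atomXYZ(rA, "C1'")
  c1b <- g4hydro:::.atomXYZ(rB, "C1'")
  rBr <- rotateResidue(rB, axis = c1b - c1a, origin = c1a, angleDeg = 10)
  pr <- simplePairParams(rA, rBr)
  expect_equal(abs(pr$propeller), 10, tolerance = 1e-6)
  expect_equal(pr$buckle, 0, tolerance = 1e-6)
  # displacing B along the mean normal is pure stagger
  rBt <- rB
  rBt$z <- rBt$z + 0.5
  pt <- simplePairParams(rA, rBt)
  expect_equal(pt$stagger, 0.5, tolerance = 1e-9)
  expect_equal(pt$buckle, 0, tolerance = 1e-9)
  # antisymmetry: swapping arguments negates buckle and propeller,
  # stagger is invariant
  rBb <- rotateResidue(rB, axis = vcrossTest(c1b - c1a, c(0, 0, 1)),
                       origin = (c1a + c1b) / 2, angleDeg = 7)
  p1 <- simplePairParams(rA, rBb)
  p2 <- simplePairParams(rBb, rA)
  expect_equal(p1$buckle, -p2$buckle, tolerance = 1e-9)
  expect_equal(p1$propeller, -p2$propeller, tolerance = 1e-9)
  expect_equal(p1$stagger, p2$stagger, tolerance = 1e-9)
  expect_gt(abs(p1$buckle), 1)
})

test_that("tetrad shape classification covers all sign patterns", {
  mk <- function(buckle, propeller = rep(0, 4))
    cbind(buckle = buckle, propeller = propeller, stagger = 0)
  # planar takes precedence
  expect_equal(classifyTetradShape(mk(c(2, -3, 1, -2), rep(4.9, 4))), "planar")
  expect_equal(classifyTetradShape(mk(c(8, 7, 9, 8))), "convex")
  expect_equal(classifyTetradShape(mk(c(-8, -7, -9, -8))), "concave")
  expect_equal(classifyTetradShape(mk(c(10, -10, 10, -10))), "saddle")
  expect_equal(classifyTetradShape(mk(c(-10, 10, -10, 10))), "saddle")
  # exhaustive over all above-threshold sign patterns: total + deterministic
  for (i in 0:15) {
    signs <- ifelse(bitwAnd(i, 2^(0:3)) > 0, 1, -1)
    lab <- classifyTetradShape(mk(6 * signs))
    want <- if (all(signs > 0)) "convex"
            else if (all(signs < 0)) "concave"
            else if (all(signs == c(1, -1, 1, -1)) ||
                     all(signs == c(-1, 1, -1, 1))) "saddle"
            else "other"
    expect_equal(lab, want)
  }
  # large propeller escapes planar; alternating (even small) buckles
  # then classify as saddle per the rule ordering
  expect_equal(classifyTetradShape(mk(c(1, -1, 1, -1), rep(12, 4))), "saddle")
  # zero buckle with large propeller has no sign consensus at all
  expect_equal(classifyTetradShape(mk(rep(0, 4), rep(12, 4))), "other")
  expect_error(classifyTetradShape(mk(c(NA, 1, 1, 1))), "missing")
})

test_that("channel ion spacing reads off the builder rise and handles edge cases", {
  g4 <- buildIdealG4(4, 30, 3.3, ions = TRUE) # 3 ions -> 2 spacings
  sp <- channelIonSpacing(g4)
  expect_length(sp, 2L)
  expect_equal(sp, rep(3.3, 2), tolerance = 1e-9)
  noIons <- buildIdealG4(3, 30, 3.4, ions = FALSE)
  expect_length(channelIonSpacing(noIons), 0L)
})
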