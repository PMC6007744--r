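test_that("AER follows the sphere-volume relation", {
  expect_equal(aerFromVolume(4 * pi / 3), 1)
  expect_equal(round(aerFromVolume(5.661), 3), 1.106)
  expect_equal(round(aerFromVolume(11.056), 3), 1.382)
  expect_error(aerFromVolume(-1), "positive")
  expect_error(aerFromVolume(0), "positive")
})

test_that("atom-to-bead conversion counts heavy atoms and carries masses", {
  g4 <- buildIdealG4(2, 30, 3.4, ions = TRUE)
  beads <- atomsToBeads(g4, aer = 2.54)
  a <- atoms(g4)
  expect_equal(nBeads(beads), sum(a$elesy != "H"))
  expect_true(all(beadRadii(beads) == 2.54))
  # potassium beads weigh 39.0983
  expect_equal(sort(unique(beadWeights(beads))),
               c(12.011, 14.007, 15.999, 39.0983))
  expect_error(atomsToBeads(g4, aer = 0), "positive")
})

test_that("radius of gyration includes the bead self-term", {
  # single bead: self-term only
  one <- BeadModel(matrix(0, 1, 3), radii = 5)
  expect_equal(radiusOfGyration(one) * 10, sqrt(3 / 5) * 5)
  # uniform sphere: closed form within discretization error
  m <- makeSphereBeadModel(20, 2)
  expect_equal(radiusOfGyration(m) * 10, sqrt(3 / 5) * 20, tolerance = 0.05)
})

test_that("pair-distance distribution has the right support and mode", {
  two <- BeadModel(rbind(c(0, 0, 0), c(10, 0, 0)), radii = 1.5)
  pr <- pairDistanceDistribution(two)
  expect_equal(pr$dmax * 10, 13) # d + 2 sigma
  expect_equal(sum(pr$p) * diff(pr$r[1:2]), 1, tolerance = 1e-9)
  # solid sphere: P(r) mode near R (analytic mode ~1.05 R)
  m <- makeSphereBeadModel(20, 1.5)
  prs <- pairDistanceDistribution(m)
  mode <- prs$r[which.max(prs$p)] * 10
  expect_gt(mode, 0.9 * 20)
  expect_lt(mode, 1.2 * 20)
  expect_error(pairDistanceDistribution(BeadModel(matrix(0, 1, 3), radii = 1)),
               "2 beads")
})

test_that("hydrodynamic radius reproduces Stokes and touching-sphere limits", {
  one <- BeadModel(matrix(0, 1, 3), radii = 7)
  expect_equal(hydrodynamicRadius(one, "kirkwood") * 10, 7)
  expect_equal(hydrodynamicRadius(one, "rpy") * 10, 7)
  # two touching beads, Kirkwood: (1/4)(2/a + 2/2a) = 3/(4a) -> Rh = 4a/3
  for (a in c(1, 2.5)) {
    two <- BeadModel(rbind(c(0, 0, 0), c(2 * a, 0, 0)), radii = a)
    expect_equal(hydrodynamicRadius(two, "kirkwood") * 10, 4 * a / 3,
                 tolerance = 1e-12)
  }
  expect_error(hydrodynamicRadius(BeadModel(matrix(0, 1, 3))), "radii")
})

test_that("descriptors are rigid-motion invariant and scale linearly", {
  set.seed(21)
  centers <- matrix(rnorm(60, sd = 8), 20)
  m <- BeadModel(centers, radii = 1.5, weights = runif(20, 0.5, 2))
  rot <- randomRotation(4)
  moved <- BeadModel(sweep(centers %*% t(rot), 2, c(-30, 12, 5), `+`),
                     radii = 1.5, weights = beadWeights(m))
  expect_equal(radiusOfGyration(moved), radiusOfGyration(m), tolerance = 1e-9)
  expect_equal(hydrodynamicRadius(moved, "kirkwood"),
               hydrodynamicRadius(m, "kirkwood"), tolerance = 1e-9)
  expect_equal(hydrodynamicRadius(moved, "rpy"),
               hydrodynamicRadius(m, "rpy"), tolerance = 1e-6)
  expect_equal(pairDistanceDistribution(moved)$dmax,
               pairDistanceDistribution(m)$dmax, tolerance = 1e-9)
  # uniform scaling by 2 doubles Rg, Dmax and Rh
  scaled <- BeadModel(2 * centers, radii = 3, weights = beadWeights(m))
  expect_equal(radiusOfGyration(scaled), 2 * radiusOfGyration(m),
               tolerance = 1e-9)
  expect_equal(pairDistanceDistribution(scaled)$dmax,
               2 * pairDistanceDistribution(m)$dmax, tolerance = 1e-9)
  expect_equal(hydrodynamicRadius(scaled, "kirkwood"),
               2 * hydrodynamicRadius(m, "kirkwood"), tolerance = 1e-9)
  expect_equal(hydrodynamicRadius(scaled, "rpy"),
               2 * hydrodynamicRadius(m, "rpy"), tolerance = 1e-6)
})

test_that("shell-sphere estimates converge to the Stokes radius", {
  # friction is generated at the surface: shell models converge for both
  # estimators, and the relative error decreases monotonically
  errK <- errR <- c()
  for (a in c(3, 2, 1.25)) {
    m <- makeSphereBeadModel(20, a, shell = TRUE)
    errK <- c(errK, abs(hydrodynamicRadius(m, "kirkwood") * 10 - 20) / 20)
    errR <- c(errR, abs(hydrodynamicRadius(m, "rpy") * 10 - 20) / 20)
  }
  expect_true(all(diff(errK) < 0))
  expect_lt(errK[3], 0.03)
  expect_lt(errR[3], 0.03)
})

test_that("oligonucleotide masses match atomic composition", {
  # deoxyguanosine C10H13N5O4
  expect_equal(massFromSequence("G"), 267.24, tolerance = 0.01)
  mono <- massFromSequence("GGGTTGCGGAGGGTGGGCCT", nCations = 2)
  expect_equal(mono, 6364.3, tolerance = 0.5)
  # additivity: dimer with 5 K+ = 2 x (monomer with 2 K+) + 1 K+
  dimer <- 2 * massFromSequence("GGGTTGCGGAGGGTGGGCCT") + 5 * 39.0983
  expect_equal(dimer, 2 * mono + 39.0983, tolerance = 1e-9)
  expect_equal(dimer, 12767.7, tolerance = 0.5)
  # RNA variant and error handling
  expect_gt(massFromSequence("GGGUU"), massFromSequence("GGGTT") - 50)
  expect_error(massFromSequence("GGXT"), "invalid base")
  expect_error(massFromSequence("GGUT"), "invalid base") # U in DNA context
})

test_that("Svedberg relation and frictional ratio reproduce hand-derived values", {
  # dimer-scale inputs: M 12.7677 kDa, vbar 0.541, Rh 1.94 nm, water 20 C
  s <- sedimentationCoefficient(12767.7, 0.541, 1.94)
  expect_equal(s, 2.67, tolerance = 0.05)
  # inverse proportionality in Rh
  expect_equal(sedimentationCoefficient(12767.7, 0.541, 2 * 1.94), s / 2,
               tolerance = 1e-9)
  expect_error(sedimentationCoefficient(1000, 1 / 0.998206, 1.5),
               "buoyancy")
  # frictional ratio: R0 = (3 M vbar / 4 pi NA)^(1/3) ~ 1.40 nm
  fr <- frictionalRatio(1.94, 12767.7, 0.541)
  expect_equal(fr, 1.39, tolerance = 0.01)
  expect_equal(suppressWarnings(frictionalRatio(1.399, 12767.7, 0.541)), 1,
               tolerance = 0.01)
  expect_warning(fr2 <- frictionalRatio(0.5, 12767.7, 0.541), "unphysical")
  expect_lt(fr2, 1)
})

test_that("standardization to water at 20 C behaves like Eq.-1 style correction", {
  # identity at standard conditions, for any s
  expect_equal(standardizeS(2.7, waterAt20C(), 0.541), 2.7)
  expect_equal(standardizeS(-1.3, waterAt20C(), 0.541), -1.3)
  # linearity in s
  hepes <- SolventConditions(1.0045, 0.0101543, 20)
  f1 <- standardizeS(1, hepes, 0.541)
  expect_equal(standardizeS(2.645, hepes, 0.541), 2.645 * f1, tolerance = 1e-12)
  expect_gt(f1, 1) # denser, more viscous buffer slows sedimentation
})

test_that("bead volume uses the dummy-atom volume when present", {
  m <- BeadModel(matrix(rnorm(300), 100), radii = 1.382,
                 dummyAtomVolume = 11.056)
  v <- beadVolume(m)
  expect_equal(as.numeric(v), 1.1056, tolerance = 1e-9)
  expect_equal(attr(v, "method"), "dummy_atom_volume")
  one <- BeadModel(matrix(0, 1, 3), radii = 10) # 1 nm bead
  expect_equal(as.numeric(beadVolume(one)), 4 / 3 * pi, tolerance = 1e-9)
})
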