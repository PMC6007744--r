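test_that("dihedral matches hand-evaluated reference cases", {
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0)), 180)
  # hand evaluation of the atan2 formula for a +z-displaced fourth point
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 1)), -90)
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("dihedral is rigid-motion invariant, reversal-symmetric and mirror-odd", {
  set.seed(5)
  for (i in 1:25) {
    p <- lapply(1:4, function(k) rnorm(3))
    # reject near-degenerate draws
    if (inherits(try(d0 <- dihedral(p[[1]], p[[2]], p[[3]], p[[4]]),
                     silent = TRUE), "try-error")) next
    rot <- randomRotation(i)
    shift <- rnorm(3, sd = 10)
    pr <- lapply(p, function(v) as.numeric(rot %*% v + shift))
    expect_equal(dihedral(pr[[1]], pr[[2]], pr[[3]], pr[[4]]), d0,
                 tolerance = 1e-9)
    expect_equal(dihedral(p[[4]], p[[3]], p[[2]], p[[1]]), d0,
                 tolerance = 1e-9)
    pm <- lapply(p, function(v) c(v[1], v[2], -v[3])) # mirror z -> -z
    dm <- dihedral(pm[[1]], pm[[2]], pm[[3]], pm[[4]])
    if (abs(abs(d0) - 180) > 1e-6)
      expect_equal(dm, -d0, tolerance = 1e-9)
  }
})

test_that("torsion profile recovers NeRF-built backbone torsions", {
  s <- buildChainFromInternalCoords(backboneSpec(4, -60), resid = "DG")
  tp <- torsionProfile(s, "A")
  vals <- as.matrix(tp[, c("alpha", "beta", "gamma", "delta",
                           "epsilon", "zeta")])
  expect_lt(max(abs(vals[!is.na(vals)] + 60)), 1e-6)
  # terminal residues: no upstream phosphate / downstream phosphate
  expect_true(is.na(tp$alpha[1]))
  expect_true(is.na(tp$epsilon[nrow(tp)]) && is.na(tp$zeta[nrow(tp)]))
  # mixed random torsions round-trip through the profile
  set.seed(9)
  tor <- runif(6 * 5 - 3, -170, 170)
  sp <- backboneSpec(5, NA)
  sp$torsion <- c(NA, NA, NA, tor)
  s2 <- buildChainFromInternalCoords(sp, resid = "DG")
  tp2 <- torsionProfile(s2, "A")
  vals2 <- as.matrix(tp2[, c("alpha", "beta", "gamma", "delta",
                             "epsilon", "zeta")])
  # the k-th backbone torsion of residue i is the NeRF torsion of chain
  # atom 6*(i-1) + k + 2 (the last atom of its defining quartet)
  full <- c(NA, NA, NA, tor)
  nDefined <- 0L
  for (i in seq_len(5)) {
    for (k in 1:6) {
      got <- unname(vals2[i, k])
      at <- 6L * (i - 1L) + k + 2L
      want <- if (at >= 4L && at <= length(full)) full[at] else NA
      if (!is.na(got)) {
        expect_false(is.na(want))
        expect_equal(got, want, tolerance = 1e-6)
        nDefined <- nDefined + 1L
      }
    }
  }
  expect_gte(nDefined, 25L)
})

test_that("glycosidic classification uses the (-90, 90] syn window", {
  expect_equal(classifyGlycosidic(c(-120, 60, 90, -90, 179)),
               c("anti", "syn", "syn", "anti", "anti"))
  expect_true(is.na(classifyGlycosidic(NA_real_)))
  # every guanine of the ideal builder (chi = -120) is anti
  g4 <- buildIdealG4(2, 30, 3.4, ions = FALSE)
  for (ch in c("A", "B", "C", "D")) {
    tp <- torsionProfile(g4, ch)
    expect_true(all(tp$glycosidic == "anti"))
    expect_equal(tp$chi, rep(-120, nrow(tp)), tolerance = 1e-6)
  }
})

test_that("special gamma/zeta ranges are flagged and restrictable", {
  tab <- data.frame(chain = "A", resno = 1:4, resid = "DG", base = "G",
                    alpha = NA, beta = NA,
                    gamma = c(-60.6, 55, -77.6, -44.9),
                    delta = NA, epsilon = NA,
                    zeta = c(100, 60, 180, 74.9), chi = NA,
                    glycosidic = NA, gamma_bulge_range = FALSE,
                    zeta_loop_range = FALSE, stringsAsFactors = FALSE)
  out <- flagSpecialRanges(tab)
  # gamma -60.6 inside [-75, -45]; 55 canonical; -77.6 outside; -44.9 outside
  expect_equal(out$gamma_bulge_range, c(TRUE, FALSE, FALSE, FALSE))
  # zeta 100 and 180 inside [75, 180]; 60 and 74.9 outside
  expect_equal(out$zeta_loop_range, c(TRUE, FALSE, TRUE, FALSE))
  # restriction to core residues
  out2 <- flagSpecialRanges(tab, coreResidues = "A:2")
  expect_false(any(out2$gamma_bulge_range))
})

test_that("torsion tables export to CSV", {
  g4 <- buildIdealG4(2, 30, 3.4, ions = FALSE)
  tp <- torsionProfile(g4, "A")
  f <- withr::local_tempfile(fileext = ".csv")
  writeTorsionCSV(tp, f)
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(tp))
  expect_true(all(c("alpha", "zeta", "chi", "glycosidic") %in% names(back)))
})
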