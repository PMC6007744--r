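## Synthetic generators: chains from internal coordinates (NeRF), ideal
## parallel G-quadruplexes, analytic sphere bead models, and simulated
## sedimentation-velocity species series. These provide known-answer inputs
## for every downstream analysis stage.

## natural-extension (NeRF) placement of D given A-B-C, bond length r (A),
## bond angle theta at C (deg), torsion phi about B-C (deg)
nerfPlace <- function(A, B, C, r, theta, phi) {
  th <- deg2rad(theta)
  ph <- deg2rad(phi)
  bc <- unitv(C - B)
  ab <- B - A
  nv <- vcross(ab, bc)
  if (vnorm(nv) < 1e-9) stop("degenerate (collinear) reference frame")
  nv <- unitv(nv)
  mv <- vcross(nv, bc)
  d <- r * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  C + d[1L] * bc + d[2L] * mv + d[3L] * nv
}

#' Build a chain from internal coordinates
#'
#' Converts an internal-coordinate specification (bond length, bond angle,
#' torsion per atom, each relative to the three preceding atoms) into
#' Cartesian coordinates by natural-extension (NeRF) construction. Every
#' specified torsion is reproduced exactly, which makes the generated chain
#' an oracle for torsion-angle computation.
#'
#' @param spec data.frame with columns \code{name} (atom name),
#'   \code{bondLength} (Angstroms, > 0), \code{bondAngle} (degrees, in
#'   (0, 180)), \code{torsion} (degrees, in (-180, 180]) and optionally
#'   \code{resno} (residue number, default 1). The first three rows supply
#'   atom names only; their positions come from \code{seedFrame}.
#' @param seedFrame 3 x 3 matrix of the first three atom positions
#'   (rows); must not be collinear. A default non-degenerate frame is used
#'   when omitted.
#' @param chainId Chain identifier of the generated chain.
#' @param resid Residue name given to generated residues.
#' @return An \linkS4class{AtomicStructure}.
#' @examples
#' sp <- data.frame(name = c("A1", "A2", "A3", "A4"),
#'                  bondLength = c(NA, NA, NA, 1.5),
#'                  bondAngle = c(NA, NA, NA, 109.5),
#'                  torsion = c(NA, NA, NA, 180))
#' s <- buildChainFromInternalCoords(sp)
#' @export
buildChainFromInternalCoords <- function(spec, seedFrame = NULL,
                                         chainId = "A", resid = "GLY") {
  stopifnot(is.data.frame(spec), nrow(spec) >= 4L)
  if (is.null(spec$resno)) spec$resno <- 1L
  if (is.null(seedFrame))
    seedFrame <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.25, 1.3, 0))
  seedFrame <- as.matrix(seedFrame)
  stopifnot(all(dim(seedFrame) == c(3L, 3L)))
  if (vnorm(vcross(seedFrame[2L, ] - seedFrame[1L, ],
                   seedFrame[3L, ] - seedFrame[2L, ])) < 1e-9)
    stop("degenerate (collinear) seed frame")
  n <- nrow(spec)
  xyz <- matrix(NA_real_, n, 3L)
  xyz[1:3, ] <- seedFrame
  for (i in 4:n) {
    r <- spec$bondLength[i]
    th <- spec$bondAngle[i]
    ph <- spec$torsion[i]
    if (!is.finite(r) || r <= 0) stop("bond length must be positive (row ", i, ")")
    if (!is.finite(th) || th <= 0 || th >= 180)
      stop("bond angle must lie strictly between 0 and 180 degrees (row ", i, ")")
    if (!is.finite(ph) || ph <= -180 || ph > 180)
      stop("torsion must lie in (-180, 180] (row ", i, ")")
    xyz[i, ] <- nerfPlace(xyz[i - 3L, ], xyz[i - 2L, ], xyz[i - 1L, ],
                          r, th, ph)
  }
  atoms <- data.frame(model = 1L, chain = chainId,
                      resno = as.integer(spec$resno), resid = resid,
                      elety = as.character(spec$name),
                      elesy = toupper(substr(sub("[0-9'*].*$", "",
                                                 spec$name), 1L, 1L)),
                      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                      o = 1, b = 0, type = "ATOM",
                      stringsAsFactors = FALSE)
  new("AtomicStructure", atoms = atoms, title = "NeRF-built chain")
}

## Solve the rigid in-plane placement (tx, ty, theta) of the guanine
## template such that, with the Hoogsteen neighbour generated by a +90
## degree rotation about z, N1(g)-O6(h) = N2(g)-N7(h) = 2.90 A and the C1'
## atom sits at c1Radius from the channel axis. Deterministic: fixed
## starting point near the physical solution.
.solveTetradPlacement <- function(c1Radius) {
  tmpl <- .BASE_TEMPLATES$G[, 1:2]
  rot2 <- function(th) matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  place <- function(p) sweep(tmpl %*% t(rot2(p[3L])), 2L, -p[1:2])
  obj <- function(p) {
    g <- place(p)
    h <- g %*% t(rot2(pi / 2))
    sum(c(sqrt(sum((g["N1", ] - h["O6", ])^2)) - 2.90,
          sqrt(sum((g["N2", ] - h["N7", ])^2)) - 2.90,
          sqrt(sum(g["C1'", ]^2)) - c1Radius)^2)
  }
  fit <- stats::nlminb(c(-2.463, -1.120, 0.918), obj,
                       control = list(abs.tol = 1e-16, rel.tol = 1e-14,
                                      iter.max = 500))
  if (fit$objective > 0.05)
    stop("no physical tetrad placement for c1Radius = ", c1Radius)
  place(fit$par)
}

#' Build an ideal parallel G-quadruplex
#'
#' Generates an idealized parallel-stranded quadruplex: four strands (chains
#' A-D) of \code{nTetrads} guanines each. Every tetrad is exactly 4-fold
#' symmetric about the z axis (the channel); tetrad k is rotated by
#' \code{k * twist} degrees and translated \code{k * rise} Angstroms along
#' z. Base planes are exactly perpendicular to the axis, so buckle,
#' propeller and stagger of the pristine output are zero and its shape
#' classifies as "planar" by construction. Guanine base atoms come from a
#' planar standard-frame template placed so that the Hoogsteen contacts
#' (N1->O6, N2->N7) of adjacent strands are 2.90 A; a sugar O4' atom is
#' added in the anti glycosidic orientation so that chi is computable.
#' Channel cations (potassium) are optionally placed on the axis midway
#' between consecutive tetrads.
#'
#' Positive \code{twist} corresponds to counter-clockwise stacking when
#' viewed from the 5' side looking along the 5'-to-3' channel direction
#' (+z); this is also the sign convention of \code{\link{stackingTwist}}.
#'
#' @param nTetrads Number of stacked tetrads (>= 1).
#' @param twist Stacking twist per tetrad step, degrees (default 30).
#' @param rise Stacking rise per tetrad step, Angstroms (default 3.4, > 0).
#' @param c1Radius Distance of the C1' atoms from the channel axis,
#'   Angstroms.
#' @param ions Place K+ ions on the axis midway between tetrads?
#' @param chi Glycosidic torsion (O4'-C1'-N9-C4) given to every guanine,
#'   degrees; the default -120 is a canonical anti value.
#' @return An \linkS4class{AtomicStructure} with chains A-D (and ions in
#'   chain E when requested).
#' @examples
#' g4 <- buildIdealG4(nTetrads = 3, twist = 30, rise = 3.4)
#' @export
buildIdealG4 <- function(nTetrads = 3, twist = 30, rise = 3.4,
                         c1Radius = 8.26, ions = TRUE, chi = -120) {
  stopifnot(nTetrads >= 1, rise > 0, c1Radius > 0)
  g2d <- .solveTetradPlacement(c1Radius)
  base <- cbind(g2d, 0)              # planar base + C1', z = 0
  rownames(base) <- rownames(.BASE_TEMPLATES$G)
  ## add O4' in the requested glycosidic orientation:
  ## chi = dihedral(O4', C1', N9, C4) == dihedral(C4, N9, C1', O4')
  o4 <- nerfPlace(base["C4", ], base["N9", ], base["C1'", ],
                  r = 1.42, theta = 108, phi = chi)
  base <- rbind(base, `O4'` = o4)
  rows <- list()
  for (s in 0:3) {                    # strand = chain
    for (k in seq_len(nTetrads) - 1L) {
      rot <- rotZ(90 * s + twist * k)
      xyz <- base %*% t(rot)
      xyz[, 3L] <- xyz[, 3L] + k * rise
      rows[[length(rows) + 1L]] <- data.frame(
        model = 1L, chain = LETTERS[s + 1L], resno = k + 1L, resid = "DG",
        elety = rownames(base),
        elesy = toupper(substr(sub("[0-9'*].*$", "", rownames(base)), 1L, 1L)),
        x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
        o = 1, b = 0, type = "ATOM", stringsAsFactors = FALSE)
    }
  }
  if (ions && nTetrads >= 2L) {
    for (k in seq_len(nTetrads - 1L) - 1L) {
      rows[[length(rows) + 1L]] <- data.frame(
        model = 1L, chain = "E", resno = k + 1L, resid = "K",
        elety = "K", elesy = "K",
        x = 0, y = 0, z = (k + 0.5) * rise,
        o = 1, b = 0, type = "HETATM", stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  new("AtomicStructure", atoms = atoms, title = "ideal parallel G4")
}

#' Sphere bead model on a cubic lattice
#'
#' Deterministic bead model of a sphere of radius \code{sphereRadius}:
#' beads of radius \code{beadRadius} on a cubic lattice with spacing
#' \code{2 * beadRadius}, keeping centers inside the sphere. With
#' \code{shell = TRUE} only the outermost lattice layer is kept and its
#' centers are projected onto the sphere surface, giving the shell-type
#' model appropriate for Kirkwood-style hydrodynamic estimates (the
#' friction of a rigid body is generated at its surface; see the package
#' vignette).
#'
#' @param sphereRadius Sphere radius, Angstroms.
#' @param beadRadius Bead radius, Angstroms; must be smaller than
#'   \code{sphereRadius}.
#' @param shell Keep only the surface layer, projected to the surface?
#' @return A \linkS4class{BeadModel} with unit weights.
#' @examples
#' filled <- makeSphereBeadModel(20, 2)
#' surface <- makeSphereBeadModel(20, 2, shell = TRUE)
#' @export
makeSphereBeadModel <- function(sphereRadius, beadRadius, shell = FALSE) {
  stopifnot(sphereRadius > 0, beadRadius > 0)
  if (beadRadius >= sphereRadius)
    stop("beadRadius must be smaller than sphereRadius")
  s <- seq(-sphereRadius, sphereRadius, by = 2 * beadRadius)
  g <- as.matrix(expand.grid(x = s, y = s, z = s))
  d <- sqrt(rowSums(g^2))
  if (shell) {
    keep <- d <= sphereRadius & d > sphereRadius - 2 * beadRadius
    g <- g[keep, , drop = FALSE]
    g <- g * (sphereRadius / sqrt(rowSums(g^2)))
  } else {
    g <- g[d <= sphereRadius, , drop = FALSE]
  }
  if (nrow(g) == 0L) stop("no beads produced; decrease beadRadius")
  dimnames(g) <- NULL
  BeadModel(g, radii = beadRadius, weights = 1)
}

#' Simulate a sedimentation-velocity species series
#'
#' Emulates per-concentration species-analysis output for one sedimenting
#' species with linear concentration dependence:
#' \eqn{s_{app}(c) = s_0 (1 - k_s c) + \epsilon},
#' \eqn{\epsilon \sim N(0, \sigma^2)} homoscedastic, with constant species
#' fraction. Apparent masses receive the same relative noise. Reproducible
#' for a given seed; the generator never touches the global RNG state.
#'
#' @param s0 Infinite-dilution sedimentation coefficient, S.
#' @param kS Concentration coefficient, ml/mg.
#' @param m0 Molecular mass, kDa.
#' @param fractionDimer Constant molecular fraction assigned to the series.
#' @param concentrations Loading concentrations, mg/ml (positive, unique).
#' @param noiseSD Gaussian noise standard deviation on s, S.
#' @param seed Integer seed.
#' @param buffer \linkS4class{SolventConditions} attached to the series.
#' @param vbar Partial specific volume, cm^3/g.
#' @param speciesLabel Label ("dimer" by default).
#' @return A \linkS4class{SpeciesSeries}.
#' @examples
#' ser <- simulateSVSeries(2.70, 0.005, 12.77, 0.9,
#'                         c(0.5, 1, 2, 4), noiseSD = 0.02, seed = 1)
#' @export
simulateSVSeries <- function(s0, kS, m0, fractionDimer, concentrations,
                             noiseSD = 0, seed = 1,
                             buffer = waterAt20C(), vbar = 0.541,
                             speciesLabel = "dimer") {
  stopifnot(s0 > 0, all(concentrations > 0), noiseSD >= 0,
            fractionDimer >= 0, fractionDimer <= 1)
  ## draw reproducibly without disturbing the caller's RNG state
  oldSeed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  rng <- stats::rnorm(2L * length(concentrations))
  if (is.null(oldSeed)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", oldSeed, envir = globalenv())
  }
  n <- length(concentrations)
  sTrue <- s0 * (1 - kS * concentrations)
  sApp <- sTrue + noiseSD * rng[seq_len(n)]
  mApp <- m0 * (1 + (noiseSD / s0) * rng[n + seq_len(n)])
  rec <- data.frame(conc_mg_ml = concentrations, s_app_S = sApp,
                    s_sd = rep(noiseSD, n), M_kDa = mApp,
                    M_sd = rep(m0 * noiseSD / s0, n),
                    fraction = rep(fractionDimer, n),
                    fraction_sd = rep(0, n))
  new("SpeciesSeries", records = rec, speciesLabel = speciesLabel,
      buffer = buffer, vbar = vbar, vbarSD = 0, standardized = FALSE)
}
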