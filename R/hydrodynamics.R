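## Scattering and hydrodynamic descriptors of bead models and atomic
## structures: Rg, P(r)/Dmax, Kirkwood and Rotne-Prager-Yamakawa
## hydrodynamic radii, sedimentation coefficient, buffer standardization,
## frictional ratio, molecular mass from atomic composition, bead volume.
## Bead models live in Angstroms; derived descriptors are reported in nm
## (and Svedberg for s), matching common practice in the SAXS/AUC
## literature.

#' Bead radius from dummy-atom volume
#'
#' The atomic element radius (AER) of a dummy-atom bead is the radius of
#' the sphere with the dummy-atom volume:
#' \eqn{AER = (3 V_{DA} / 4\pi)^{1/3}}.
#'
#' @param vDA Dummy-atom volume, Angstrom^3 (> 0).
#' @return Bead radius, Angstroms.
#' @examples
#' aerFromVolume(5.661)  # 1.106
#' aerFromVolume(11.056) # 1.382
#' @export
aerFromVolume <- function(vDA) {
  if (any(!is.finite(vDA) | vDA <= 0))
    stop("dummy-atom volume must be positive")
  (3 * vDA / (4 * pi))^(1 / 3)
}

#' Convert an atomic structure to a bead model
#'
#' One bead per non-hydrogen atom, centered at the atom position, with a
#' uniform atomic element radius and the atomic mass as bead weight. The
#' default AER of 2.54 Angstroms is the value calibrated for quadruplex
#' DNA atomic-level hydrodynamic calculations.
#'
#' @param structure An \linkS4class{AtomicStructure}.
#' @param aer Atomic element radius, Angstroms (> 0).
#' @param model Model number.
#' @return A \linkS4class{BeadModel} with atomic-mass weights.
#' @export
atomsToBeads <- function(structure, aer = 2.54, model = 1L) {
  stopifnot(is(structure, "AtomicStructure"))
  if (!is.finite(aer) || aer <= 0) stop("aer must be positive")
  a <- structure@atoms
  a <- a[a$model == model & a$elesy != "H", , drop = FALSE]
  if (nrow(a) == 0L) stop("structure has no heavy atoms")
  BeadModel(as.matrix(a[, c("x", "y", "z")]), radii = aer,
            weights = atomicMass(a$elesy))
}

#' Radius of gyration of a bead model
#'
#' Weighted radius of gyration including the bead self-term:
#' \eqn{R_g^2 = \sum w_i |r_i - \bar r|^2 / \sum w_i +
#' (3/5) \langle \sigma^2 \rangle_w}.
#'
#' @param model A \linkS4class{BeadModel}.
#' @return Rg in nm.
#' @export
radiusOfGyration <- function(model) {
  stopifnot(is(model, "BeadModel"))
  w <- model@weights
  ctr <- colSums(model@centers * w) / sum(w)
  d2 <- rowSums(sweep(model@centers, 2L, ctr)^2)
  sig2 <- if (all(is.na(model@radii))) 0 else
    sum(w * model@radii^2) / sum(w)
  sqrt(sum(w * d2) / sum(w) + 0.6 * sig2) / 10
}

#' Pair-distance distribution P(r)
#'
#' Weighted histogram of all inter-bead center distances, smeared by the
#' bead diameter (each pair contributes a triangular kernel of half-width
#' \eqn{\sigma_i + \sigma_j}), normalized to unit integral. The maximum
#' dimension is the largest center distance plus one bead diameter.
#'
#' @param model A \linkS4class{BeadModel} with at least 2 beads.
#' @param nBins Number of grid bins; default gives a bin width of
#'   max(bead diameter, dmax/200).
#' @return List with \code{r} (bin centers, nm), \code{p} (density, 1/nm),
#'   and \code{dmax} (nm).
#' @export
pairDistanceDistribution <- function(model, nBins = NULL) {
  stopifnot(is(model, "BeadModel"))
  n <- nrow(model@centers)
  if (n < 2L) stop("P(r) needs at least 2 beads")
  sigma <- model@radii
  if (all(is.na(sigma))) sigma <- rep(0, n)
  d <- as.matrix(stats::dist(model@centers))
  iu <- which(upper.tri(d), arr.ind = TRUE)
  dd <- d[upper.tri(d)]
  ww <- model@weights[iu[, 1L]] * model@weights[iu[, 2L]]
  smear <- sigma[iu[, 1L]] + sigma[iu[, 2L]]
  dmax <- max(dd) + 2 * max(sigma)
  if (is.null(nBins)) {
    width <- max(2 * mean(sigma), dmax / 200)
    nBins <- max(10L, ceiling(dmax / width))
  }
  edges <- seq(0, dmax, length.out = nBins + 1L)
  width <- edges[2L] - edges[1L]
  p <- numeric(nBins)
  ## triangular smearing kernel per pair over [d - s, d + s]
  for (q in seq_along(dd)) {
    s <- max(smear[q], width / 2)
    lo <- max(1L, floor((dd[q] - s) / width) + 1L)
    hi <- min(nBins, floor((dd[q] + s) / width) + 1L)
    ctrs <- (edges[lo:hi] + edges[(lo + 1L):(hi + 1L)]) / 2
    k <- pmax(0, 1 - abs(ctrs - dd[q]) / s)
    if (sum(k) > 0) p[lo:hi] <- p[lo:hi] + ww[q] * k / sum(k)
  }
  p <- p / (sum(p) * width / 10)      # unit integral on the nm scale
  list(r = (edges[-1L] - width / 2) / 10, p = p, dmax = dmax / 10)
}

## Kirkwood double-sum estimate of the hydrodynamic radius (Angstroms in,
## Angstroms out)
.kirkwoodRh <- function(centers, radii) {
  n <- nrow(centers)
  selfTerm <- sum(1 / radii)
  if (n == 1L) return(1 / selfTerm)
  dsum <- 2 * sum(1 / stats::dist(centers))
  n^2 / (selfTerm + dsum)
}

## Rigid-body translational friction from inversion of the 3N x 3N
## Rotne-Prager-Yamakawa mobility supermatrix; returns the equivalent
## Stokes radius (trace of the translational resistance tensor / 3, in
## units where 6*pi*eta = 1). Overlapping beads use the standard RPY
## overlap form (exact for equal radii; the mean radius is used, with a
## warning, for overlapping unequal beads).
.rpyRh <- function(centers, radii) {
  n <- nrow(centers)
  if (n == 1L) return(radii[1L])
  m <- matrix(0, 3L * n, 3L * n)
  warned <- FALSE
  for (i in seq_len(n)) {
    ii <- (3L * i - 2L):(3L * i)
    m[ii, ii] <- diag(3L) / radii[i]
    if (i < n) for (j in (i + 1L):n) {
      rij <- centers[j, ] - centers[i, ]
      r <- sqrt(sum(rij^2))
      rh <- rij / r
      pp <- outer(rh, rh)
      s2 <- radii[i]^2 + radii[j]^2
      if (r >= radii[i] + radii[j]) {
        blk <- (3 / (4 * r)) * ((1 + s2 / (3 * r^2)) * diag(3L) +
                                (1 - s2 / r^2) * pp)
      } else {
        if (abs(radii[i] - radii[j]) > 1e-9 && !warned) {
          warning("overlapping beads with unequal radii; using the ",
                  "mean-radius RPY overlap correction")
          warned <- TRUE
        }
        ab <- (radii[i] + radii[j]) / 2
        blk <- (1 / ab) * ((1 - 9 * r / (32 * ab)) * diag(3L) +
                           (3 * r / (32 * ab)) * pp)
      }
      jj <- (3L * j - 2L):(3L * j)
      m[ii, jj] <- blk
      m[jj, ii] <- blk
    }
  }
  u <- matrix(0, 3L * n, 3L)
  for (k in 1:3) u[seq(k, 3L * n, 3L), k] <- 1
  f <- solve(m, u)
  xi <- crossprod(u, f)
  sum(diag(xi)) / 3
}

#' Hydrodynamic radius of a rigid bead model
#'
#' Translational hydrodynamic (Stokes) radius of the rigid bead assembly.
#' Method \code{"kirkwood"} uses the orientationally averaged double-sum
#' approximation \eqn{1/R_h = (1/N^2)(\sum_i 1/\sigma_i +
#' \sum_{i \ne j} 1/r_{ij})}; it is fast and appropriate for shell-type
#' models (rigid-body friction is generated at the surface, so
#' volume-filled models bias it low; see the vignette). Method
#' \code{"rpy"} computes the rigid-body friction from inversion of the
#' 3N x 3N Rotne-Prager-Yamakawa mobility supermatrix (trace of the
#' translational resistance tensor / 3) and is the accuracy path.
#'
#' @param model A \linkS4class{BeadModel} with positive radii.
#' @param method "kirkwood" (default) or "rpy".
#' @return Hydrodynamic radius, nm.
#' @examples
#' two <- BeadModel(rbind(c(0, 0, 0), c(2, 0, 0)), radii = 1)
#' hydrodynamicRadius(two) # 4/3 / 10 nm (Kirkwood, touching spheres)
#' @export
hydrodynamicRadius <- function(model, method = c("kirkwood", "rpy")) {
  stopifnot(is(model, "BeadModel"))
  method <- match.arg(method)
  if (any(is.na(model@radii)) || any(model@radii <= 0))
    stop("hydrodynamic radius requires positive bead radii")
  rh <- switch(method,
               kirkwood = .kirkwoodRh(model@centers, model@radii),
               rpy = .rpyRh(model@centers, model@radii))
  rh / 10
}

#' Molecular mass of an oligonucleotide from its sequence
#'
#' Average-isotopic mass of a 5'-OH, 3'-OH oligonucleotide (n - 1
#' phosphodiester linkages) plus bound monovalent cations. DNA sequences
#' use A/C/G/T, RNA sequences A/C/G/U; the nucleic-acid type is inferred
#' from the presence of T or U unless given. A 5'-monophosphate can be
#' added for phosphorylated synthetic oligos.
#'
#' @param sequence Base string, e.g. "GGGTTGCGGAGGGTGGGCCT".
#' @param nCations Number of bound cations (default 0).
#' @param cationMass Cation mass, Da (default potassium, 39.0983).
#' @param type "DNA", "RNA" or "auto".
#' @param phosphate5 Add a 5'-terminal monophosphate?
#' @return Mass in Da.
#' @examples
#' massFromSequence("GGGTTGCGGAGGGTGGGCCT", nCations = 2) # 6364.3 Da
#' @export
massFromSequence <- function(sequence, nCations = 0, cationMass = 39.0983,
                             type = c("auto", "DNA", "RNA"),
                             phosphate5 = FALSE) {
  type <- match.arg(type)
  stopifnot(nCations >= 0)
  bases <- strsplit(toupper(gsub("\\s", "", sequence)), "")[[1L]]
  if (!length(bases)) stop("empty sequence")
  if (type == "auto")
    type <- if ("U" %in% bases) "RNA" else "DNA"
  tab <- .nucleosideMass[[type]]
  bad <- setdiff(bases, names(tab))
  if (length(bad))
    stop("invalid base symbol(s) for ", type, ": ",
         paste(unique(bad), collapse = ", "))
  n <- length(bases)
  sum(tab[bases]) + (n - 1) * .LINKAGE_MASS +
    (if (phosphate5) .PHOSPHATE_MASS else 0) + nCations * cationMass
}

#' Sedimentation coefficient of a rigid particle
#'
#' Svedberg relation \eqn{s = M (1 - \bar v \rho) / (N_A \, 6\pi\eta R_h)}.
#'
#' @param mass Molecular mass, Da.
#' @param vbar Partial specific volume, cm^3/g.
#' @param rh Hydrodynamic radius, nm.
#' @param solvent \linkS4class{SolventConditions}; default water at 20 C.
#' @return Sedimentation coefficient in Svedberg (1e-13 s).
#' @export
sedimentationCoefficient <- function(mass, vbar, rh,
                                     solvent = waterAt20C()) {
  stopifnot(mass > 0, vbar > 0, rh > 0)
  buoy <- 1 - vbar * solvent@density
  if (abs(buoy) < 1e-12)
    stop("neutral buoyancy: 1 - vbar * rho is zero")
  sSec <- mass * buoy / (.NA_CONST * 6 * pi * solvent@viscosity * rh * 1e-7)
  sSec / 1e-13
}

#' Standardize a sedimentation coefficient to water at 20 C
#'
#' Multiplicative buffer correction
#' \eqn{s_{20,w} = s_{T,b} \, (\eta_{T,b}/\eta_{20,w}) \,
#' (1 - \bar v \rho_{20,w}) / (1 - \bar v \rho_{T,b})},
#' with fixed standard-water constants (viscosity 0.010016 P, density
#' 0.998206 g/cm^3) and the partial specific volume treated as buffer- and
#' temperature-independent.
#'
#' @param sTb Measured sedimentation coefficient(s), S.
#' @param buffer \linkS4class{SolventConditions} of the measurement buffer.
#' @param vbar Partial specific volume, cm^3/g (default 0.541).
#' @return Standardized s, same length as \code{sTb}.
#' @examples
#' standardizeS(2.645, SolventConditions(1.0045, 0.0101543), vbar = 0.541)
#' @export
standardizeS <- function(sTb, buffer, vbar = 0.541) {
  stopifnot(is(buffer, "SolventConditions"), vbar > 0)
  denom <- 1 - vbar * buffer@density
  if (abs(denom) < 1e-12) stop("zero buoyancy denominator")
  factor <- (buffer@viscosity / .ETA_W20) *
    (1 - vbar * .RHO_W20) / denom
  sTb * factor
}

#' Frictional ratio
#'
#' \eqn{f/f_0 = R_h / R_0} with \eqn{R_0 = (3 M \bar v / 4\pi N_A)^{1/3}}
#' the radius of the compact (anhydrous) sphere of equal mass. Values
#' below 1 are unphysical for rigid bodies and trigger a warning.
#'
#' @param rh Hydrodynamic radius, nm.
#' @param mass Molecular mass, Da.
#' @param vbar Partial specific volume, cm^3/g.
#' @return Dimensionless frictional ratio.
#' @export
frictionalRatio <- function(rh, mass, vbar) {
  stopifnot(rh > 0, mass > 0, vbar > 0)
  r0 <- (3 * mass * vbar / (4 * pi * .NA_CONST))^(1 / 3) * 1e7 # cm -> nm
  fr <- rh / r0
  if (fr < 1)
    warning("frictional ratio below 1 (rh smaller than the compact ",
            "sphere); unphysical for a rigid body")
  fr
}

#' Volume of a bead model
#'
#' When the model carries a dummy-atom volume, the total volume is
#' \eqn{N V_{DA}}; otherwise the overlap-uncorrected sum of bead volumes
#' \eqn{\sum (4/3)\pi\sigma_i^3}.
#'
#' @param model A \linkS4class{BeadModel}.
#' @return Volume in nm^3 (attribute \code{method} records which rule was
#'   used).
#' @export
beadVolume <- function(model) {
  stopifnot(is(model, "BeadModel"))
  n <- nrow(model@centers)
  if (!is.na(model@dummyAtomVolume)) {
    v <- n * model@dummyAtomVolume / 1e3
    attr(v, "method") <- "dummy_atom_volume"
  } else {
    if (any(is.na(model@radii))) stop("bead radii unset and no dummy-atom volume")
    v <- sum(4 / 3 * pi * model@radii^3) / 1e3
    attr(v, "method") <- "sum_of_beads_no_overlap"
  }
  v
}
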