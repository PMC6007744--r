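#' @import methods
NULL

#' Atomic coordinate model
#'
#' Container for a hierarchical atomic model (models > chains > residues >
#' atoms) read from a PDB-format file or built by one of the synthetic
#' generators. Atoms are stored as a flat table; the (model, chain, resno)
#' columns carry the hierarchy. Coordinates are in Angstroms.
#'
#' @slot atoms data.frame with columns \code{model} (integer), \code{chain}
#'   (character), \code{resno} (integer author numbering), \code{resid}
#'   (residue name as in the file), \code{elety} (atom name, e.g. "C1'"),
#'   \code{elesy} (element symbol), \code{x}, \code{y}, \code{z}
#'   (Angstroms), \code{o} (occupancy), \code{b} (B-factor, Angstrom^2),
#'   \code{type} ("ATOM"/"HETATM").
#' @slot title Free-text header/title.
#' @export
setClass("AtomicStructure",
  representation(atoms = "data.frame", title = "character"),
  prototype(title = ""))

setValidity("AtomicStructure", function(object) {
  need <- c("model", "chain", "resno", "resid", "elety", "elesy",
            "x", "y", "z", "o", "b", "type")
  a <- object@atoms
  if (!all(need %in% names(a)))
    return(paste("atoms table must contain columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a) == 0L) return("structure contains no atoms")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("non-finite coordinates")
  if (any(a$o < 0 | a$o > 1, na.rm = TRUE))
    return("occupancies must lie in [0, 1]")
  TRUE
})

#' Dummy-atom bead model
#'
#' A rigid assembly of spherical beads: centers (Angstroms), per-bead radii
#' and weights, and (for models read from ab initio SAXS programs) the
#' dummy-atom volume parsed from the file header, related to the bead radius
#' by the sphere-volume formula.
#'
#' @slot centers numeric N x 3 matrix, Angstroms.
#' @slot radii numeric length-N bead radii, Angstroms (NA when the source
#'   file carried no volume record).
#' @slot weights numeric length-N per-bead weights (1 for dummy atoms,
#'   atomic masses for atom-derived beads).
#' @slot dummyAtomVolume single numeric, Angstrom^3, or NA when absent.
#' @export
setClass("BeadModel",
  representation(centers = "matrix", radii = "numeric",
                 weights = "numeric", dummyAtomVolume = "numeric"),
  prototype(dummyAtomVolume = NA_real_))

setValidity("BeadModel", function(object) {
  n <- nrow(object@centers)
  if (n < 1L) return("bead model must contain at least one bead")
  if (ncol(object@centers) != 3L) return("centers must be an N x 3 matrix")
  if (!all(is.finite(object@centers))) return("non-finite bead centers")
  if (length(object@radii) != n) return("radii length must match centers")
  if (length(object@weights) != n) return("weights length must match centers")
  if (any(!is.na(object@radii) & object@radii <= 0))
    return("bead radii must be positive")
  v <- object@dummyAtomVolume
  if (length(v) != 1L) return("dummyAtomVolume must be a single value")
  if (!is.na(v) && v <= 0) return("dummyAtomVolume must be positive")
  TRUE
})

#' Guanine tetrad
#'
#' An ordered 4-cycle of guanine residues joined by Hoogsteen hydrogen bonds
#' (N1->O6 and N2->N7 around the cycle), with per-adjacent-pair simple
#' base-pair parameters and a shape label.
#'
#' @slot residues character(4) residue keys "chain:resno", cycle order
#'   (donor to acceptor), starting at the lowest key.
#' @slot chains character(4) chain ids of the cycle members.
#' @slot seqNums integer(4) residue numbers of the cycle members.
#' @slot pairParams numeric 4 x 3 matrix (columns buckle, propeller,
#'   stagger; degrees, degrees, Angstroms), row k describing the pair
#'   (residue k, residue k+1 mod 4).
#' @slot normal numeric(3) unit tetrad normal, oriented along the strand
#'   5'->3' channel direction where determinable.
#' @slot origins numeric 4 x 3 base-frame origins, Angstroms.
#' @slot axes numeric 4 x 3 per-base in-plane reference axes (C1'->N9
#'   projected onto the tetrad plane), used for stacking-twist measurement.
#' @slot shape character shape label: "planar", "convex", "concave",
#'   "saddle" or "other".
#' @export
setClass("Tetrad",
  representation(residues = "character", chains = "character",
                 seqNums = "integer", pairParams = "matrix",
                 normal = "numeric", origins = "matrix", axes = "matrix",
                 shape = "character"))

setValidity("Tetrad", function(object) {
  if (length(object@residues) != 4L) return("a tetrad has exactly 4 residues")
  if (!all(dim(object@pairParams) == c(4L, 3L)))
    return("pairParams must be 4 x 3")
  if (abs(vnorm(object@normal) - 1) > 1e-6)
    return("tetrad normal must be a unit vector")
  TRUE
})

#' Solvent conditions
#'
#' Buffer density, viscosity and temperature entering the buoyancy and
#' friction terms of the Svedberg and standardization relations.
#'
#' @slot density g/cm^3.
#' @slot viscosity poise.
#' @slot temperature degrees Celsius.
#' @export
setClass("SolventConditions",
  representation(density = "numeric", viscosity = "numeric",
                 temperature = "numeric"))

setValidity("SolventConditions", function(object) {
  if (length(object@density) != 1L || object@density <= 0)
    return("density must be a single positive value (g/cm^3)")
  if (length(object@viscosity) != 1L || object@viscosity <= 0)
    return("viscosity must be a single positive value (poise)")
  TRUE
})

#' Per-concentration sedimentation-velocity species results
#'
#' One species (e.g. monomer or dimer) of a sedimentation-velocity species
#' analysis: apparent sedimentation coefficient, apparent molecular mass and
#' molecular fraction at each loading concentration, with uncertainties,
#' plus the solvent conditions and partial specific volume needed for
#' standardization.
#'
#' @slot records data.frame with columns \code{conc_mg_ml}, \code{s_app_S},
#'   \code{s_sd}, \code{M_kDa}, \code{M_sd}, \code{fraction},
#'   \code{fraction_sd}.
#' @slot speciesLabel "monomer", "dimer" or other free label.
#' @slot buffer \linkS4class{SolventConditions} of the measurement buffer.
#' @slot vbar partial specific volume, cm^3/g.
#' @slot vbarSD uncertainty of \code{vbar}, cm^3/g.
#' @slot standardized logical; TRUE once s values have been corrected to
#'   water at 20 degrees C.
#' @export
setClass("SpeciesSeries",
  representation(records = "data.frame", speciesLabel = "character",
                 buffer = "SolventConditions", vbar = "numeric",
                 vbarSD = "numeric", standardized = "logical"),
  prototype(speciesLabel = "other", vbar = 0.541, vbarSD = 0,
            standardized = FALSE))

setValidity("SpeciesSeries", function(object) {
  need <- c("conc_mg_ml", "s_app_S", "s_sd", "M_kDa", "M_sd",
            "fraction", "fraction_sd")
  r <- object@records
  if (!all(need %in% names(r)))
    return(paste("records must contain columns:",
                 paste(setdiff(need, names(r)), collapse = ", ")))
  if (any(r$conc_mg_ml <= 0)) return("concentrations must be positive")
  if (anyDuplicated(r$conc_mg_ml)) return("concentrations must be unique")
  if (any(r$fraction < 0 | r$fraction > 1, na.rm = TRUE))
    return("fractions must lie in [0, 1]")
  if (any(c(r$s_sd, r$M_sd, r$fraction_sd) < 0, na.rm = TRUE))
    return("standard deviations must be non-negative")
  if (object@vbar <= 0) return("vbar must be positive")
  TRUE
})

#' Infinite-dilution extrapolation result
#'
#' Weighted or unweighted linear fit of an apparent hydrodynamic quantity
#' against loading concentration; the intercept is the infinite-dilution
#' value, with 95\% confidence intervals from the t distribution on n - 2
#' degrees of freedom.
#'
#' @slot quantity which column was extrapolated ("s" or "M").
#' @slot intercept fitted intercept (infinite-dilution value).
#' @slot interceptCI numeric(2) 95\% confidence interval of the intercept.
#' @slot slope fitted slope (per mg/ml).
#' @slot slopeCI numeric(2) 95\% confidence interval of the slope.
#' @slot nPoints number of concentrations used.
#' @slot weighted logical, inverse-variance weighting applied.
#' @slot standardized logical, TRUE if the series had been corrected to
#'   standard conditions before fitting.
#' @export
setClass("ExtrapolationResult",
  representation(quantity = "character", intercept = "numeric",
                 interceptCI = "numeric", slope = "numeric",
                 slopeCI = "numeric", nPoints = "integer",
                 weighted = "logical", standardized = "logical"))

setValidity("ExtrapolationResult", function(object) {
  if (object@nPoints < 2L) return("extrapolation needs at least 2 points")
  if (length(object@interceptCI) != 2L || length(object@slopeCI) != 2L)
    return("confidence intervals must have length 2")
  TRUE
})
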