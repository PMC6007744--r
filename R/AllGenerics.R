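#' Accessors for g4hydro classes
#'
#' Small accessor generics: \code{atoms} returns the flat atom table of an
#' \linkS4class{AtomicStructure}; \code{nAtoms}/\code{chainIds} summarize
#' it; \code{beadCenters}, \code{beadRadii}, \code{beadWeights},
#' \code{dummyAtomVolume} and \code{nBeads} expose the slots of a
#' \linkS4class{BeadModel}; \code{records} returns the per-concentration
#' table of a \linkS4class{SpeciesSeries}.
#'
#' @param x An object of the respective class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))
#' @rdname accessors
#' @export
setGeneric("beadCenters", function(x) standardGeneric("beadCenters"))
#' @rdname accessors
#' @export
setGeneric("beadRadii", function(x) standardGeneric("beadRadii"))
#' @rdname accessors
#' @export
setGeneric("beadWeights", function(x) standardGeneric("beadWeights"))
#' @rdname accessors
#' @export
setGeneric("dummyAtomVolume", function(x) standardGeneric("dummyAtomVolume"))
#' @rdname accessors
#' @export
setGeneric("nBeads", function(x) standardGeneric("nBeads"))
#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname accessors
#' @export
setMethod("atoms", "AtomicStructure", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("nAtoms", "AtomicStructure",
          function(x) nrow(x@atoms[x@atoms$model == x@atoms$model[1L], ]))
#' @rdname accessors
#' @export
setMethod("chainIds", "AtomicStructure", function(x) unique(x@atoms$chain))
#' @rdname accessors
#' @export
setMethod("beadCenters", "BeadModel", function(x) x@centers)
#' @rdname accessors
#' @export
setMethod("beadRadii", "BeadModel", function(x) x@radii)
#' @rdname accessors
#' @export
setMethod("beadWeights", "BeadModel", function(x) x@weights)
#' @rdname accessors
#' @export
setMethod("dummyAtomVolume", "BeadModel", function(x) x@dummyAtomVolume)
#' @rdname accessors
#' @export
setMethod("nBeads", "BeadModel", function(x) nrow(x@centers))
#' @rdname accessors
#' @export
setMethod("records", "SpeciesSeries", function(x) x@records)

setMethod("show", "AtomicStructure", function(object) {
  a <- object@atoms
  m1 <- a[a$model == a$model[1L], ]
  cat("AtomicStructure:", length(unique(a$model)), "model(s),",
      length(unique(m1$chain)), "chain(s),",
      nrow(unique(m1[, c("chain", "resno")])), "residues,",
      nrow(m1), "atoms\n")
  if (nzchar(object@title)) cat("  title:", object@title, "\n")
})

setMethod("show", "BeadModel", function(object) {
  cat("BeadModel:", nrow(object@centers), "beads")
  if (!is.na(object@dummyAtomVolume))
    cat(sprintf(", dummy-atom volume %.3f A^3 (radius %.3f A)",
                object@dummyAtomVolume, object@radii[1L]))
  cat("\n")
})

setMethod("show", "Tetrad", function(object) {
  cat("Tetrad [", paste(object@residues, collapse = " -> "), "] shape:",
      object@shape, "\n")
  pp <- object@pairParams
  cat(sprintf("  buckle %s deg; propeller %s deg; stagger %s A\n",
              paste(sprintf("%.1f", pp[, 1L]), collapse = "/"),
              paste(sprintf("%.1f", pp[, 2L]), collapse = "/"),
              paste(sprintf("%.2f", pp[, 3L]), collapse = "/")))
})

setMethod("show", "SpeciesSeries", function(object) {
  cat("SpeciesSeries (", object@speciesLabel, "): ",
      nrow(object@records), " concentrations",
      if (object@standardized) ", standardized to water/20C" else "",
      "\n", sep = "")
})

setMethod("show", "SolventConditions", function(object) {
  cat(sprintf("SolventConditions: rho %.6g g/cm^3, eta %.6g P, T %.4g C\n",
              object@density, object@viscosity, object@temperature))
})

setMethod("show", "ExtrapolationResult", function(object) {
  cat(sprintf(
    "ExtrapolationResult (%s%s): intercept %.6g [%.6g, %.6g], slope %.4g [%.4g, %.4g], n = %d\n",
    object@quantity, if (object@standardized) ", standardized" else "",
    object@intercept, object@interceptCI[1L], object@interceptCI[2L],
    object@slope, object@slopeCI[1L], object@slopeCI[2L], object@nPoints))
})

#' Construct solvent conditions
#'
#' @param density buffer density, g/cm^3.
#' @param viscosity buffer viscosity, poise.
#' @param temperature temperature, degrees C.
#' @return A \linkS4class{SolventConditions} object.
#' @examples
#' hepes <- SolventConditions(1.0045, 0.0101543, 20)
#' @export
SolventConditions <- function(density, viscosity, temperature = 20) {
  new("SolventConditions", density = density, viscosity = viscosity,
      temperature = temperature)
}

#' Standard water at 20 degrees C
#'
#' The standard reference condition for sedimentation coefficients
#' (viscosity 0.010016 P, density 0.998206 g/cm^3).
#'
#' @return A \linkS4class{SolventConditions} object.
#' @export
waterAt20C <- function() SolventConditions(.RHO_W20, .ETA_W20, 20)

#' Construct a bead model
#'
#' @param centers numeric N x 3 matrix of bead centers, Angstroms.
#' @param radii per-bead radii (recycled), Angstroms; NA when unknown.
#' @param weights per-bead weights (recycled), default 1.
#' @param dummyAtomVolume optional dummy-atom volume, Angstrom^3.
#' @return A \linkS4class{BeadModel}.
#' @export
BeadModel <- function(centers, radii = NA_real_, weights = 1,
                      dummyAtomVolume = NA_real_) {
  centers <- as.matrix(centers)
  storage.mode(centers) <- "double"
  n <- nrow(centers)
  new("BeadModel", centers = centers,
      radii = rep_len(as.numeric(radii), n),
      weights = rep_len(as.numeric(weights), n),
      dummyAtomVolume = as.numeric(dummyAtomVolume))
}
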