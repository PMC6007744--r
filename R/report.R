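## One-shot analysis chain: torsions -> tetrads -> stacking/ion geometry ->
## hydrodynamics, with a JSON-serializable result.

#' Run the full quadruplex analysis chain
#'
#' Executes, for one structure, the torsion profile of every chain, tetrad
#' detection and shape classification, stacking-twist and channel-ion
#' measurements, and hydrodynamic descriptors from the atomic bead model
#' (Rg, P(r)/Dmax, Rh, volume, and - when a sequence-derived mass is
#' available - sedimentation coefficient and frictional ratio). Identical
#' configuration and inputs yield an identical report (no randomness).
#'
#' Failures of individual stages are collected in the \code{failures}
#' element rather than aborting the remaining stages.
#'
#' @param input An \linkS4class{AtomicStructure} or a path to a PDB file.
#' @param aer Atomic element radius for the bead conversion, Angstroms.
#' @param hoogsteenCutoff Hoogsteen donor-acceptor cutoff, Angstroms.
#' @param planarityThreshold Tetrad planarity threshold, degrees.
#' @param gammaRange,zetaRange Special torsion ranges, degrees.
#' @param vbar Partial specific volume, cm^3/g.
#' @param buffer \linkS4class{SolventConditions} for s standardization.
#' @param rhMethod "kirkwood" or "rpy" for the hydrodynamic radius.
#' @param ionElement Channel cation element symbol.
#' @param outJson Optional path; when given, the report is written as JSON.
#' @return A list with elements \code{torsions} (one table per chain),
#'   \code{tetrads}, \code{stackingTwists}, \code{ionSpacing},
#'   \code{hydro}, \code{failures}.
#' @export
runReport <- function(input, aer = 2.54, hoogsteenCutoff = 3.5,
                      planarityThreshold = 5, gammaRange = c(-75, -45),
                      zetaRange = c(75, 180), vbar = 0.541,
                      buffer = waterAt20C(),
                      rhMethod = c("kirkwood", "rpy"), ionElement = "K",
                      outJson = NULL) {
  rhMethod <- match.arg(rhMethod)
  structure <- if (is(input, "AtomicStructure")) input
               else readStructure(input)
  failures <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      failures <<- c(failures, paste0(name, ": ", conditionMessage(e)))
      NULL
    })
  }
  tetrads <- stage("tetrads", detectTetrads(
    structure, cutoff = hoogsteenCutoff,
    planarityThreshold = planarityThreshold))
  coreKeys <- if (length(tetrads))
    unique(unlist(lapply(tetrads, function(t) t@residues))) else NULL
  nucChains <- unique(structure@atoms$chain[
    !is.na(normalizeBaseName(structure@atoms$resid))])
  torsions <- stage("torsions", {
    tl <- lapply(nucChains, function(ch)
      flagSpecialRanges(torsionProfile(structure, ch),
                        coreResidues = coreKeys,
                        gammaRange = gammaRange, zetaRange = zetaRange))
    names(tl) <- nucChains
    tl
  })
  twists <- stage("stacking", {
    if (length(tetrads) >= 2L) {
      vapply(seq_len(length(tetrads) - 1L), function(i)
        tryCatch(stackingTwist(tetrads[[i]], tetrads[[i + 1L]]),
                 error = function(e) NA_real_), numeric(1L))
    } else numeric(0)
  })
  spacing <- stage("ions", channelIonSpacing(structure, ionElement))
  hydro <- stage("hydro", {
    beads <- atomsToBeads(structure, aer = aer)
    pr <- pairDistanceDistribution(beads)
    rh <- hydrodynamicRadius(beads, method = rhMethod)
    seqs <- vapply(nucChains, function(ch) {
      rt <- .chainResidues(structure, ch)
      paste(normalizeBaseName(rt$resid), collapse = "")
    }, character(1L))
    nIons <- sum(structure@atoms$model == structure@atoms$model[1L] &
                 structure@atoms$elesy == toupper(ionElement))
    mass <- if (!any(grepl("NA", seqs, fixed = TRUE)) && length(seqs))
      sum(vapply(seqs, massFromSequence, numeric(1L))) +
        nIons * atomicMass(ionElement) else NA_real_
    out <- list(nBeads = nBeads(beads), rgNm = radiusOfGyration(beads),
                dmaxNm = pr$dmax, rhNm = rh, method = rhMethod,
                volumeNm3 = as.numeric(beadVolume(beads)), massDa = mass)
    if (is.finite(mass)) {
      out$sS <- sedimentationCoefficient(mass, vbar, rh)
      out$frictionalRatio <- frictionalRatio(rh, mass, vbar)
    }
    out
  })
  report <- list(
    config = list(aer = aer, hoogsteenCutoff = hoogsteenCutoff,
                  planarityThreshold = planarityThreshold,
                  gammaRange = gammaRange, zetaRange = zetaRange,
                  vbar = vbar, rhMethod = rhMethod),
    nTetrads = length(tetrads),
    tetrads = lapply(tetrads, function(t) list(
      residues = t@residues, shape = t@shape,
      buckle = unname(t@pairParams[, 1L]),
      propeller = unname(t@pairParams[, 2L]),
      stagger = unname(t@pairParams[, 3L]),
      normal = t@normal)),
    stackingTwists = twists,
    ionSpacing = spacing,
    torsions = torsions,
    hydro = hydro,
    failures = failures)
  if (!is.null(outJson))
    jsonlite::write_json(report, outJson, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
  report
}
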