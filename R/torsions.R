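## Backbone and glycosidic torsion-angle profiling for nucleic-acid chains,
## syn/anti classification, and flagging of the bulge/loop-associated gamma
## and zeta ranges.

## backbone atom-name quartets per torsion; (i-1)/(i+1) marks the
## neighbouring residue's atom
.TORSION_DEFS <- list(
  alpha   = list(c("O3'", -1L), c("P", 0L), c("O5'", 0L), c("C5'", 0L)),
  beta    = list(c("P", 0L), c("O5'", 0L), c("C5'", 0L), c("C4'", 0L)),
  gamma   = list(c("O5'", 0L), c("C5'", 0L), c("C4'", 0L), c("C3'", 0L)),
  delta   = list(c("C5'", 0L), c("C4'", 0L), c("C3'", 0L), c("O3'", 0L)),
  epsilon = list(c("C4'", 0L), c("C3'", 0L), c("O3'", 0L), c("P", 1L)),
  zeta    = list(c("C3'", 0L), c("O3'", 0L), c("P", 1L), c("O5'", 1L))
)

#' Per-residue torsion profile of a nucleic-acid chain
#'
#' Computes the six backbone torsions (alpha: O3'(i-1)-P-O5'-C5'; beta:
#' P-O5'-C5'-C4'; gamma: O5'-C5'-C4'-C3'; delta: C5'-C4'-C3'-O3'; epsilon:
#' C4'-C3'-O3'-P(i+1); zeta: C3'-O3'-P(i+1)-O5'(i+1)) and the glycosidic
#' torsion chi (purines O4'-C1'-N9-C4, pyrimidines O4'-C1'-N1-C2) for every
#' residue of one chain, in degrees in \eqn{(-180, 180]}. Residues are taken
#' in residue-number order. Missing atoms (chain termini, disordered bases)
#' yield NA angles rather than errors. The glycosidic class (syn/anti) is
#' attached via \code{\link{classifyGlycosidic}}.
#'
#' @param structure An \linkS4class{AtomicStructure}.
#' @param chainId Chain identifier; default is the first chain.
#' @param model Model number (for NMR-style multi-model files).
#' @return A torsion table: data.frame with columns \code{chain},
#'   \code{resno}, \code{resid}, \code{base} (normalized base class),
#'   \code{alpha} ... \code{zeta}, \code{chi}, \code{glycosidic}
#'   ("syn"/"anti"/NA), and logical flag columns \code{gamma_bulge_range}
#'   and \code{zeta_loop_range} (initialized FALSE; see
#'   \code{\link{flagSpecialRanges}}).
#' @export
torsionProfile <- function(structure, chainId = NULL, model = 1L) {
  stopifnot(is(structure, "AtomicStructure"))
  if (is.null(chainId)) chainId <- structure@atoms$chain[1L]
  resTab <- .chainResidues(structure, chainId, model = model)
  n <- nrow(resTab)
  resList <- lapply(seq_len(n), function(i)
    residueAtoms(structure, chainId, resTab$resno[i], model = model))
  coords <- function(i, name) {
    if (i < 1L || i > n) return(NULL)
    .atomXYZ(resList[[i]], name)
  }
  out <- data.frame(chain = resTab$chain, resno = resTab$resno,
                    resid = resTab$resid,
                    base = normalizeBaseName(resTab$resid),
                    stringsAsFactors = FALSE)
  for (ang in names(.TORSION_DEFS)) out[[ang]] <- NA_real_
  out$chi <- NA_real_
  for (i in seq_len(n)) {
    for (ang in names(.TORSION_DEFS)) {
      def <- .TORSION_DEFS[[ang]]
      pts <- lapply(def, function(d) coords(i + as.integer(d[2L]), d[1L]))
      if (!any(vapply(pts, is.null, logical(1L)))) {
        out[[ang]][i] <- tryCatch(
          dihedral(pts[[1L]], pts[[2L]], pts[[3L]], pts[[4L]]),
          error = function(e) NA_real_)
      }
    }
    base <- out$base[i]
    chiNames <- if (isTRUE(isPurine(base))) c("O4'", "C1'", "N9", "C4")
                else c("O4'", "C1'", "N1", "C2")
    pts <- lapply(chiNames, function(nm) coords(i, nm))
    if (!any(vapply(pts, is.null, logical(1L)))) {
      out$chi[i] <- tryCatch(
        dihedral(pts[[1L]], pts[[2L]], pts[[3L]], pts[[4L]]),
        error = function(e) NA_real_)
    }
  }
  out$glycosidic <- classifyGlycosidic(out$chi)
  out$gamma_bulge_range <- FALSE
  out$zeta_loop_range <- FALSE
  out
}

#' Syn/anti glycosidic classification
#'
#' A glycosidic torsion chi is classified syn when chi lies in
#' \eqn{(-90, +90]} degrees and anti otherwise. The boundary makes the
#' classification total over defined angles; undefined (NA) chi yields NA.
#'
#' @param chi Glycosidic torsion(s), degrees in \eqn{(-180, 180]}.
#' @return Character vector "syn"/"anti" (NA where chi is NA).
#' @examples
#' classifyGlycosidic(c(-120, 60)) # "anti" "syn"
#' @export
classifyGlycosidic <- function(chi) {
  out <- ifelse(is.na(chi), NA_character_,
                ifelse(chi > -90 & chi <= 90, "syn", "anti"))
  as.character(out)
}

#' Flag bulge/loop-associated torsion ranges
#'
#' Marks residues whose gamma torsion falls in the bulge-associated range
#' (default \eqn{[-75, -45]} degrees) or whose zeta torsion falls in the
#' loop-associated range (default \eqn{[75, 180]} degrees). Idealized
#' quadruplexes without loops or bulges populate neither range, so these
#' flags highlight the torsional signature of accommodating a bulge or
#' loop in the quadruplex core. Flags can be restricted to a set of core
#' residues (e.g. tetrad guanylates).
#'
#' @param table A torsion table from \code{\link{torsionProfile}}.
#' @param coreResidues Optional character vector of residue keys
#'   "chain:resno" to which flagging is restricted; default all rows.
#' @param gammaRange Numeric(2), degrees (default c(-75, -45)).
#' @param zetaRange Numeric(2), degrees (default c(75, 180)).
#' @return The table with \code{gamma_bulge_range} and
#'   \code{zeta_loop_range} updated.
#' @export
flagSpecialRanges <- function(table, coreResidues = NULL,
                              gammaRange = c(-75, -45),
                              zetaRange = c(75, 180)) {
  stopifnot(is.data.frame(table), all(c("gamma", "zeta") %in% names(table)))
  inCore <- if (is.null(coreResidues)) rep(TRUE, nrow(table))
            else paste(table$chain, table$resno, sep = ":") %in% coreResidues
  g <- table$gamma
  z <- table$zeta
  table$gamma_bulge_range <- inCore & !is.na(g) &
    g >= min(gammaRange) & g <= max(gammaRange)
  table$zeta_loop_range <- inCore & !is.na(z) &
    z >= min(zetaRange) & z <= max(zetaRange)
  table
}

#' Export a torsion table as CSV
#'
#' One row per residue with all seven angles, the syn/anti class and the
#' range flags; the tabular twin of a backbone torsion-angle plot.
#'
#' @param table Torsion table from \code{\link{torsionProfile}}.
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
writeTorsionCSV <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
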