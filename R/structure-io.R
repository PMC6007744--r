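## Coordinate-file input/output. Parsing and record writing are delegated to
## bio3d; this layer adds alternate-location resolution, hydrogen filtering,
## multi-model bookkeeping and the dummy-atom bead-model dialect.

.atomsFromBio3d <- function(pdb, hydrogens) {
  at <- pdb$atom
  nModels <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  elesy <- at$elesy
  if (is.null(elesy) || all(is.na(elesy)) || all(!nzchar(trimws(elesy)))) {
    elesy <- rep(NA_character_, nrow(at))
  }
  elesy <- trimws(elesy)
  ## derive the element from the atom name where the element column is blank
  guess <- toupper(sub("[0-9'*].*$", "", trimws(at$elety)))
  guess <- substr(guess, 1L, ifelse(guess %in% c("CL", "BR", "NA", "MG", "BA"),
                                    2L, 1L))
  elesy[is.na(elesy) | !nzchar(elesy)] <- guess[is.na(elesy) | !nzchar(elesy)]
  chain <- at$chain
  chain[is.na(chain)] <- " "
  o <- at$o
  o[is.na(o)] <- 1
  b <- at$b
  b[is.na(b)] <- 0
  xyz <- matrix(pdb$xyz, nrow = nModels)
  out <- do.call(rbind, lapply(seq_len(nModels), function(m) {
    data.frame(model = m, chain = chain, resno = as.integer(at$resno),
               resid = trimws(at$resid), elety = trimws(at$elety),
               elesy = toupper(elesy),
               x = xyz[m, seq(1L, ncol(xyz), 3L)],
               y = xyz[m, seq(2L, ncol(xyz), 3L)],
               z = xyz[m, seq(3L, ncol(xyz), 3L)],
               o = o, b = b, type = at$type,
               alt = if (is.null(at$alt)) NA_character_ else at$alt,
               stringsAsFactors = FALSE)
  }))
  ## alternate locations: keep the highest-occupancy conformer, ties going
  ## to the first encountered
  hasAlt <- !is.na(out$alt) & nzchar(trimws(out$alt))
  if (any(hasAlt)) {
    key <- paste(out$model, out$chain, out$resno, out$elety, sep = "\r")
    keep <- rep(TRUE, nrow(out))
    for (k in unique(key[hasAlt])) {
      idx <- which(key == k)
      if (length(idx) > 1L) keep[idx[-which.max(out$o[idx])]] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
  }
  out$alt <- NULL
  if (!hydrogens) out <- out[out$elesy != "H", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an atomic coordinate file
#'
#' Reads a PDB-format coordinate file into an
#' \linkS4class{AtomicStructure}. All ATOM/HETATM records are represented;
#' NMR-style multi-model files preserve model order; alternate locations
#' are resolved to the highest-occupancy conformer (ties to the first
#' encountered). Hydrogens are dropped by default because the geometric and
#' hydrodynamic analyses operate on heavy atoms.
#'
#' @param path Path to the coordinate file.
#' @param formatHint Optional format name; only "pdb" is supported.
#' @param hydrogens Keep hydrogen atoms? Default FALSE.
#' @return An \linkS4class{AtomicStructure}.
#' @seealso \code{\link{writeStructure}}, \code{\link{readBeadModel}}
#' @export
readStructure <- function(path, formatHint = "pdb", hydrogens = FALSE) {
  if (!file.exists(path)) stop("cannot read coordinate file: ", path)
  if (!identical(tolower(formatHint), "pdb"))
    stop("unsupported format hint: ", formatHint)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("unreadable coordinate file '", path, "': ",
                             conditionMessage(e)))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0L)
    stop("no atom records found in ", path)
  atoms <- .atomsFromBio3d(pdb, hydrogens = hydrogens)
  if (nrow(atoms) == 0L) stop("no atom records left after filtering in ", path)
  new("AtomicStructure", atoms = atoms, title = "")
}

#' Write an atomic structure to a PDB-format file
#'
#' Writes standard ATOM records (coordinates to 3 decimals) such that
#' \code{readStructure(writeStructure(x))} is the identity up to format
#' precision. Only the first model is written. Files with more than 99999
#' atoms exceed the fixed-width serial field and are refused.
#'
#' @param structure An \linkS4class{AtomicStructure}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeStructure <- function(structure, path) {
  stopifnot(is(structure, "AtomicStructure"))
  a <- structure@atoms
  a <- a[a$model == a$model[1L], , drop = FALSE]
  if (nrow(a) > 99999L)
    stop("structure has more than 99999 atoms; fixed-width PDB numbering ",
         "would overflow")
  ok <- tryCatch({
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     type = a$type, resno = a$resno, resid = a$resid,
                     chain = ifelse(a$chain == " ", "", a$chain),
                     elety = a$elety, o = a$o, b = a$b, elesy = a$elesy)
    TRUE
  }, error = function(e) stop("cannot write '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read a SAXS dummy-atom bead model
#'
#' Reads DAMMIF/DAMMIN-style dummy-atom PDB files (one bead per ATOM
#' record). The per-bead volume is parsed from a header remark matching the
#' phrases "dummy atom volume" (DAMMIF) or "average volume per atom"
#' (DAMMIN), case-insensitively; when present, all bead radii are set from
#' it via \code{\link{aerFromVolume}}, otherwise radii are left NA.
#'
#' @param path Path to the bead-model file.
#' @return A \linkS4class{BeadModel} with unit weights.
#' @export
readBeadModel <- function(path) {
  if (!file.exists(path)) stop("cannot read bead-model file: ", path)
  header <- grep("^(REMARK|TITLE|HEADER)", readLines(path, warn = FALSE),
                 value = TRUE)
  vda <- NA_real_
  hit <- grep("dummy atom volume|average volume per atom", header,
              ignore.case = TRUE, value = TRUE)
  if (length(hit)) {
    num <- regmatches(hit[1L],
                      regexpr("[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?\\s*$",
                              hit[1L]))
    if (length(num) && nzchar(trimws(num))) {
      vda <- as.numeric(trimws(num))
    } else {
      warning("malformed volume remark in ", path, "; radii left unset")
    }
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("unreadable bead-model file '", path, "': ",
                             conditionMessage(e)))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0L)
    stop("no bead records found in ", path)
  centers <- as.matrix(pdb$atom[, c("x", "y", "z")])
  radii <- if (is.na(vda)) NA_real_ else aerFromVolume(vda)
  BeadModel(centers, radii = radii, weights = 1, dummyAtomVolume = vda)
}

#' Write a bead model as a dummy-atom PDB file
#'
#' Emits the DAMMIF-style dialect read back by \code{\link{readBeadModel}}:
#' a "Dummy atom volume" remark (when the model carries one) followed by one
#' ATOM record per bead with residue name DUM.
#'
#' @param model A \linkS4class{BeadModel}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeBeadModel <- function(model, path) {
  stopifnot(is(model, "BeadModel"))
  n <- nrow(model@centers)
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  bio3d::write.pdb(file = tmp,
                   xyz = as.numeric(t(model@centers)),
                   type = rep("ATOM", n), resno = seq_len(n),
                   resid = rep("DUM", n), chain = rep("A", n),
                   elety = rep("CA", n), o = rep(1, n), b = rep(0, n))
  body <- readLines(tmp, warn = FALSE)
  head <- character(0)
  if (!is.na(model@dummyAtomVolume))
    head <- sprintf("REMARK 265  Dummy atom volume   : %.4f", model@dummyAtomVolume)
  writeLines(c(head, body), path)
  invisible(path)
}

## --- residue-level access -------------------------------------------------

## atoms of one residue (first model), as a small data.frame
residueAtoms <- function(structure, chainId, seqNum, model = 1L) {
  a <- structure@atoms
  out <- a[a$model == model & a$chain == chainId & a$resno == seqNum, ,
           drop = FALSE]
  if (nrow(out) == 0L)
    stop("no residue ", chainId, ":", seqNum, " in structure")
  out
}

## coordinates of a named atom inside a residue table, or NULL
.atomXYZ <- function(res, name) {
  alias <- c(name, chartr("'", "*", name))
  i <- which(res$elety %in% alias)
  if (!length(i)) return(NULL)
  as.numeric(res[i[1L], c("x", "y", "z")])
}

## residue index table of one chain, ordered by residue number
.chainResidues <- function(structure, chainId, model = 1L) {
  a <- structure@atoms
  a <- a[a$model == model & a$chain == chainId, , drop = FALSE]
  if (nrow(a) == 0L) stop("chain not found: ", chainId)
  u <- unique(a[, c("chain", "resno", "resid")])
  u[order(u$resno), , drop = FALSE]
}
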