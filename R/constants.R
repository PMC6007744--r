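## Physical constants and reference tables.

## Avogadro constant, 1/mol
.NA_CONST <- 6.02214076e23

## standard water at 20 degrees C (SEDNTERP-compatible values):
## viscosity in poise, density in g/cm^3
.ETA_W20 <- 0.010016
.RHO_W20 <- 0.998206

## average atomic masses, Da
.ATOMIC_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.973762,
  S = 32.06, K = 39.0983, NA. = 22.98977, MG = 24.305, CL = 35.45,
  BR = 79.904, BA = 137.327, F = 18.998403, I = 126.90447
)

atomicMass <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  m <- .ATOMIC_MASS[key]
  if (anyNA(m))
    stop("no atomic mass tabulated for element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  unname(m)
}

## Standard planar base reference frames (base ring atoms + C1', z = 0).
## Coordinates follow the published standard nucleic-acid base frames; they
## serve as least-squares fitting templates, so only their internal geometry
## matters (locked by the equivariance/invariance tests, not by absolute
## values).
.BASE_TEMPLATES <- list(
  G = rbind(
    N9    = c(-1.289, 4.551, 0), C8  = c( 0.023, 4.962, 0),
    N7    = c( 0.870, 3.969, 0), C5  = c( 0.071, 2.833, 0),
    C6    = c( 0.424, 1.460, 0), O6  = c( 1.554, 0.955, 0),
    N1    = c(-0.700, 0.641, 0), C2  = c(-1.999, 1.087, 0),
    N2    = c(-2.949, 0.139, 0), N3  = c(-2.342, 2.364, 0),
    C4    = c(-1.265, 3.177, 0), `C1'` = c(-2.477, 5.399, 0)),
  A = rbind(
    N9    = c(-1.291, 4.498, 0), C8  = c( 0.024, 4.897, 0),
    N7    = c( 0.877, 3.902, 0), C5  = c( 0.071, 2.771, 0),
    C6    = c( 0.369, 1.398, 0), N6  = c( 1.611, 0.909, 0),
    N1    = c(-0.668, 0.532, 0), C2  = c(-1.912, 1.023, 0),
    N3    = c(-2.320, 2.290, 0), C4  = c(-1.267, 3.124, 0),
    `C1'` = c(-2.479, 5.346, 0)),
  C = rbind(
    N1    = c(-1.285, 4.542, 0), C2  = c(-1.472, 3.158, 0),
    O2    = c(-2.628, 2.709, 0), N3  = c(-0.391, 2.344, 0),
    C4    = c( 0.837, 2.868, 0), N4  = c( 1.875, 2.027, 0),
    C5    = c( 1.056, 4.275, 0), C6  = c(-0.023, 5.068, 0),
    `C1'` = c(-2.477, 5.402, 0)),
  U = rbind(
    N1    = c(-1.284, 4.500, 0), C2  = c(-1.462, 3.131, 0),
    O2    = c(-2.563, 2.608, 0), N3  = c(-0.302, 2.397, 0),
    C4    = c( 0.989, 2.884, 0), O4  = c( 1.935, 2.094, 0),
    C5    = c( 1.089, 4.311, 0), C6  = c(-0.024, 5.053, 0),
    `C1'` = c(-2.491, 5.430, 0))
)
.BASE_TEMPLATES$T <- .BASE_TEMPLATES$U

## purine / pyrimidine ring atoms used for frame fitting
.PURINE_RING <- c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
.PYRIMIDINE_RING <- c("N1", "C2", "N3", "C4", "C5", "C6")

## Map residue names to a one-letter base class; DNA and RNA share classes.
normalizeBaseName <- function(resid) {
  r <- toupper(trimws(resid))
  r <- sub("^D", "", r)         # DG, DA, DC, DT, DU
  map <- c(G = "G", GUA = "G", A = "A", ADE = "A", C = "C", CYT = "C",
           T = "T", THY = "T", U = "U", URA = "U")
  out <- unname(map[r])
  out[is.na(out)] <- NA_character_
  out
}

isPurine <- function(baseClass) baseClass %in% c("G", "A")

## average masses of 2'-deoxyribo- and ribonucleosides, computed from their
## molecular formulas (5'-OH, 3'-OH)
.nucleosideMass <- local({
  f <- function(c, h, n, o)
    c * 12.011 + h * 1.008 + n * 14.007 + o * 15.999
  list(
    DNA = c(A = f(10, 13, 5, 3), C = f(9, 13, 3, 4),
            G = f(10, 13, 5, 4), T = f(10, 14, 2, 5)),
    RNA = c(A = f(10, 13, 5, 4), C = f(9, 13, 3, 5),
            G = f(10, 13, 5, 5), U = f(9, 12, 2, 6))
  )
})

## internal phosphodiester linkage: +HPO3, -H2O
.LINKAGE_MASS <- (1.008 + 30.973762 + 3 * 15.999) - (2 * 1.008 + 15.999)
## terminal 5'-monophosphate (HPO3)
.PHOSPHATE_MASS <- 1.008 + 30.973762 + 3 * 15.999
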