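# Shared helpers: rigid motions and small hand-built fixtures, all
# generated in code.

# cross product (test-local copy, independent of package internals)
vcrossTest <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# random proper rotation matrix, deterministic for a given seed
randomRotation <- function(seed) {
  set.seed(seed)
  q <- svd(matrix(rnorm(9), 3))$u
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply a rigid motion (rotation + translation) to a structure
rigidMotion <- function(structure, rot = diag(3), shift = c(0, 0, 0)) {
  a <- atoms(structure)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(rot)
  a$x <- xyz[, 1] + shift[1]
  a$y <- xyz[, 2] + shift[2]
  a$z <- xyz[, 3] + shift[3]
  methods::new("AtomicStructure", atoms = a, title = structure@title)
}

# rotate a residue atom table about an axis through a point
rotateResidue <- function(res, axis, origin, angleDeg) {
  axis <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  xyz <- t(R %*% (t(as.matrix(res[, c("x", "y", "z")])) - origin) + origin)
  res$x <- xyz[, 1]
  res$y <- xyz[, 2]
  res$z <- xyz[, 3]
  res
}

# minimal hand-formatted PDB ATOM line (fixed-width)
pdbAtomLine <- function(serial, name, alt, resname, chain, resno,
                        x, y, z, occ, b, element) {
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resname, chain, resno, x, y, z, occ, b, element)
}

# a NeRF backbone spec with uniform torsion values
backboneSpec <- function(nres, torsion, bondLength = 1.55, bondAngle = 110) {
  bb <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'")
  data.frame(name = rep(bb, nres), resno = rep(seq_len(nres), each = 6),
             bondLength = bondLength, bondAngle = bondAngle,
             torsion = torsion, stringsAsFactors = FALSE)
}
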