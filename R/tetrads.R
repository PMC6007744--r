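## Guanine-tetrad detection from Hoogsteen hydrogen-bond geometry, simple
## base-pair parameters (buckle / propeller / stagger), shape
## classification, stacking twist and channel-ion spacing.

#' Standard base reference frame of a residue
#'
#' Least-squares (Kabsch) superposition of the residue's base ring atoms
#' (9 for purines, 6 for pyrimidines) onto a planar standard base template.
#' The frame origin is the image of the template origin; the z axis is the
#' fitted base-plane normal, whose sign follows the template's atom-order
#' chirality and is therefore consistent across a structure.
#'
#' @param res Residue atom table (from \code{residueAtoms}) or an
#'   \linkS4class{AtomicStructure} together with \code{chainId}/\code{seqNum}.
#' @param chainId,seqNum Residue address when \code{res} is a structure.
#' @return List with elements \code{origin} (3-vector, Angstroms),
#'   \code{x}, \code{y}, \code{z} (orthonormal right-handed axes),
#'   \code{rotation} (3 x 3), \code{rmsd} (fit residual, Angstroms), and
#'   \code{base} (base class).
#' @export
baseFrame <- function(res, chainId = NULL, seqNum = NULL) {
  if (is(res, "AtomicStructure")) {
    stopifnot(!is.null(chainId), !is.null(seqNum))
    res <- residueAtoms(res, chainId, seqNum)
  }
  base <- normalizeBaseName(res$resid[1L])
  if (is.na(base))
    stop("residue ", res$resid[1L], " is not a recognized nucleotide")
  tmpl <- .BASE_TEMPLATES[[base]]
  ring <- if (isPurine(base)) .PURINE_RING else .PYRIMIDINE_RING
  obs <- lapply(ring, function(nm) .atomXYZ(res, nm))
  missing <- ring[vapply(obs, is.null, logical(1L))]
  if (length(missing))
    stop("cannot build base frame: missing ring atom(s) ",
         paste(missing, collapse = ", "))
  obs <- do.call(rbind, obs)
  fit <- kabsch(tmpl[ring, , drop = FALSE], obs)
  pred <- sweep(tmpl[ring, ] %*% t(fit$rotation), 2L, -fit$translation)
  list(origin = fit$translation,
       x = fit$rotation[, 1L], y = fit$rotation[, 2L],
       z = fit$rotation[, 3L], rotation = fit$rotation,
       rmsd = sqrt(mean(rowSums((pred - obs)^2))), base = base)
}

## Bend decomposition shared by the public and the cycle-oriented pair
## parameters. Axes: m = mean base normal; yAxis = reference long axis
## projected perpendicular to m; x = y cross m. The rotation taking z_i to
## z_j is resolved into its components about x (buckle) and y (propeller).
.pairBend <- function(zi, zj, yRef, oi, oj) {
  if (sum(zi * zj) < 0) zj <- -zj
  m <- unitv(zi + zj)
  yv <- yRef - sum(yRef * m) * m
  if (vnorm(yv) < 1e-9) stop("degenerate pair long axis")
  yv <- unitv(yv)
  xv <- vcross(yv, m)
  cr <- vcross(zi, zj)
  phi <- rad2deg(atan2(vnorm(cr), sum(zi * zj)))
  a <- if (vnorm(cr) < 1e-12) c(0, 0, 0) else unitv(cr)
  list(buckle = phi * sum(a * xv), propeller = phi * sum(a * yv),
       stagger = sum((oj - oi) * m), m = m)
}

#' Simple base-pair parameters
#'
#' Buckle, propeller twist and stagger of a (possibly non-canonical) base
#' pair, computed from the two standard base frames with the C1'-C1'
#' direction as the pair long axis: the rotation taking the first base's
#' normal onto the second's is resolved into its component about the long
#' axis (propeller) and about the in-plane axis perpendicular to it
#' (buckle), so that buckle and propeller are the two components of the
#' total inter-normal bend. Stagger is the displacement of the frame
#' origins along the mean normal, reported as an unsigned magnitude.
#'
#' The in-plane axes are tied to the canonical (residue-key-ordered) pair,
#' while the bend is measured from the first argument to the second;
#' swapping the arguments therefore negates buckle and propeller and leaves
#' stagger unchanged.
#'
#' @param resI,resJ Residue atom tables (from \code{residueAtoms}).
#' @return List with \code{buckle} (degrees), \code{propeller} (degrees),
#'   \code{stagger} (Angstroms, >= 0).
#' @export
simplePairParams <- function(resI, resJ) {
  fi <- baseFrame(resI)
  fj <- baseFrame(resJ)
  c1i <- .atomXYZ(resI, "C1'")
  c1j <- .atomXYZ(resJ, "C1'")
  if (is.null(c1i) || is.null(c1j))
    stop("both residues need a C1' atom for the pair long axis")
  keyI <- paste(resI$chain[1L], resI$resno[1L], sep = ":")
  keyJ <- paste(resJ$chain[1L], resJ$resno[1L], sep = ":")
  ## canonical long axis: from the lower to the higher residue key
  yRef <- if (keyI <= keyJ) c1j - c1i else c1i - c1j
  bend <- .pairBend(fi$z, fj$z, yRef, fi$origin, fj$origin)
  list(buckle = bend$buckle, propeller = bend$propeller,
       stagger = abs(bend$stagger))
}

## guanine Hoogsteen-edge coordinates needed for detection
.hoogsteenAtoms <- function(res) {
  list(N1 = .atomXYZ(res, "N1"), O6 = .atomXYZ(res, "O6"),
       N2 = .atomXYZ(res, "N2"), N7 = .atomXYZ(res, "N7"))
}

#' Detect guanine tetrads
#'
#' Builds a directed Hoogsteen hydrogen-bond graph over all guanine
#' residues: an edge g -> h exists when both heavy-atom donor-acceptor
#' distances N1(g)-O6(h) and N2(g)-N7(h) are at most \code{cutoff}
#' (hydrogens are not required, so no angle term is used). Tetrads are
#' directed 4-cycles in this graph; each guanine joins at most one tetrad.
#' Cycle order is normalized to start at the lowest residue key, following
#' the donor-to-acceptor direction. Detection is invariant to file order
#' and to rigid motion of the structure.
#'
#' For each tetrad, simple pair parameters are computed for the four
#' adjacent pairs around the cycle with a cycle-consistent orientation (the
#' tetrad normal, oriented along the strands' 5'-to-3' direction where that
#' is determinable, serves as the common reference), and the shape is
#' classified with \code{\link{classifyTetradShape}}.
#'
#' @param structure An \linkS4class{AtomicStructure}.
#' @param cutoff Donor-acceptor heavy-atom distance cutoff, Angstroms
#'   (default 3.5).
#' @param planarityThreshold Degrees, passed to
#'   \code{\link{classifyTetradShape}}.
#' @param model Model number.
#' @return List of \linkS4class{Tetrad} objects (possibly empty), ordered
#'   along the channel axis.
#' @export
detectTetrads <- function(structure, cutoff = 3.5, planarityThreshold = 5,
                          model = 1L) {
  stopifnot(is(structure, "AtomicStructure"))
  a <- structure@atoms
  a <- a[a$model == model, , drop = FALSE]
  gsel <- unique(a[!is.na(normalizeBaseName(a$resid)) &
                   normalizeBaseName(a$resid) == "G", c("chain", "resno")])
  if (nrow(gsel) == 0L) return(list())
  gsel <- gsel[order(gsel$chain, gsel$resno), , drop = FALSE]
  keys <- paste(gsel$chain, gsel$resno, sep = ":")
  resList <- lapply(seq_len(nrow(gsel)), function(i)
    residueAtoms(structure, gsel$chain[i], gsel$resno[i], model = model))
  hoog <- lapply(resList, .hoogsteenAtoms)
  ok <- vapply(hoog, function(h) !any(vapply(h, is.null, logical(1L))),
               logical(1L))
  ng <- length(keys)
  ## directed edges donor -> acceptor
  edges <- vector("list", ng)
  for (i in seq_len(ng)) {
    if (!ok[i]) next
    tgt <- integer(0)
    for (j in seq_len(ng)) {
      if (i == j || !ok[j]) next
      if (vnorm(hoog[[i]]$N1 - hoog[[j]]$O6) <= cutoff &&
          vnorm(hoog[[i]]$N2 - hoog[[j]]$N7) <= cutoff)
        tgt <- c(tgt, j)
    }
    edges[[i]] <- tgt
  }
  ## directed 4-cycles, deduplicated by member set
  cycles <- list()
  seen <- character(0)
  for (i in seq_len(ng)) {
    for (j in edges[[i]]) for (k in edges[[j]]) for (l in edges[[k]]) {
      if (i %in% edges[[l]] && length(unique(c(i, j, k, l))) == 4L) {
        cyc <- c(i, j, k, l)
        start <- order(keys[cyc])[1L]
        cyc <- cyc[((seq_len(4L) + start - 2L) %% 4L) + 1L]
        id <- paste(sort(keys[cyc]), collapse = "|")
        if (!(id %in% seen)) {
          seen <- c(seen, id)
          cycles[[length(cycles) + 1L]] <- cyc
        }
      }
    }
  }
  if (!length(cycles)) return(list())
  ## each guanine in at most one tetrad (deterministic greedy order)
  cycles <- cycles[order(vapply(cycles, function(cy)
    paste(sort(keys[cy]), collapse = "|"), character(1L)))]
  used <- logical(ng)
  cycles <- Filter(function(cy) {
    if (any(used[cy])) return(FALSE)
    used[cy] <<- TRUE
    TRUE
  }, cycles)
  frames <- lapply(resList, function(r)
    tryCatch(baseFrame(r), error = function(e) NULL))
  tetrads <- lapply(cycles, function(cy)
    .assembleTetrad(cy, keys, gsel, resList, frames, planarityThreshold))
  ## orient normals along the strands' 5'->3' direction, then order the
  ## tetrads along the channel axis
  tetrads <- .orientTetradNormals(tetrads)
  ord <- order(vapply(tetrads, function(t)
    sum(colMeans(t@origins) * tetrads[[1L]]@normal), numeric(1L)))
  tetrads[ord]
}

.assembleTetrad <- function(cy, keys, gsel, resList, frames, threshold) {
  fr <- frames[cy]
  if (any(vapply(fr, is.null, logical(1L))))
    stop("base frame failed for tetrad ", paste(keys[cy], collapse = ","))
  zs <- lapply(fr, `[[`, "z")
  z0 <- zs[[1L]]
  zs <- lapply(zs, function(z) if (sum(z * z0) < 0) -z else z)
  normal <- unitv(Reduce(`+`, zs) / 4)
  origins <- do.call(rbind, lapply(fr, `[[`, "origin"))
  ## cycle-oriented pair parameters: common normal reference keeps buckle
  ## signs consistent around the Hoogsteen cycle
  pp <- matrix(NA_real_, 4L, 3L,
               dimnames = list(NULL, c("buckle", "propeller", "stagger")))
  for (k in seq_len(4L)) {
    i <- k
    j <- if (k == 4L) 1L else k + 1L
    c1i <- .atomXYZ(resList[[cy[i]]], "C1'")
    c1j <- .atomXYZ(resList[[cy[j]]], "C1'")
    bend <- .pairBend(zs[[i]], zs[[j]], c1j - c1i,
                      fr[[i]]$origin, fr[[j]]$origin)
    pp[k, ] <- c(bend$buckle, bend$propeller, abs(bend$stagger))
  }
  axes <- do.call(rbind, lapply(seq_len(4L), function(k) {
    c1 <- .atomXYZ(resList[[cy[k]]], "C1'")
    n9 <- .atomXYZ(resList[[cy[k]]], "N9")
    v <- n9 - c1
    v <- v - sum(v * normal) * normal
    unitv(v)
  }))
  tet <- new("Tetrad", residues = keys[cy], chains = gsel$chain[cy],
             seqNums = as.integer(gsel$resno[cy]), pairParams = pp,
             normal = normal, origins = origins, axes = axes,
             shape = "other")
  tet@shape <- classifyTetradShape(tet, threshold = threshold)
  tet
}

## Flip tetrad normals (and dependent buckle signs) so that they point
## along the strands' 5'->3' direction, inferred from covalently
## consecutive guanines (same chain, increasing residue number) appearing
## in different tetrads.
.orientTetradNormals <- function(tetrads) {
  if (length(tetrads) < 2L) return(tetrads)
  sense <- 0
  for (t1 in tetrads) for (t2 in tetrads) {
    for (k in seq_len(4L)) {
      hit <- which(t2@chains == t1@chains[k] &
                   t2@seqNums == t1@seqNums[k] + 1L)
      if (length(hit) == 1L) {
        d <- t2@origins[hit, ] - t1@origins[k, ]
        sense <- sense + sign(sum(d * t1@normal))
      }
    }
  }
  if (sense < 0) {
    tetrads <- lapply(tetrads, function(t) {
      t@normal <- -t@normal
      t@pairParams[, "buckle"] <- -t@pairParams[, "buckle"]
      t@shape <- classifyTetradShape(t)
      t
    })
  }
  tetrads
}

#' Classify tetrad shape
#'
#' Applies the planarity rules: a tetrad is \emph{planar} if all four
#' buckles and all four propeller twists are below the threshold in
#' magnitude; otherwise \emph{convex} if all four buckles are positive,
#' \emph{concave} if all four are negative, \emph{saddle} if the buckle
#' signs alternate around the cycle, and \emph{other} in every remaining
#' case. Evaluation order is exactly as listed (planar takes precedence),
#' making the classification total and deterministic.
#'
#' @param tetrad A \linkS4class{Tetrad}, or a 4 x 2+ matrix/data.frame with
#'   buckle and propeller columns.
#' @param threshold Planarity threshold, degrees (default 5).
#' @return One of "planar", "convex", "concave", "saddle", "other".
#' @export
classifyTetradShape <- function(tetrad, threshold = 5) {
  pp <- if (is(tetrad, "Tetrad")) tetrad@pairParams else as.matrix(tetrad)
  if (any(is.na(pp[, 1:2]))) stop("missing pair parameters")
  buckle <- pp[, 1L]
  propeller <- pp[, 2L]
  if (all(abs(buckle) < threshold) && all(abs(propeller) < threshold))
    return("planar")
  if (all(buckle > 0)) return("convex")
  if (all(buckle < 0)) return("concave")
  s <- sign(buckle)
  if (all(s == c(1, -1, 1, -1)) || all(s == c(-1, 1, -1, 1)))
    return("saddle")
  "other"
}

#' Stacking twist between consecutive tetrads
#'
#' Mean over the four strands of the rotation angle, about the mean tetrad
#' normal, from the first tetrad's in-plane reference axes (C1'->N9
#' projected onto the tetrad plane) to the second's. Guanines are paired
#' across the two tetrads by chain, taking the nearest residue numbers.
#' Pass the 5'-side tetrad first; the sign is then positive for
#' counter-clockwise stacking viewed from the 5' side looking along the
#' 5'-to-3' channel direction, matching the twist convention of
#' \code{\link{buildIdealG4}}.
#'
#' @param t1,t2 Consecutive \linkS4class{Tetrad} objects sharing their
#'   four strands, 5'-side tetrad first.
#' @return Twist in degrees in \eqn{(-180, 180]}.
#' @export
stackingTwist <- function(t1, t2) {
  stopifnot(is(t1, "Tetrad"), is(t2, "Tetrad"))
  nv <- unitv(t1@normal + t2@normal)
  sSum <- 0
  cSum <- 0
  nPaired <- 0L
  for (k in seq_len(4L)) {
    j <- which(t2@chains == t1@chains[k])
    if (!length(j)) next
    j <- j[which.min(abs(t2@seqNums[j] - t1@seqNums[k]))]
    v1 <- unitv(t1@axes[k, ] - sum(t1@axes[k, ] * nv) * nv)
    v2 <- unitv(t2@axes[j, ] - sum(t2@axes[j, ] * nv) * nv)
    th <- atan2(sum(vcross(v1, v2) * nv), sum(v1 * v2))
    sSum <- sSum + sin(th)
    cSum <- cSum + cos(th)
    nPaired <- nPaired + 1L
  }
  if (nPaired == 0L)
    stop("tetrads share no strands; cannot pair guanines")
  wrapAngle(rad2deg(atan2(sSum, cSum)))
}

#' Channel-ion spacing
#'
#' Projects all ions of the given element onto the principal axis of the
#' ion set, sorts them along it, and returns the consecutive Euclidean
#' distances. For a quadruplex channel this is the cation-grid spacing.
#'
#' @param structure An \linkS4class{AtomicStructure}.
#' @param ionElement Element symbol, default "K".
#' @param model Model number.
#' @return Numeric vector of consecutive distances, Angstroms (length 0
#'   when fewer than 2 ions are present).
#' @export
channelIonSpacing <- function(structure, ionElement = "K", model = 1L) {
  stopifnot(is(structure, "AtomicStructure"))
  a <- structure@atoms
  sel <- a$model == model & a$elesy == toupper(ionElement)
  xyz <- as.matrix(a[sel, c("x", "y", "z")])
  if (nrow(xyz) < 2L) return(numeric(0))
  ctr <- sweep(xyz, 2L, colMeans(xyz))
  axis1 <- svd(ctr)$v[, 1L]
  ord <- order(ctr %*% axis1)
  xyz <- xyz[ord, , drop = FALSE]
  unname(sqrt(rowSums((xyz[-1L, , drop = FALSE] -
                       xyz[-nrow(xyz), , drop = FALSE])^2)))
}
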