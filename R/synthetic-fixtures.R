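# Deterministic toy-structure, charge-system and score-set generators.
# Fixtures use alanine-like backbones with grafted side-chain atoms placed
# so that each planted residue's reactive atom sits exactly at its target
# coordinate; simpler than rotamer modelling and sufficient for everything
# downstream (parsing, parameterization, search, electrostatics).

#' Embed a pairwise-distance vector as 3D coordinates
#'
#' Classical multidimensional scaling of a canonical-pair-order distance
#' vector into n points in 3-space; errors if the distances are not
#' realizable in 3D to the requested accuracy. Published distance tables can
#' thereby serve as inputs to geometry fixtures.
#'
#' @param d canonical-pair-order distance vector, length n(n-1)/2.
#' @param n number of points.
#' @param tol maximum absolute reconstruction error tolerated (A).
#' @return n x 3 coordinate matrix.
#' @export
embedFromDistances <- function(d, n, tol = 1e-6) {
  stopifnot(length(d) == n * (n - 1) / 2)
  M <- matrix(0, n, n)
  pr <- canonicalPairs(n)
  for (k in seq_len(ncol(pr))) {
    M[pr[1, k], pr[2, k]] <- d[k]
    M[pr[2, k], pr[1, k]] <- d[k]
  }
  xyz <- tryCatch(suppressWarnings(stats::cmdscale(M, k = min(3L, n - 1L))),
                  error = function(e) NULL)
  if (is.null(xyz) || any(!is.finite(xyz)))
    abort("distances are not 3D-realizable (degenerate embedding)",
          "claspFixtureError")
  if (ncol(xyz) < 3L)
    xyz <- cbind(xyz, matrix(0, n, 3L - ncol(xyz)))
  err <- max(abs(pairwiseDistances(xyz) - d))
  if (err > tol)
    abort(sprintf("distances are not 3D-realizable (error %.3g A)", err),
          "claspFixtureError")
  xyz
}

# Side-chain heavy atoms per residue type, in graft order ending at atoms
# that can carry the reactive role; subset of the charge table entries.
.SIDECHAINS <- list(
  ALA = c("CB"), SER = c("CB", "OG"), THR = c("CG2", "CB", "OG1"),
  CYS = c("CB", "SG"), TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2",
                               "CZ", "OH"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  ARG = c("CB", "CG", "CD", "NE", "NH2", "CZ", "NH1"),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ASP = c("CB", "CG", "OD2", "OD1"), GLU = c("CB", "CG", "CD", "OE2",
                                             "OE1"),
  ASN = c("CB", "CG", "ND2", "OD1"), GLN = c("CB", "CG", "CD", "NE2",
                                             "OE1"),
  GLY = character(), LEU = c("CB", "CG", "CD1", "CD2"),
  VAL = c("CB", "CG1", "CG2"))

.pdbAtomLine <- function(serial, name, resid, chain, resno, xyz, occ = 1,
                         het = FALSE) {
  el <- substr(name, 1L, 1L)
  nm <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial, nm, resid, chain, resno,
          xyz[1], xyz[2], xyz[3], occ, 0, el)
}

# Place one residue so its reactive atom (last side-chain atom listed for
# the type) sits at `target`; backbone extends along `dir`.
.graftResidue <- function(serial, resid, chain, resno, target, dir) {
  dir <- dir / sqrt(sum(dir^2))
  ortho <- if (abs(dir[3]) < 0.9) c(-dir[2], dir[1], 0) else c(0, -dir[3],
                                                               dir[2])
  ortho <- ortho / sqrt(sum(ortho^2))
  side <- .SIDECHAINS[[resid]]
  nside <- length(side)
  ca <- target + dir * (1.5 * max(nside, 1L))
  lines <- character()
  pos <- list(N = ca + dir * 1.46 + ortho * 0.4,
              CA = ca,
              C = ca + dir * 1.2 - ortho * 1.0,
              O = ca + dir * 1.4 - ortho * 2.1)
  for (k in seq_along(side)) {
    frac <- (nside - k) / nside
    p <- target + dir * (1.5 * nside * frac)
    if (k < nside) p <- p + ortho * 0.45  # lift intermediates off the axis
    pos[[side[k]]] <- p
  }
  for (nm in names(pos)) {
    lines <- c(lines, .pdbAtomLine(serial, nm, resid, chain, resno,
                                   pos[[nm]]))
    serial <- serial + 1L
  }
  list(lines = lines, serial = serial)
}

#' Generate a toy PDB structure with planted motif sites
#'
#' Builds syntactically valid single-chain PDB text in which each requested
#' site's reactive atom lies exactly at its (optionally noise-perturbed)
#' target coordinate, plus optional decoy residues placed outside the
#' search cutoff. Byte-identical output for a fixed spec and seed.
#'
#' @param sites data.frame with columns `resid` (3-letter code) and `x`,
#'   `y`, `z` (target reactive-atom coordinates, A).
#' @param decoys number of decoy residues to scatter beyond `cutoff`.
#' @param noise coordinate noise sigma (A) applied to the targets.
#' @param seed integer seed; fixed seed implies identical bytes.
#' @param chain chain identifier.
#' @param cutoff decoys are placed farther than this from the site centroid.
#' @param decoyTypes residue types decoys are drawn from.
#' @return character vector of PDB lines.
#' @export
makeToyStructure <- function(sites, decoys = 0L, noise = 0, seed = 1L,
                             chain = "A", cutoff = 15,
                             decoyTypes = c("SER", "LYS", "HIS", "ASP",
                                            "ALA", "LEU", "THR", "ARG")) {
  stopifnot(noise >= 0, all(sites$resid %in% names(.SIDECHAINS)))
  withSeed(seed, {
    n <- nrow(sites)
    tgt <- as.matrix(sites[, c("x", "y", "z")])
    if (noise > 0)
      tgt <- tgt + matrix(stats::rnorm(3 * n, 0, noise), n, 3)
    centroid <- colMeans(tgt)
    lines <- character()
    serial <- 1L
    for (i in seq_len(n)) {
      away <- tgt[i, ] - centroid
      if (sum(away^2) < 1e-8) away <- c(0, 0, 1)
      g <- .graftResidue(serial, sites$resid[i], chain, 10L + 10L * (i - 1L),
                         tgt[i, ], away)
      lines <- c(lines, g$lines)
      serial <- g$serial
    }
    if (decoys > 0) {
      placed <- tgt
      for (j in seq_len(decoys)) {
        repeat {
          u <- stats::rnorm(3)
          u <- u / sqrt(sum(u^2))
          r <- cutoff + 5 + stats::runif(1, 0, 15)
          p <- centroid + u * r
          if (!nrow(placed) ||
              min(sqrt(rowSums(sweep(placed, 2, p)^2))) > 4) break
        }
        placed <- rbind(placed, p)
        rt <- sample(decoyTypes, 1L)
        g <- .graftResidue(serial, rt, chain, 500L + j, p,
                           p - centroid)
        lines <- c(lines, g$lines)
        serial <- g$serial
      }
    }
    coords <- do.call(rbind, lapply(lines, function(l)
      as.numeric(c(substr(l, 31, 38), substr(l, 39, 46),
                   substr(l, 47, 54)))))
    dm <- as.matrix(stats::dist(coords))
    diag(dm) <- Inf
    if (min(dm) < 1)
      abort(sprintf("generated atoms overlap (min separation %.2f A)",
                    min(dm)), "claspFixtureError")
    c(lines, "TER", "END")
  })
}

#' Point-charge fixtures for the solver
#'
#' Parameterized point-charge systems used as electrostatics oracles:
#' `monopole` is one +1 e charge, `dipole` two opposite unit charges 4 A
#' apart (its midplane potential vanishes by symmetry), `random` is a seeded
#' cloud of charges in \[-1, 1\] e.
#'
#' @param kind one of "monopole", "dipole", "random".
#' @param seed integer seed (used by "random").
#' @param n number of atoms for "random".
#' @return data.frame usable by [solvePotential()] (x, y, z, charge,
#'   radius).
#' @export
makeChargeFixture <- function(kind = c("monopole", "dipole", "random"),
                              seed = 1L, n = 20L) {
  kind <- match.arg(kind)
  base <- function(x, y, z, q)
    data.frame(name = "Q", resid = "QPT", chain = "A",
               resno = seq_along(x), x = x, y = y, z = z,
               charge = q, radius = 1.5, stringsAsFactors = FALSE)
  switch(kind,
    monopole = base(0, 0, 0, 1),
    dipole = base(c(-2, 2), c(0, 0), c(0, 0), c(1, -1)),
    random = withSeed(seed, {
      base(stats::runif(n, -4, 4), stats::runif(n, -4, 4),
           stats::runif(n, -4, 4), stats::runif(n, -1, 1))
    }))
}

#' Labelled synthetic score set
#'
#' Emulates the discrimination task the PD filter addresses: all items are
#' spatial matches to a reference motif, but positives ("family members")
#' carry planted geometry close to the reference and PDs drawn tightly
#' around a family PD profile, while negatives ("geometric decoys") carry
#' comparable geometry with PDs from a broad uninformative distribution.
#' The default profile mirrors the class A-D beta-lactamase family
#' statistics (per-pair means of order +/-100-250 kT/e with standard
#' deviations of order 10-25 kT/e).
#'
#' @param nPos,nNeg item counts (>= 1).
#' @param seed integer seed.
#' @param profileMean,profileSd family PD profile (kT/e), canonical pair
#'   order.
#' @param dRef reference distances (A) of the emulated 4-residue motif.
#' @param sigmaPos,sigmaNeg coordinate noise (A) applied to the planted
#'   geometry of positives and negatives.
#' @param negRange half-width (kT/e) of the uniform decoy PD distribution.
#' @return list: `positive` (logical), `deltaD`, `pQ` (item x pair
#'   matrices), `dRef`, `pRef`, `refXYZ`.
#' @export
makeLabeledScoreset <- function(nPos = 5L, nNeg = 45L, seed = 1L,
                                profileMean = c(-201.7, 22.3, -250.3,
                                                224.0, -48.6, -272.7),
                                profileSd = c(7.8, 15.3, 9.0, 8.9, 15.7,
                                              24.0),
                                dRef = c(3.1, 7.3, 8.4, 7.5, 6.8, 6.4),
                                sigmaPos = 0.15, sigmaNeg = 0.25,
                                negRange = 300) {
  stopifnot(nPos >= 1, nNeg >= 1)
  n <- as.integer(round((1 + sqrt(1 + 8 * length(dRef))) / 2))
  refXYZ <- embedFromDistances(dRef, n, tol = 0.05)
  dRefExact <- pairwiseDistances(refXYZ)
  withSeed(seed, {
    total <- nPos + nNeg
    positive <- c(rep(TRUE, nPos), rep(FALSE, nNeg))
    p <- length(dRef)
    deltaD <- matrix(0, total, p)
    pQ <- matrix(0, total, p)
    for (t in seq_len(total)) {
      sg <- if (positive[t]) sigmaPos else sigmaNeg
      xyz <- refXYZ + matrix(stats::rnorm(3 * n, 0, sg), n, 3)
      deltaD[t, ] <- pairwiseDistances(xyz) - dRefExact
      pQ[t, ] <- if (positive[t])
        stats::rnorm(p, profileMean, profileSd)
      else stats::runif(p, -negRange, negRange)
    }
    list(positive = positive, deltaD = deltaD, pQ = pQ, dRef = dRefExact,
         pRef = profileMean, refXYZ = refXYZ)
  })
}

#' Score a labelled score set
#'
#' Applies the CLASP score to every item of a [makeLabeledScoreset()]
#' result, returning one score per item.
#'
#' @param set a labelled score set.
#' @param wd,wp weights (set `wp = 0` for distance-only scoring).
#' @param epsZero,pFloor PD-term thresholds, see [pdTerm()].
#' @return numeric score vector.
#' @export
scoreLabeledSet <- function(set, wd = 1, wp = 1, epsZero = 25,
                            pFloor = 50) {
  vapply(seq_along(set$positive), function(t) {
    D <- distanceTerm(abs(set$deltaD[t, ]), set$dRef)
    P <- if (wp > 0) pdTerm(set$pQ[t, ], set$pRef, epsZero, pFloor) else 0
    wd * D + wp * P
  }, 0)
}

#' Reference fixture geometries from published distance tables
#'
#' Site tables for the serine-protease catalytic triad and a class A
#' beta-lactamase-like four-residue site, with reactive-atom coordinates
#' realizing the published pairwise distances (trypsin 1A0J: Ser-Asp 7.8,
#' His-Asp 5.5, Ser-His 3.3 A; alkaline phosphatase 1K7H predicted site:
#' 7.7, 3.2, 4.6 A). Site order is (Ser, His, Asp), so the canonical pairs
#' are (S,H), (S,D), (H,D). The beta-lactamase geometry is a synthetic
#' stand-in with realistic distances (no published full distance set).
#'
#' @param which one of "trypsin-1a0j", "sap-1k7h", "blactamase".
#' @return data.frame of sites (resid, x, y, z) for [makeToyStructure()].
#' @export
fixtureSites <- function(which = c("trypsin-1a0j", "sap-1k7h",
                                   "blactamase")) {
  which <- match.arg(which)
  if (which == "blactamase") {
    d <- c(3.1, 7.3, 8.4, 7.5, 6.8, 6.4)  # S70/K73, S70/S130, S70/K234, ...
    xyz <- embedFromDistances(d, 4L, tol = 1e-4)
    return(data.frame(resid = c("SER", "LYS", "SER", "LYS"),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE))
  }
  d <- if (which == "trypsin-1a0j") c(3.3, 7.8, 5.5) else c(4.6, 7.7, 3.2)
  xyz <- embedFromDistances(d, 3L, tol = 1e-6)
  data.frame(resid = c("SER", "HIS", "ASP"),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}
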