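#' Solve the electrostatic potential on a cubic lattice
#'
#' Finite-difference solution of the variable-dielectric Poisson equation
#' (the zero-ionic-strength limit of the linearized Poisson-Boltzmann
#' equation) for a parameterized structure. Node dielectric is the solute
#' value inside the union of atom spheres inflated by the probe radius and
#' the solvent value elsewhere, with harmonic averaging on cell faces.
#' Charges are spread to the eight surrounding nodes by trilinear weights.
#' The Dirichlet boundary is the Coulomb superposition in pure solvent.
#' The interior is solved by red-black successive over-relaxation.
#'
#' @param s parameterized [ClaspStructure-class] (charges and radii
#'   assigned), or a data.frame of atoms with columns x, y, z, charge,
#'   radius.
#' @param params a [GridParams-class].
#' @param uniformDielectric use the solvent dielectric everywhere (used by
#'   the analytic-Coulomb validation fixtures).
#' @param boundaryOffset constant (kT/e) added to every boundary value;
#'   potential differences are invariant to it.
#' @return a [PotentialGrid-class] with potentials in kT/e.
#' @export
solvePotential <- function(s, params = new("GridParams"),
                           uniformDielectric = FALSE, boundaryOffset = 0) {
  a <- if (is(s, "ClaspStructure")) atoms(s) else s
  if (!nrow(a)) abort("no atoms to solve for", "claspSolverError")
  if (!all(c("charge", "radius") %in% names(a)))
    abort("atoms lack charge/radius; run assignParameters first",
          "claspParameterizationError")
  validObject(params)

  xyz <- as.matrix(a[, c("x", "y", "z")])
  lo <- apply(xyz, 2L, min) - params@padding
  hi <- apply(xyz, 2L, max) + params@padding
  h <- params@h
  if (is.na(h)) {
    for (cand in seq(0.4, 0.6, by = 0.05)) {
      if (prod(floor((hi - lo) / cand) + 2) <= params@maxNodes) {
        h <- cand
        break
      }
    }
    if (is.na(h)) h <- 0.6
  }
  dims <- as.integer(floor((hi - lo) / h) + 2L)
  origin <- as.numeric(lo)

  eps <- if (uniformDielectric ||
             isTRUE(all.equal(params@soluteEps, params@solventEps))) {
    array(params@solventEps, dims)
  } else {
    .markDielectric(dims, origin, h, xyz, a$radius, params@probeRadius,
                    params@soluteEps, params@solventEps)
  }

  C <- coulombConstant(params@tempK)
  phi <- .coulombBoundary(dims, origin, h, xyz, a$charge, C,
                          params@solventEps)
  if (boundaryOffset != 0) {
    bmask <- array(FALSE, dims)
    bmask[c(1, dims[1]), , ] <- TRUE
    bmask[, c(1, dims[2]), ] <- TRUE
    bmask[, , c(1, dims[3])] <- TRUE
    phi[bmask] <- phi[bmask] + boundaryOffset
  }

  # trilinear charge spreading; source term 4 pi C q / h per node
  src <- array(0, dims)
  for (t in seq_len(nrow(a))) {
    g <- (xyz[t, ] - origin) / h
    i0 <- pmin(pmax(floor(g), 0), dims - 2)
    f <- g - i0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) f[1] else 1 - f[1]) *
           (if (dy) f[2] else 1 - f[2]) *
           (if (dz) f[3] else 1 - f[3])
      ii <- i0 + c(dx, dy, dz) + 1
      src[ii[1], ii[2], ii[3]] <- src[ii[1], ii[2], ii[3]] +
        4 * pi * C * a$charge[t] * w / h
    }
  }

  fit <- .sorSolve(phi, eps, src, dims, params@omega, params@tol,
                   params@maxIter)
  if (!fit$converged)
    abort(sprintf("solver did not converge in %d iterations (residual %.3g)",
                  fit$iterations, fit$residual), "claspConvergenceError")
  new("PotentialGrid", origin = origin, h = h, dims = dims,
      phi = fit$phi, eps = eps)
}

#' Interpolate the potential at a point
#'
#' Trilinear interpolation of the eight surrounding grid nodes.
#'
#' @param grid a [PotentialGrid-class].
#' @param point numeric length-3 coordinate (A), strictly inside the grid.
#' @return potential in kT/e.
#' @export
potentialAt <- function(grid, point) {
  g <- (as.numeric(point) - grid@origin) / grid@h
  if (any(g < 0) || any(g > grid@dims - 1))
    abort(sprintf("point (%.2f, %.2f, %.2f) lies outside the grid",
                  point[1], point[2], point[3]), "claspBoundsError")
  i0 <- pmin(pmax(floor(g), 0), grid@dims - 2)
  f <- g - i0
  v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[1] else 1 - f[1]) *
         (if (dy) f[2] else 1 - f[2]) *
         (if (dz) f[3] else 1 - f[3])
    if (w > 0) {
      ii <- i0 + c(dx, dy, dz) + 1
      v <- v + w * grid@phi[ii[1], ii[2], ii[3]]
    }
  }
  v
}

#' Potential difference between two reactive atoms
#'
#' PD(a, b) = phi(a) - phi(b) on the same solved grid, with the atoms taken
#' in motif order; exactly antisymmetric under argument exchange.
#'
#' @param grid a [PotentialGrid-class].
#' @param a,b atom rows (one-row data.frames with x, y, z) or length-3
#'   coordinates.
#' @return PD in kT/e.
#' @export
pairPD <- function(grid, a, b) {
  pa <- if (is.data.frame(a)) c(a$x, a$y, a$z) else as.numeric(a)
  pb <- if (is.data.frame(b)) c(b$x, b$y, b$z) else as.numeric(b)
  potentialAt(grid, pa) - potentialAt(grid, pb)
}

#' Shift an intrinsic pKa by a charging energy
#'
#' The charging free energy (kT units) of the ionized form is converted to
#' pKa units by dividing by ln(10) = 2.303 and added with the sign such that
#' destabilizing the deprotonated form of an acid raises its pKa, while
#' destabilizing the protonated form of a base lowers it.
#'
#' @param intrinsicPka model-compound pKa.
#' @param chargingEnergy energy in kT destabilizing the charged form.
#' @param siteIsAcid logical; TRUE for Asp/Glu-like sites, FALSE for
#'   Lys/Arg/His-like sites.
#' @return shifted pKa.
#' @export
estimatePka <- function(intrinsicPka, chargingEnergy, siteIsAcid = TRUE) {
  stopifnot(is.finite(intrinsicPka), is.finite(chargingEnergy))
  shift <- chargingEnergy / log(10)
  if (siteIsAcid) intrinsicPka + shift else intrinsicPka - shift
}

#' OpenDX scalar grid I/O
#'
#' Reads and writes the OpenDX format used by common Poisson-Boltzmann
#' solvers for potential maps (data stored z-fastest, three values per
#' line).
#'
#' @param grid a [PotentialGrid-class].
#' @param path output file.
#' @export
writeDX <- function(grid, path) {
  d <- grid@dims
  n <- prod(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar grid written by clasp (potential in kT/e)",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6e %.6e %.6e", grid@origin[1], grid@origin[2],
            grid@origin[3]),
    sprintf("delta %.6e 0.000000e+00 0.000000e+00", grid@h),
    sprintf("delta 0.000000e+00 %.6e 0.000000e+00", grid@h),
    sprintf("delta 0.000000e+00 0.000000e+00 %.6e", grid@h),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            n)), con)
  vals <- as.vector(aperm(grid@phi, c(3, 2, 1)))  # z fastest in file
  pad <- c(vals, rep(NA_real_, (3 - n %% 3) %% 3))
  m <- matrix(pad, ncol = 3, byrow = TRUE)
  lines <- apply(m, 1L, function(r)
    paste(sprintf("%.6e", r[!is.na(r)]), collapse = " "))
  writeLines(lines, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "potential" class field'), con)
  invisible(path)
}

#' @rdname writeDX
#' @return `readDX`: a [PotentialGrid-class] (dielectric map not stored).
#' @export
readDX <- function(path) {
  lines <- readLines(path)
  cts <- lines[grep("gridpositions counts", lines)[1]]
  d <- as.integer(strsplit(sub(".*counts ", "", cts), " ")[[1]])
  org <- as.numeric(strsplit(sub("^origin ", "",
                                 lines[grep("^origin", lines)[1]]),
                             " ")[[1]])
  deltas <- lines[grep("^delta", lines)]
  h <- max(as.numeric(strsplit(sub("^delta ", "", deltas[1]), " ")[[1]]))
  dstart <- grep("data follows", lines)[1] + 1L
  dend <- grep("^attribute", lines)[1] - 1L
  vals <- as.numeric(unlist(strsplit(trimws(lines[dstart:dend]),
                                     "[[:space:]]+")))
  phi <- aperm(array(vals, rev(d)), c(3, 2, 1))
  new("PotentialGrid", origin = org, h = h, dims = d, phi = phi, eps = NULL)
}
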