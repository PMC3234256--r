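#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib clasp, .registration = TRUE
NULL

#' Protein structure with resolved atom records
#'
#' Container for a parsed single-model protein structure. Atom records are
#' stored as a data.frame with one row per retained atom (first model only,
#' one alternate location per atom position). HETATM records are kept and
#' flagged so that metal ions can take part in electrostatics while organic
#' ligands can be rejected at parameterization time.
#'
#' @slot atoms data.frame with columns `eleno`, `name`, `altloc`, `resid`
#'   (3-letter code), `chain`, `resno`, `icode`, `x`, `y`, `z`, `occ`, `het`
#'   (logical), `element`, and (after [assignParameters()]) `charge` (e) and
#'   `radius` (Angstrom).
#' @slot sourceId character scalar, e.g. a PDB accession or fixture label.
#' @slot model integer scalar; index of the retained model (always the first).
#' @export
setClass("ClaspStructure",
  representation(atoms = "data.frame", sourceId = "character",
                 model = "integer"),
  prototype(sourceId = "unknown", model = 1L))

setValidity("ClaspStructure", function(object) {
  a <- object@atoms
  need <- c("eleno", "name", "altloc", "resid", "chain", "resno", "icode",
            "x", "y", "z", "occ", "het", "element")
  if (!all(need %in% names(a)))
    return(paste("atoms lacks columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a)) {
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      return("non-finite atom coordinates")
    if (any(a$occ < 0 | a$occ > 1, na.rm = TRUE))
      return("occupancy outside [0, 1]")
  }
  TRUE
})

#' Parameters of the finite-difference Poisson-Boltzmann solve
#'
#' Defaults follow the standard continuum-electrostatics setup for active-site
#' potential work: solute dielectric 2, solvent dielectric 78, solvent probe
#' 1.4 Angstrom, 298 K, zero ionic strength. Potentials are reported in kT/e.
#'
#' @slot h grid spacing in Angstrom; `NA` selects the finest spacing on a
#'   0.05 A ladder within \[0.4, 0.6\] A whose node count fits `maxNodes`.
#' @slot soluteEps,solventEps dimensionless dielectric constants.
#' @slot probeRadius solvent probe radius (A) used to inflate atom spheres
#'   when painting the solute dielectric region.
#' @slot tempK temperature in kelvin (enters the kT/e unit conversion).
#' @slot ionicStrength mol/L; only the zero-ionic-strength (pure Poisson)
#'   regime is solved, the value is accepted for interface compatibility.
#' @slot padding A of empty space beyond the molecular extent on each side.
#' @slot tol relative residual convergence criterion.
#' @slot maxIter successive-over-relaxation iteration cap.
#' @slot omega SOR relaxation factor.
#' @slot maxNodes cap on total grid nodes used by automatic `h` selection.
#' @export
setClass("GridParams",
  representation(h = "numeric", soluteEps = "numeric", solventEps = "numeric",
                 probeRadius = "numeric", tempK = "numeric",
                 ionicStrength = "numeric", padding = "numeric",
                 tol = "numeric", maxIter = "integer", omega = "numeric",
                 maxNodes = "numeric"),
  prototype(h = NA_real_, soluteEps = 2, solventEps = 78, probeRadius = 1.4,
            tempK = 298, ionicStrength = 0, padding = 10, tol = 1e-6,
            maxIter = 20000L, omega = 1.9, maxNodes = 1.5e6))

setValidity("GridParams", function(object) {
  if (!is.na(object@h) && (object@h < 0.3 || object@h > 1.0))
    return("grid spacing h must lie in [0.3, 1.0] Angstrom")
  if (object@soluteEps <= 0 || object@solventEps <= 0)
    return("dielectric constants must be positive")
  if (object@padding <= object@probeRadius)
    return("padding must exceed the probe radius")
  if (object@tol <= 0) return("tol must be positive")
  if (object@omega <= 0 || object@omega >= 2)
    return("omega must lie in (0, 2)")
  TRUE
})

#' Electrostatic potential on a cubic lattice
#'
#' @slot origin A coordinates of node (1, 1, 1).
#' @slot h grid spacing (A).
#' @slot dims integer node counts along x, y, z.
#' @slot phi 3D array of potentials in kT/e.
#' @slot eps 3D array of node dielectric values, or NULL when the medium is
#'   uniform.
#' @export
setClass("PotentialGrid",
  representation(origin = "numeric", h = "numeric", dims = "integer",
                 phi = "array", eps = "ANY"))

setValidity("PotentialGrid", function(object) {
  if (length(object@origin) != 3L) return("origin must have length 3")
  if (length(object@dims) != 3L) return("dims must have length 3")
  if (!all(dim(object@phi) == object@dims))
    return("phi dimensions disagree with dims")
  if (!all(is.finite(object@phi))) return("non-finite potential values")
  TRUE
})

#' Active-site motif: ordered residue-group sites with reference vectors
#'
#' A motif carries 3-5 ordered sites taken from a reference structure. Each
#' site names a stereochemical group (the residue types allowed to fill it),
#' the reference residue, and its reactive atom. Reference pairwise
#' reactive-atom distances (`dRef`, A) and potential differences (`pRef`,
#' kT/e) are stored in the canonical pair order: lexicographic (i, j) with
#' i < j over site indices; each PD is phi(site i) - phi(site j).
#'
#' @slot sourceId reference structure identifier.
#' @slot sites data.frame with columns `label` (group label), `chain`,
#'   `resno`, `icode`, `resid`, `atom` (reactive atom name).
#' @slot dRef numeric vector, length n(n-1)/2.
#' @slot pRef numeric vector, same length and pair order (may be all NA for a
#'   purely geometric motif).
#' @export
setClass("Motif",
  representation(sourceId = "character", sites = "data.frame",
                 dRef = "numeric", pRef = "numeric"))

setValidity("Motif", function(object) {
  n <- nrow(object@sites)
  if (!n %in% 3:5) return("a motif must have 3, 4 or 5 sites")
  p <- n * (n - 1L) / 2L
  if (length(object@dRef) != p)
    return(sprintf("dRef must have length %d", p))
  if (length(object@pRef) != p)
    return(sprintf("pRef must have length %d", p))
  if (any(!is.na(object@dRef) & object@dRef <= 0))
    return("reference distances must be positive")
  need <- c("label", "chain", "resno", "icode", "resid", "atom")
  if (!all(need %in% names(object@sites)))
    return(paste("sites lacks columns:",
                 paste(setdiff(need, names(object@sites)), collapse = ", ")))
  TRUE
})

#' Set of spatially congruent candidate matches
#'
#' One row per candidate residue tuple found in a query structure. Matrices
#' are indexed \[match, site\] or \[match, pair\] with pairs in canonical
#' order.
#'
#' @slot motifId identifier of the probed motif.
#' @slot residues character matrix of residue keys ("chain:RES:resno").
#' @slot resTypes character matrix of 3-letter residue types.
#' @slot coords numeric matrix, 3 columns per site (reactive-atom x, y, z).
#' @slot dQ numeric matrix of query pairwise distances (A).
#' @slot deltaD numeric matrix of signed deviations dQ - dRef (A).
#' @slot dRef reference distances the deviations refer to.
#' @export
setClass("MatchSet",
  representation(motifId = "character", residues = "matrix",
                 resTypes = "matrix", coords = "matrix", dQ = "matrix",
                 deltaD = "matrix", dRef = "numeric"))

setValidity("MatchSet", function(object) {
  m <- nrow(object@residues)
  if (nrow(object@dQ) != m || nrow(object@deltaD) != m ||
      nrow(object@coords) != m)
    return("match matrices disagree in row count")
  n <- ncol(object@residues)
  p <- n * (n - 1L) / 2L
  if (m > 0 && (ncol(object@dQ) != p || ncol(object@deltaD) != p))
    return("pair matrices disagree with site count")
  TRUE
})

#' Matches scored by combined spatial and electrostatic deviation
#'
#' Extends [MatchSet-class] with per-match query potential differences and
#' the CLASP score decomposition S = w_d * D + w_p * P, where D sums
#' reference-normalized absolute distance deviations and P sums
#' reference-normalized absolute PD deviations (with a both-near-zero ignore
#' band and a denominator floor). Lower scores are better; the reference
#' structure itself scores exactly zero.
#'
#' @slot pQ numeric matrix of query potential differences (kT/e).
#' @slot pRef reference PDs used for the P term.
#' @slot D,P,S numeric vectors: distance term, PD term, combined score.
#' @slot weights numeric c(wd, wp).
#' @slot thresholds numeric c(epsZero, pFloor) in kT/e.
#' @export
setClass("ScoredMatches", contains = "MatchSet",
  representation(pQ = "matrix", pRef = "numeric", D = "numeric",
                 P = "numeric", S = "numeric", weights = "numeric",
                 thresholds = "numeric"))

setValidity("ScoredMatches", function(object) {
  m <- nrow(object@residues)
  if (length(object@S) != m || length(object@D) != m ||
      length(object@P) != m)
    return("score vectors disagree with match count")
  if (any(object@S < -1e-12, na.rm = TRUE))
    return("scores must be non-negative")
  TRUE
})
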