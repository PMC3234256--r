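#' Out-of-process Poisson-Boltzmann backend
#'
#' Contract for delegating the potential calculation to the standard
#' external pipeline (PDB2PQR for charge assignment, APBS for the solve),
#' used as the fidelity reference when those executables are installed. The
#' internal solver remains fully usable when they are not.
#'
#' @param params a [GridParams-class].
#' @param pqrPath path to the PQR input written for the solver.
#' @param dxPath path the solver should write the potential map to.
#' @param dims,origin grid node counts and lower corner (A).
#' @return `apbsInputText`: character vector, the generated solver input.
#' @export
apbsInputText <- function(params, pqrPath, dxPath, dims, origin) {
  lens <- (dims - 1) * if (is.na(params@h)) 0.5 else params@h
  ctr <- origin + lens / 2
  c("read", sprintf("    mol pqr %s", pqrPath), "end",
    "elec", "    mg-manual",
    sprintf("    dime %d %d %d", dims[1], dims[2], dims[3]),
    sprintf("    grid %.4f %.4f %.4f",
            lens[1] / (dims[1] - 1), lens[2] / (dims[2] - 1),
            lens[3] / (dims[3] - 1)),
    sprintf("    gcent %.3f %.3f %.3f", ctr[1], ctr[2], ctr[3]),
    "    mol 1", "    lpbe", "    bcfl sdh",
    sprintf("    pdie %.3f", params@soluteEps),
    sprintf("    sdie %.3f", params@solventEps),
    sprintf("    srad %.3f", params@probeRadius),
    sprintf("    temp %.2f", params@tempK),
    "    chgm spl2", "    srfm smol", "    swin 0.3", "    sdens 10.0",
    "    calcenergy no", "    calcforce no",
    sprintf("    write pot dx %s", sub("\\.dx$", "", dxPath)),
    "end", "quit")
}

#' @rdname apbsInputText
#' @return `externalBackendAvailable`: TRUE when both `pdb2pqr` and `apbs`
#'   are on the PATH.
#' @export
externalBackendAvailable <- function() {
  nzchar(Sys.which("pdb2pqr")) && nzchar(Sys.which("apbs"))
}

#' @rdname apbsInputText
#' @param pdbText PDB text (or path) of the query structure.
#' @param workDir scratch directory for intermediate files.
#' @return `externalGrid`: a [PotentialGrid-class] in kT/e.
#' @export
externalGrid <- function(pdbText, params = new("GridParams"),
                         workDir = tempfile("apbs")) {
  if (!externalBackendAvailable())
    abort("external backend unavailable: pdb2pqr and/or apbs not on PATH",
          "claspBackendUnavailableError")
  dir.create(workDir, recursive = TRUE, showWarnings = FALSE)
  pdb <- file.path(workDir, "query.pdb")
  if (length(pdbText) == 1L && !grepl("\n", pdbText) && file.exists(pdbText))
    file.copy(pdbText, pdb)
  else writeLines(pdbText, pdb)
  pqr <- file.path(workDir, "query.pqr")
  log1 <- system2("pdb2pqr", c("--ff=PARSE", pdb, pqr),
                  stdout = TRUE, stderr = TRUE)
  if (!file.exists(pqr))
    abort(paste("pdb2pqr failed:", paste(utils::tail(log1, 5),
                collapse = " / ")), "claspBackendError")
  s <- readPQR(pqr)
  xyz <- as.matrix(atoms(s)[, c("x", "y", "z")])
  h <- if (is.na(params@h)) 0.5 else params@h
  lo <- apply(xyz, 2, min) - params@padding
  hi <- apply(xyz, 2, max) + params@padding
  dims <- as.integer(floor((hi - lo) / h) + 2L)
  dx <- file.path(workDir, "pot.dx")
  inp <- file.path(workDir, "apbs.in")
  writeLines(apbsInputText(params, pqr, dx, dims, lo), inp)
  log2 <- system2("apbs", inp, stdout = TRUE, stderr = TRUE)
  if (!file.exists(dx))
    abort(paste("apbs failed:", paste(utils::tail(log2, 5),
                collapse = " / ")), "claspBackendError")
  readDX(dx)
}
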