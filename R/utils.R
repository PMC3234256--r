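# Canonical pair order over n motif sites: lexicographic (i, j), i < j.
# All dRef/pRef/dQ/deltaD vectors follow this order; PDs are phi(i) - phi(j).
canonicalPairs <- function(n) {
  stopifnot(n >= 2)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  t(idx)  # 2 x p matrix: rows i, j
}

# Index of pair (i, j), i < j, inside the canonical order for n sites.
pairIndex <- function(i, j, n) {
  if (i > j) { k <- i; i <- j; j <- k }
  (i - 1L) * n - i * (i - 1L) / 2L + (j - i)
}

residueKey <- function(chain, resid, resno, icode = "") {
  sprintf("%s:%s:%d%s", chain, resid, as.integer(resno), trimws(icode))
}

pairwiseDistances <- function(xyz) {
  # xyz: n x 3 matrix -> canonical-order distance vector
  n <- nrow(xyz)
  pr <- canonicalPairs(n)
  sqrt(colSums((t(xyz[pr[1, ], , drop = FALSE]) -
                t(xyz[pr[2, ], , drop = FALSE]))^2))
}

# Run code with a temporary RNG state so generators are pure in (spec, seed).
withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Coulomb constant e^2 / (4 pi eps0 kT) expressed in Angstrom, so that
# phi [kT/e] = coulombConstant(T) * q [e] / (eps * r [A]).  Computed from
# CODATA physical constants rather than a hard-coded approximation.
coulombConstant <- function(tempK = 298) {
  e <- 1.602176634e-19       # C
  eps0 <- 8.8541878128e-12   # F/m
  kB <- 1.380649e-23         # J/K
  e^2 / (4 * pi * eps0 * kB * tempK) * 1e10
}

# Deterministic ordering of scored matches: S, then D, then residue keys.
orderMatches <- function(scored) {
  keys <- apply(scored@residues, 1L, paste, collapse = " ")
  order(scored@S, scored@D, keys)
}

abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "claspError")))
}
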