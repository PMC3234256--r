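# Shared fixture builders. Expensive objects (parsed structures, solved
# grids, motifs) are memoized per session.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# Solver parameters kept modest for fixture-sized systems.
testGridParams <- function(h = 0.6, padding = 8)
  new("GridParams", h = h, padding = padding)

fixtureStructure <- function(kind = c("trypsin-1a0j", "sap-1k7h",
                                      "blactamase"),
                             decoys = 0L, seed = 11L) {
  kind <- match.arg(kind)
  memo(sprintf("struct-%s-%d-%d", kind, decoys, seed), {
    pdb <- makeToyStructure(fixtureSites(kind), decoys = decoys,
                            seed = seed)
    readPDB(pdb, sourceId = kind)
  })
}

fixtureGrid <- function(kind, decoys = 0L, seed = 11L) {
  memo(sprintf("grid-%s-%d-%d", kind, decoys, seed), {
    s <- assignParameters(fixtureStructure(kind, decoys, seed))
    solvePotential(s, testGridParams())
  })
}

fixtureMotif <- function(kind, withPD = FALSE, decoys = 0L, seed = 11L) {
  memo(sprintf("motif-%s-%d-%d-%d", kind, withPD, decoys, seed), {
    s <- fixtureStructure(kind, decoys, seed)
    resnos <- unique(atoms(s)$resno)
    resnos <- sort(resnos[resnos < 500])  # planted sites only
    sel <- sprintf("A:%d", resnos)
    labels <- switch(kind,
      "blactamase" = c("Sergrp", "Lysgrp", "Sergrp", "Lysgrp"),
      c("Sergrp", "Hisgrp", "Aspgrp"))
    buildMotif(s, sel, labels = labels,
               grid = if (withPD) fixtureGrid(kind, decoys, seed))
  })
}

# Random small structure + a motif drawn from its own residues, for the
# search-oracle equivalence property.
randomSearchCase <- function(seed) {
  set.seed(seed)
  repeat {
    nres <- sample(5:7, 1L)
    types <- c("SER", "HIS", "ASP",
               sample(c("SER", "HIS", "ASP", "LYS", "ALA", "THR"),
                      nres - 3L, replace = TRUE))
    sites <- data.frame(resid = types,
                        x = runif(nres, 0, 14), y = runif(nres, 0, 14),
                        z = runif(nres, 0, 14))
    if (min(dist(sites[, c("x", "y", "z")])) < 3.5) next
    txt <- tryCatch(makeToyStructure(sites, seed = seed),
                    error = function(e) NULL)
    if (is.null(txt)) next
    s <- readPDB(txt, sourceId = sprintf("rand-%d", seed))
    m <- tryCatch(
      buildMotif(s, sprintf("A:%d", 10L * (seq_len(3L) - 1L) + 10L),
                 labels = c("Sergrp", "Hisgrp", "Aspgrp")),
      error = function(e) NULL)
    if (is.null(m)) next
    return(list(s = s, m = m))
  }
}

# Concatenate two structures into one chain with renumbered residues.
mergeStructures <- function(s1, s2, offset = 400L) {
  a1 <- atoms(s1)
  a2 <- atoms(s2)
  a2$resno <- a2$resno + offset
  a2$eleno <- a2$eleno + max(a1$eleno)
  new("ClaspStructure", atoms = rbind(a1, a2), sourceId = s1@sourceId,
      model = 1L)
}

# Apply a rigid motion (or reflection) to all atom coordinates.
transformStructure <- function(s, R = diag(3), t = c(0, 0, 0)) {
  a <- atoms(s)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + t[1]
  a$y <- xyz[, 2] + t[2]
  a$z <- xyz[, 3] + t[3]
  new("ClaspStructure", atoms = a, sourceId = s@sourceId, model = s@model)
}

rotationMatrix <- function(axis = c(1, 1, 0), angle = 1.1) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

matchKeySet <- function(ms) {
  if (matchCount(ms) == 0L) return(character())
  sort(apply(matchResidues(ms), 1L, paste, collapse = " "))
}

# Printed reference values used as inputs to worked-example fixtures:
# class A beta-lactamase PD row (2G2U) and its class C counterpart (2QZ6),
# canonical pair order over (S70, K73, S130, K234); the lysozyme 2EQL
# deviation sets; serine-protease triad distance tables.
PD_2G2U <- c(-201.7, 22.3, -250.3, 224.0, -48.6, -272.7)
PD_2QZ6 <- c(-196.5, 15.9, -240.3, 212.4, -43.7, -256.1)
PD_SD_TABLE1 <- c(7.8, 15.3, 9.0, 8.9, 15.7, 24.0)
EQL_DIST_DEV <- c(0.2, 0.7, 0.5, 0.3, 0.7, 1.0)
EQL_PD_DEV <- c(9, 229, 122, 219, 113, 106)
DIST_1A0J <- c(3.3, 7.8, 5.5)   # (S,H), (S,D), (H,D)
DIST_1K7H <- c(4.6, 7.7, 3.2)
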