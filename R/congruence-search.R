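# Assemble a MatchSet from chosen residue-row tuples (motif site order).
.buildMatchSet <- function(m, sites, tuples) {
  n <- nSites(m)
  p <- n * (n - 1L) / 2L
  nm <- length(tuples)
  residues <- matrix(NA_character_, nm, n)
  resTypes <- matrix(NA_character_, nm, n)
  coords <- matrix(NA_real_, nm, 3L * n)
  dQ <- matrix(NA_real_, nm, p)
  for (t in seq_along(tuples)) {
    rows <- sites[tuples[[t]], , drop = FALSE]
    residues[t, ] <- rows$key
    resTypes[t, ] <- rows$resid
    xyz <- as.matrix(rows[, c("x", "y", "z")])
    coords[t, ] <- as.vector(t(xyz))
    dQ[t, ] <- pairwiseDistances(xyz)
  }
  if (nm > 1L) {
    ord <- order(apply(residues, 1L, paste, collapse = " "))
    residues <- residues[ord, , drop = FALSE]
    resTypes <- resTypes[ord, , drop = FALSE]
    coords <- coords[ord, , drop = FALSE]
    dQ <- dQ[ord, , drop = FALSE]
  }
  deltaD <- sweep(dQ, 2L, m@dRef)
  new("MatchSet", motifId = m@sourceId, residues = residues,
      resTypes = resTypes, coords = coords, dQ = dQ, deltaD = deltaD,
      dRef = m@dRef)
}

.siteCandidates <- function(sites, m, groups) {
  lapply(seq_len(nSites(m)), function(i) {
    lbl <- m@sites$label[i]
    mem <- groups[[lbl]]
    if (is.null(mem))
      abort(sprintf("unknown group label '%s'", lbl), "claspMotifError")
    which(sites$resid %in% mem)
  })
}

.accept <- function(xyz, dRef, n, cutoff, tol) {
  d <- pairwiseDistances(xyz)
  all(d <= cutoff) && all(abs(d - dRef) <= tol)
}

#' Enumerate spatially congruent motif matches
#'
#' Finds every ordered residue tuple in the query structure such that each
#' site's residue type belongs to its stereochemical group, all pairwise
#' reactive-atom distances are below `cutoff`, and every per-pair deviation
#' from the motif's reference distances is at most `tol`. A residue may not
#' fill two sites of one match. Candidates are drawn from a single chain at
#' a time; multi-chain structures are scanned chain by chain. The search is
#' depth-first over sites ordered by ascending candidate count, extending a
#' partial tuple only while every new pairwise distance remains feasible, so
#' the result provably equals the brute-force enumeration.
#'
#' @param s query [ClaspStructure-class].
#' @param m a [Motif-class] with resolved reference distances.
#' @param groups stereochemical groups from [loadGroups()].
#' @param cutoff maximum pairwise reactive-atom distance within a match (A).
#' @param tol maximum absolute per-pair deviation |dQ - dRef| (A).
#' @param maxMatches cap on returned matches.
#' @param cfg reactive-atom configuration.
#' @return a [MatchSet-class], rows sorted by residue keys.
#' @export
enumerateCandidates <- function(s, m, groups = defaultGroups(), cutoff = 15,
                                tol = 1.5, maxMatches = 10000L,
                                cfg = defaultReactiveConfig()) {
  stopifnot(cutoff > 0, tol >= 0)
  if (any(is.na(m@dRef)))
    abort("motif has unresolved reference distances", "claspMotifError")
  allSites <- reactiveSites(s, cfg)
  n <- nSites(m)
  tuples <- list()
  for (ch in unique(allSites$chain)) {
    idx <- which(allSites$chain == ch)
    sites <- allSites[idx, , drop = FALSE]
    cand <- .siteCandidates(sites, m, groups)
    if (any(!lengths(cand))) next
    ord <- order(lengths(cand))  # fill scarce sites first
    xyz <- as.matrix(sites[, c("x", "y", "z")])
    chosen <- integer(n)  # by motif site index; 0 = unset
    local <- list()
    dfs <- function(level) {
      if (length(tuples) + length(local) >= maxMatches) return()
      if (level > n) {
        local[[length(local) + 1L]] <<- idx[chosen]
        return()
      }
      si <- ord[level]
      for (r in cand[[si]]) {
        if (r %in% chosen[ord[seq_len(level - 1L)]]) next
        ok <- TRUE
        for (lv in seq_len(level - 1L)) {
          sj <- ord[lv]
          d <- sqrt(sum((xyz[r, ] - xyz[chosen[sj], ])^2))
          if (d > cutoff ||
              abs(d - m@dRef[pairIndex(si, sj, n)]) > tol) {
            ok <- FALSE
            break
          }
        }
        if (ok) {
          chosen[si] <<- r
          dfs(level + 1L)
          chosen[si] <<- 0L
        }
      }
    }
    dfs(1L)
    tuples <- c(tuples, local)
  }
  .buildMatchSet(m, allSites, tuples)
}

#' Brute-force search oracle
#'
#' Full Cartesian enumeration over the per-site candidate lists with the
#' identical acceptance predicate as [enumerateCandidates()]. Intended as a
#' validation oracle on small inputs only; refuses when the candidate
#' tuple count exceeds `cap`.
#'
#' @inheritParams enumerateCandidates
#' @param cap maximum number of Cartesian tuples the oracle will consider.
#' @return a [MatchSet-class].
#' @export
bruteForceSearch <- function(s, m, groups = defaultGroups(), cutoff = 15,
                             tol = 1.5, cap = 2e5,
                             cfg = defaultReactiveConfig()) {
  allSites <- reactiveSites(s, cfg)
  n <- nSites(m)
  tuples <- list()
  for (ch in unique(allSites$chain)) {
    idx <- which(allSites$chain == ch)
    sites <- allSites[idx, , drop = FALSE]
    cand <- .siteCandidates(sites, m, groups)
    total <- prod(lengths(cand))
    if (total > cap)
      abort(sprintf("brute-force candidate count %g exceeds cap %g",
                    total, cap), "claspOracleCapError")
    if (total == 0) next
    grid <- do.call(expand.grid, c(cand, KEEP.OUT.ATTRS = FALSE))
    for (t in seq_len(nrow(grid))) {
      tup <- as.integer(grid[t, ])
      if (anyDuplicated(tup)) next
      xyz <- as.matrix(sites[tup, c("x", "y", "z")])
      if (.accept(xyz, m@dRef, n, cutoff, tol))
        tuples[[length(tuples) + 1L]] <- idx[tup]
    }
  }
  .buildMatchSet(m, allSites, tuples)
}

#' Per-pair distance deviations of a candidate
#'
#' Signed deviations dQ - dRef in canonical pair order (absolute values are
#' what the score consumes).
#'
#' @param dQ query pairwise distance vector (or a [MatchSet-class] row
#'   index).
#' @param m a [Motif-class].
#' @return numeric deviation vector.
#' @export
pairwiseDeviation <- function(dQ, m) {
  if (length(dQ) != length(m@dRef))
    abort("distance vector length disagrees with motif pair count",
          "claspMotifError")
  dQ - m@dRef
}
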