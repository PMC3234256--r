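#' Accessors for clasp objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x a clasp object.
#' @name clasp-accessors
NULL

#' @rdname clasp-accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname clasp-accessors
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' @rdname clasp-accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname clasp-accessors
#' @export
setGeneric("motifSites", function(x) standardGeneric("motifSites"))

#' @rdname clasp-accessors
#' @export
setGeneric("refDistances", function(x) standardGeneric("refDistances"))

#' @rdname clasp-accessors
#' @export
setGeneric("refPD", function(x) standardGeneric("refPD"))

#' @rdname clasp-accessors
#' @export
setGeneric("matchCount", function(x) standardGeneric("matchCount"))

#' @rdname clasp-accessors
#' @export
setGeneric("matchResidues", function(x) standardGeneric("matchResidues"))

#' @rdname clasp-accessors
#' @export
setGeneric("distanceDeviations", function(x) standardGeneric("distanceDeviations"))

#' @rdname clasp-accessors
#' @export
setGeneric("queryPD", function(x) standardGeneric("queryPD"))

#' @rdname clasp-accessors
#' @export
setGeneric("claspScores", function(x) standardGeneric("claspScores"))

#' @rdname clasp-accessors
#' @export
setMethod("atoms", "ClaspStructure", function(x) x@atoms)

#' @rdname clasp-accessors
#' @export
setMethod("sourceId", "ClaspStructure", function(x) x@sourceId)

#' @rdname clasp-accessors
#' @export
setMethod("sourceId", "Motif", function(x) x@sourceId)

#' @rdname clasp-accessors
#' @export
setMethod("nSites", "Motif", function(x) nrow(x@sites))

#' @rdname clasp-accessors
#' @export
setMethod("motifSites", "Motif", function(x) x@sites)

#' @rdname clasp-accessors
#' @export
setMethod("refDistances", "Motif", function(x) x@dRef)

#' @rdname clasp-accessors
#' @export
setMethod("refPD", "Motif", function(x) x@pRef)

#' @rdname clasp-accessors
#' @export
setMethod("matchCount", "MatchSet", function(x) nrow(x@residues))

#' @rdname clasp-accessors
#' @export
setMethod("matchResidues", "MatchSet", function(x) x@residues)

#' @rdname clasp-accessors
#' @export
setMethod("distanceDeviations", "MatchSet", function(x) x@deltaD)

#' @rdname clasp-accessors
#' @export
setMethod("queryPD", "ScoredMatches", function(x) x@pQ)

#' @rdname clasp-accessors
#' @export
setMethod("claspScores", "ScoredMatches", function(x) x@S)

setMethod("show", "ClaspStructure", function(object) {
  a <- object@atoms
  nres <- nrow(unique(a[, c("chain", "resno", "icode", "resid")]))
  cat(sprintf("ClaspStructure '%s': %d atoms, %d residues, chains: %s%s\n",
              object@sourceId, nrow(a), nres,
              paste(unique(a$chain), collapse = ","),
              if ("charge" %in% names(a)) " [parameterized]" else ""))
})

setMethod("show", "GridParams", function(object) {
  cat(sprintf(paste0("GridParams: h=%s A, eps(solute/solvent)=%g/%g, ",
                     "probe=%g A, T=%g K, I=%g M, padding=%g A\n"),
              if (is.na(object@h)) "auto" else format(object@h),
              object@soluteEps, object@solventEps, object@probeRadius,
              object@tempK, object@ionicStrength, object@padding))
})

setMethod("show", "PotentialGrid", function(object) {
  cat(sprintf(paste0("PotentialGrid: %d x %d x %d nodes, h=%g A, ",
                     "origin=(%.1f, %.1f, %.1f), phi in [%.3g, %.3g] kT/e\n"),
              object@dims[1], object@dims[2], object@dims[3], object@h,
              object@origin[1], object@origin[2], object@origin[3],
              min(object@phi), max(object@phi)))
})

setMethod("show", "Motif", function(object) {
  s <- object@sites
  cat(sprintf("Motif from '%s' with %d sites:\n", object@sourceId, nrow(s)))
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %d. %-8s %s:%s%d%s (%s)\n", i, s$label[i], s$chain[i],
                s$resid[i], s$resno[i], trimws(s$icode[i]), s$atom[i]))
  cat("  dRef (A):  ", paste(format(object@dRef, digits = 3),
                             collapse = " "), "\n")
  if (!all(is.na(object@pRef)))
    cat("  pRef (kT/e):", paste(format(object@pRef, digits = 4),
                                collapse = " "), "\n")
})

setMethod("show", "MatchSet", function(object) {
  cat(sprintf("MatchSet vs motif '%s': %d match(es), %d sites\n",
              object@motifId, nrow(object@residues), ncol(object@residues)))
  if (nrow(object@residues)) {
    k <- min(nrow(object@residues), 5L)
    for (i in seq_len(k))
      cat("  ", paste(object@residues[i, ], collapse = " "),
          sprintf(" max|dD|=%.2f A\n", max(abs(object@deltaD[i, ]))))
    if (nrow(object@residues) > k) cat("  ...\n")
  }
})

setMethod("show", "ScoredMatches", function(object) {
  cat(sprintf("ScoredMatches vs motif '%s': %d match(es); S = %g*D + %g*P\n",
              object@motifId, nrow(object@residues),
              object@weights[1], object@weights[2]))
  if (length(object@S)) {
    ord <- orderMatches(object)
    k <- min(length(ord), 5L)
    for (i in ord[seq_len(k)])
      cat(sprintf("  S=%-8.4g D=%-8.4g P=%-8.4g %s\n", object@S[i],
                  object@D[i], object@P[i],
                  paste(object@residues[i, ], collapse = " ")))
    if (length(ord) > k) cat("  ...\n")
  }
})
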