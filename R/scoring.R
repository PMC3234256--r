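#' CLASP score terms
#'
#' The distance term normalizes each absolute deviation by its reference
#' distance, so a 1 A deviation over a 4 A reference pair (0.25) counts
#' twice a 1 A deviation over an 8 A pair (0.125). The PD term normalizes
#' each absolute PD deviation by the reference PD magnitude (floored at
#' `pFloor` so near-zero references are loosely rather than infinitely
#' constrained) and ignores a pair outright when both the query and the
#' reference PD sit inside the `epsZero` band around zero.
#'
#' @param absDev absolute distance deviations |dQ - dRef| (A).
#' @param dRef reference distances (A), all positive.
#' @return `distanceTerm`: dimensionless deviation sum D.
#' @export
distanceTerm <- function(absDev, dRef) {
  if (length(absDev) != length(dRef))
    abort("deviation and reference vectors differ in length",
          "claspScoreError")
  if (any(dRef <= 0))
    abort("reference distances must be positive", "claspScoreError")
  sum(abs(absDev) / dRef)
}

#' @rdname distanceTerm
#' @param pQ,pRef query and reference PD vectors (kT/e).
#' @param epsZero both-near-zero ignore band (kT/e).
#' @param pFloor denominator floor (kT/e).
#' @return `pdTerm`: dimensionless deviation sum P.
#' @export
pdTerm <- function(pQ, pRef, epsZero = 25, pFloor = 50) {
  if (length(pQ) != length(pRef))
    abort("PD vectors differ in length", "claspScoreError")
  stopifnot(epsZero >= 0, pFloor > 0)
  contrib <- abs(pQ - pRef) / pmax(abs(pRef), pFloor)
  contrib[abs(pQ) < epsZero & abs(pRef) < epsZero] <- 0
  sum(contrib)
}

#' Score congruent matches
#'
#' Attaches query PDs to a [MatchSet-class] and computes, per match, the
#' distance term D, PD term P and combined CLASP score S = wd * D + wp * P.
#' Lower is better; probing a motif in its own reference structure yields
#' exactly zero. Query PDs may come from a solved [PotentialGrid-class]
#' (evaluated at the matched reactive atoms) or be supplied directly as a
#' matrix; with `wp = 0` (or a motif without reference PDs) the score is
#' purely spatial.
#'
#' @param matches a [MatchSet-class].
#' @param m the probed [Motif-class].
#' @param grid optional [PotentialGrid-class] for the query structure.
#' @param pQ optional matrix (match x pair) of query PDs in kT/e.
#' @param wd,wp non-negative weights (not both zero).
#' @param epsZero,pFloor PD-term thresholds (kT/e), see [pdTerm()].
#' @return a [ScoredMatches-class].
#' @export
scoreMatches <- function(matches, m, grid = NULL, pQ = NULL, wd = 1, wp = 1,
                         epsZero = 25, pFloor = 50) {
  stopifnot(wd >= 0, wp >= 0, wd + wp > 0)
  nm <- nrow(matches@residues)
  n <- ncol(matches@residues)
  pr <- canonicalPairs(n)
  p <- ncol(pr)
  usePD <- wp > 0 && !all(is.na(m@pRef))
  if (usePD && is.null(pQ)) {
    if (is.null(grid))
      abort("PD-weighted scoring needs a grid or a pQ matrix",
            "claspScoreError")
    pQ <- matrix(NA_real_, nm, p)
    for (t in seq_len(nm)) {
      xyz <- matrix(matches@coords[t, ], ncol = 3L, byrow = TRUE)
      pQ[t, ] <- vapply(seq_len(p), function(k)
        pairPD(grid, xyz[pr[1, k], ], xyz[pr[2, k], ]), 0)
    }
  }
  if (is.null(pQ)) pQ <- matrix(NA_real_, nm, p)
  D <- vapply(seq_len(nm), function(t)
    distanceTerm(abs(matches@deltaD[t, ]), matches@dRef), 0)
  P <- if (usePD)
    vapply(seq_len(nm), function(t)
      pdTerm(pQ[t, ], m@pRef, epsZero, pFloor), 0)
  else rep(0, nm)
  new("ScoredMatches", matches, pQ = pQ, pRef = m@pRef, D = D, P = P,
      S = wd * D + wp * P, weights = c(wd, wp),
      thresholds = c(epsZero, pFloor))
}

#' Best-scoring match and alternates
#'
#' Orders matches by (S, D, residue keys) and reports the top of the list as
#' the predicted catalytic site, keeping alternates (e.g. a second-best
#' serine filling the same site) in the report. A structure with no
#' congruent match yields a distinguishable no-match result rather than a
#' zero score.
#'
#' @param scored a [ScoredMatches-class].
#' @param alternates how many runner-up matches to retain.
#' @return list with `matched` (logical), `best` (one-row data.frame or
#'   NULL) and `report` (data.frame of best + alternates).
#' @export
bestMatch <- function(scored, alternates = 4L) {
  nm <- length(scored@S)
  if (nm == 0L)
    return(list(matched = FALSE, best = NULL,
                report = data.frame(rank = integer(), S = numeric(),
                                    D = numeric(), P = numeric(),
                                    residues = character())))
  ord <- orderMatches(scored)
  keep <- ord[seq_len(min(nm, 1L + alternates))]
  report <- data.frame(
    rank = seq_along(keep),
    S = scored@S[keep], D = scored@D[keep], P = scored@P[keep],
    residues = apply(scored@residues[keep, , drop = FALSE], 1L, paste,
                     collapse = " "),
    stringsAsFactors = FALSE)
  list(matched = TRUE, best = report[1L, ], report = report)
}

#' Rank a motif library against a query structure
#'
#' Scores every motif in the library against the structure and returns one
#' row per motif with its best match, sorted ascending by score; motifs with
#' no congruent match are listed last with NA score. Scanning a structure
#' against a library containing its own source motif ranks that motif first
#' with score zero.
#'
#' @param s query [ClaspStructure-class].
#' @param motifs list of [Motif-class] objects.
#' @param grid optional [PotentialGrid-class] for the structure (solved once
#'   and reused across motifs); when NULL and `wp > 0`, PDs are skipped and
#'   scoring is spatial for motifs lacking reference PDs.
#' @inheritParams scoreMatches
#' @inheritParams enumerateCandidates
#' @return data.frame: `motif`, `n`, `S`, `D`, `P`, `residues`, `matched`.
#' @export
rankLibrary <- function(s, motifs, grid = NULL, groups = defaultGroups(),
                        cutoff = 15, tol = 1.5, wd = 1, wp = 1,
                        epsZero = 25, pFloor = 50,
                        cfg = defaultReactiveConfig()) {
  if (!length(motifs))
    return(data.frame(motif = character(), n = integer(), S = numeric(),
                      D = numeric(), P = numeric(), residues = character(),
                      matched = logical(), stringsAsFactors = FALSE))
  rows <- lapply(motifs, function(m) {
    ms <- enumerateCandidates(s, m, groups, cutoff, tol, cfg = cfg)
    useWp <- if (all(is.na(m@pRef)) || is.null(grid)) 0 else wp
    sc <- scoreMatches(ms, m, grid = grid, wd = wd, wp = useWp,
                       epsZero = epsZero, pFloor = pFloor)
    bm <- bestMatch(sc)
    data.frame(motif = m@sourceId, n = nSites(m),
               S = if (bm$matched) bm$best$S else NA_real_,
               D = if (bm$matched) bm$best$D else NA_real_,
               P = if (bm$matched) bm$best$P else NA_real_,
               residues = if (bm$matched) bm$best$residues else "",
               matched = bm$matched, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(!out$matched, out$S, out$D, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classification metrics
#'
#' Sensitivity (= recall) TP/(TP+FN), specificity TN/(TN+FP) and false
#' positive rate FP/(FP+TN). A zero denominator yields NA with a flag.
#'
#' @param TP,TN,FP,FN non-negative integer confusion counts.
#' @return list with `sensitivity`, `specificity`, `fpr`, `undefined`
#'   (character vector naming any undefined metric).
#' @export
confusionMetrics <- function(TP, TN, FP, FN) {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0)
  undef <- character()
  sens <- if (TP + FN > 0) TP / (TP + FN) else {
    undef <- c(undef, "sensitivity"); NA_real_ }
  spec <- if (TN + FP > 0) TN / (TN + FP) else {
    undef <- c(undef, "specificity"); NA_real_ }
  fpr <- if (FP + TN > 0) FP / (FP + TN) else {
    undef <- c(undef, "fpr"); NA_real_ }
  list(sensitivity = sens, specificity = spec, fpr = fpr, undefined = undef)
}

#' ROC sweep over CLASP scores
#'
#' Sweeps an inclusive threshold over the observed scores (score <= t
#' predicts positive, since lower scores are better matches) and returns the
#' stepwise sensitivity-vs-FPR curve plus its area under the curve.
#'
#' @param scores numeric scores (lower = more positive).
#' @param labels logical or 0/1 vector, TRUE for true positives.
#' @return list with `curve` (data.frame threshold/fpr/sensitivity, starting
#'   at the origin) and `auc`.
#' @export
rocSweep <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (!any(labels) || all(labels))
    abort("ROC sweep needs both positive and negative labels",
          "claspScoreError")
  th <- sort(unique(scores))
  sens <- vapply(th, function(t) mean(scores[labels] <= t), 0)
  fpr <- vapply(th, function(t) mean(scores[!labels] <= t), 0)
  curve <- data.frame(threshold = c(-Inf, th), fpr = c(0, fpr),
                      sensitivity = c(0, sens))
  # trapezoidal area over the operating points (ties move diagonally)
  k <- nrow(curve)
  auc <- sum(diff(curve$fpr) *
             (curve$sensitivity[-1L] + curve$sensitivity[-k]) / 2)
  list(curve = curve, auc = auc)
}
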