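AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL")

#' Stereochemical residue groups
#'
#' Parses a group configuration: one group per line, `Label: RES RES ...`
#' (the colon is optional). Singleton `<Xxx>only` groups (e.g. `Seronly`)
#' are appended automatically for every standard amino acid. Groups let a
#' motif site accept stereochemically equivalent side chains, trading
#' specificity for sensitivity (e.g. Lys-like = \{Lys, Arg, His\}).
#'
#' @param text character vector of config lines, a single string, or a file
#'   path.
#' @return named list: group label -> character vector of 3-letter codes.
#' @export
loadGroups <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text <- trimws(sub("#.*", "", text))
  text <- text[nzchar(text)]
  groups <- list()
  for (ln in text) {
    toks <- strsplit(gsub(":", " ", ln), "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    label <- toks[1L]
    members <- toupper(toks[-1L])
    if (!length(members))
      abort(sprintf("group '%s' has no members", label), "claspConfigError")
    if (label %in% names(groups))
      abort(sprintf("duplicate group label '%s'", label), "claspConfigError")
    bad <- setdiff(members, AMINO3)
    if (length(bad))
      abort(sprintf("unknown residue code(s) in group '%s': %s", label,
                    paste(bad, collapse = ", ")), "claspConfigError")
    groups[[label]] <- members
  }
  for (aa in AMINO3) {
    lbl <- paste0(substr(aa, 1, 1), tolower(substr(aa, 2, 3)), "only")
    if (!lbl %in% names(groups)) groups[[lbl]] <- aa
  }
  groups
}

#' @rdname loadGroups
#' @export
defaultGroups <- function() {
  loadGroups(system.file("extdata", "stereo_groups.conf", package = "clasp"))
}

#' Build a motif from a reference structure
#'
#' Resolves the reactive atom of each listed residue, records all pairwise
#' reactive-atom distances in canonical pair order (lexicographic (i, j),
#' i < j over site index), and - when a potential grid is supplied - the
#' pairwise potential differences phi(i) - phi(j) over the same pairs.
#'
#' @param s reference [ClaspStructure-class].
#' @param residues character vector of residue selectors
#'   `"chain:resno"` or `"chain:resno:icode"` in motif site order.
#' @param labels group labels, one per site (default: each residue's own
#'   singleton group).
#' @param groups group configuration from [loadGroups()].
#' @param grid optional [PotentialGrid-class] for reference PDs.
#' @param cfg reactive-atom configuration.
#' @return a [Motif-class].
#' @export
buildMotif <- function(s, residues, labels = NULL, groups = defaultGroups(),
                       grid = NULL, cfg = defaultReactiveConfig()) {
  a <- atoms(s)
  n <- length(residues)
  if (!n %in% 3:5)
    abort("a motif needs 3, 4 or 5 residues", "claspMotifError")
  picked <- vector("list", n)
  for (i in seq_len(n)) {
    f <- strsplit(residues[i], ":", fixed = TRUE)[[1]]
    if (length(f) < 2L)
      abort(sprintf("bad residue selector '%s' (want chain:resno)",
                    residues[i]), "claspMotifError")
    ic <- if (length(f) >= 3L) f[3] else ""
    rows <- a[a$chain == f[1] & a$resno == as.integer(f[2]) &
              trimws(a$icode) == ic, , drop = FALSE]
    if (!nrow(rows))
      abort(sprintf("residue %s not found in %s", residues[i], sourceId(s)),
            "claspMotifError")
    picked[[i]] <- reactiveAtom(rows, cfg)
  }
  types <- vapply(picked, function(p) p$resid, "")
  if (is.null(labels)) {
    labels <- paste0(substr(types, 1, 1), tolower(substr(types, 2, 3)),
                     "only")
  }
  for (i in seq_len(n)) {
    mem <- groups[[labels[i]]]
    if (is.null(mem))
      abort(sprintf("unknown group label '%s'", labels[i]),
            "claspMotifError")
    if (!types[i] %in% mem)
      abort(sprintf("site %d residue %s is outside group %s {%s}", i,
                    types[i], labels[i], paste(mem, collapse = ", ")),
            "claspMotifError")
  }
  xyz <- t(vapply(picked, function(p) c(p$x, p$y, p$z), numeric(3)))
  dRef <- pairwiseDistances(xyz)
  pRef <- rep(NA_real_, length(dRef))
  if (!is.null(grid)) {
    pr <- canonicalPairs(n)
    pRef <- vapply(seq_len(ncol(pr)), function(k)
      pairPD(grid, xyz[pr[1, k], ], xyz[pr[2, k], ]), 0)
  }
  sites <- data.frame(
    label = labels,
    chain = vapply(picked, function(p) p$chain, ""),
    resno = vapply(picked, function(p) p$resno, 0L),
    icode = vapply(picked, function(p) trimws(p$icode), ""),
    resid = types,
    atom = vapply(picked, function(p) p$name, ""),
    stringsAsFactors = FALSE)
  new("Motif", sourceId = sourceId(s), sites = sites, dRef = dRef,
      pRef = pRef)
}

#' Construct a motif directly from reference vectors
#'
#' For motifs whose reference distances/PDs come from published tables or an
#' externally solved grid rather than from a locally available structure.
#'
#' @param sourceId reference identifier.
#' @param labels group labels per site.
#' @param resids 3-letter residue types per site.
#' @param resnos residue numbers per site.
#' @param atoms reactive atom names per site.
#' @param dRef,pRef canonical-pair-order reference vectors.
#' @param chain chain id (single).
#' @return a [Motif-class].
#' @export
motifFromVectors <- function(sourceId, labels, resids, resnos, atoms, dRef,
                             pRef = rep(NA_real_, length(dRef)),
                             chain = "A") {
  n <- length(labels)
  sites <- data.frame(label = labels, chain = chain, resno = resnos,
                      icode = "", resid = toupper(resids), atom = atoms,
                      stringsAsFactors = FALSE)
  new("Motif", sourceId = sourceId, sites = sites, dRef = dRef, pRef = pRef)
}

#' Motif file I/O
#'
#' Structured-text motif files: `source`, one `site` line per site
#' (`site <group> <chain>:<resid>:<resno> <atom>`), then `dref` and `pref`
#' vectors in canonical pair order.
#'
#' @param m a [Motif-class].
#' @param path file path.
#' @export
writeMotif <- function(m, path) {
  s <- m@sites
  lines <- c(sprintf("source %s", m@sourceId),
             sprintf("site %s %s:%s:%d%s %s", s$label, s$chain, s$resid,
                     s$resno, s$icode, s$atom),
             paste("dref", paste(sprintf("%.4f", m@dRef), collapse = " ")),
             if (!all(is.na(m@pRef)))
               paste("pref", paste(sprintf("%.4f", m@pRef),
                                   collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeMotif
#' @return `readMotif`: a [Motif-class].
#' @export
readMotif <- function(path) {
  lines <- readLines(path)
  src <- sub("^source ", "", grep("^source ", lines, value = TRUE)[1])
  siteLines <- grep("^site ", lines, value = TRUE)
  parts <- strsplit(siteLines, "[[:space:]]+")
  labels <- vapply(parts, `[[`, "", 2L)
  rid <- strsplit(vapply(parts, `[[`, "", 3L), ":", fixed = TRUE)
  atomNames <- vapply(parts, `[[`, "", 4L)
  dRef <- as.numeric(strsplit(sub("^dref ", "",
                                  grep("^dref ", lines, value = TRUE)[1]),
                              " ")[[1]])
  prefLine <- grep("^pref ", lines, value = TRUE)
  pRef <- if (length(prefLine))
    as.numeric(strsplit(sub("^pref ", "", prefLine[1]), " ")[[1]])
  else rep(NA_real_, length(dRef))
  sites <- data.frame(
    label = labels,
    chain = vapply(rid, `[[`, "", 1L),
    resno = as.integer(sub("([0-9]+).*", "\\1",
                           vapply(rid, `[[`, "", 3L))),
    icode = sub("^[0-9]+", "", vapply(rid, `[[`, "", 3L)),
    resid = vapply(rid, `[[`, "", 2L),
    atom = atomNames, stringsAsFactors = FALSE)
  new("Motif", sourceId = src, sites = sites, dRef = dRef, pRef = pRef)
}

#' Parse a Catalytic Site Atlas listing
#'
#' Targets the CSA 2.2.x comma-separated dialect with columns PDB id, site
#' number, residue type, chain, residue number, chemical function, evidence
#' type, literature entry (extra columns tolerated). One record is returned
#' per (PDB id, site number); malformed lines are skipped with a single
#' summary warning.
#'
#' @param text listing lines, single string, or file path.
#' @return data.frame with one row per site: `pdbId`, `site`, `chains`
#'   (comma-collapsed), `nResidues`, `literature` (logical),
#'   `residues` (list column of data.frames with resid, chain, resno).
#' @export
parseCSA <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text <- text[nzchar(trimws(text))]
  if (length(text) && grepl("^PDB", text[1], ignore.case = TRUE))
    text <- text[-1L]
  bad <- 0L
  rows <- list()
  for (ln in text) {
    f <- strsplit(ln, ",", fixed = TRUE)[[1]]
    ok <- length(f) >= 7L && nzchar(trimws(f[1])) &&
      !is.na(suppressWarnings(as.integer(f[5]))) &&
      toupper(trimws(f[3])) %in% AMINO3
    if (!ok) { bad <- bad + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      pdbId = tolower(trimws(f[1])), site = as.integer(f[2]),
      resid = toupper(trimws(f[3])), chain = trimws(f[4]),
      resno = as.integer(f[5]), evidence = toupper(trimws(f[7])),
      stringsAsFactors = FALSE)
  }
  if (bad > 0L)
    warning(sprintf("skipped %d malformed CSA line(s)", bad))
  if (!length(rows))
    return(data.frame(pdbId = character(), site = integer(),
                      chains = character(), nResidues = integer(),
                      literature = logical()))
  tab <- do.call(rbind, rows)
  sp <- split(tab, paste(tab$pdbId, tab$site))
  recs <- lapply(sp, function(g) {
    data.frame(pdbId = g$pdbId[1], site = g$site[1],
               chains = paste(unique(g$chain), collapse = ","),
               nResidues = nrow(g),
               literature = all(g$evidence %in% c("LIT", "LITERATURE")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out <- out[order(out$pdbId, out$site), , drop = FALSE]
  out$residues <- lapply(sp[order(names(sp))], function(g)
    g[, c("resid", "chain", "resno")])
  rownames(out) <- NULL
  out
}

#' Filter CSA records to usable motif specifications
#'
#' Retains literature-annotated sites with 3-5 residues confined to a single
#' chain (composite multi-subunit sites are dropped). Each retained record
#' gets per-site group labels defaulting to the residue's own singleton
#' group. The filter is idempotent.
#'
#' @param records output of [parseCSA()].
#' @return filtered records with an added `labels` list column.
#' @export
filterCSA <- function(records) {
  if (!nrow(records)) return(records)
  keep <- records$literature & records$nResidues >= 3L &
    records$nResidues <= 5L & !grepl(",", records$chains)
  out <- records[keep, , drop = FALSE]
  if (is.null(out$labels) && nrow(out)) {
    out$labels <- lapply(out$residues, function(r)
      paste0(substr(r$resid, 1, 1), tolower(substr(r$resid, 2, 3)), "only"))
  } else if (is.null(out$labels)) {
    out$labels <- list()
  }
  rownames(out) <- NULL
  out
}
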