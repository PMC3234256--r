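#' Read a PDB-format structure
#'
#' Parses PDB text (via bio3d) into a [ClaspStructure-class]. Only the first
#' model is retained; where alternate locations exist, the highest-occupancy
#' altloc is kept (ties broken by altloc letter). HETATM records are retained
#' and flagged (`het = TRUE`) except waters, which are dropped. Atoms are
#' returned in file order.
#'
#' @param text PDB-format character: either a single string, a character
#'   vector of lines, or a path to an existing file.
#' @param chain optional chain selector (character vector of chain ids).
#' @param sourceId identifier stored on the returned object; defaults to the
#'   file basename or "pdb-text".
#' @return a [ClaspStructure-class].
#' @export
readPDB <- function(text, chain = NULL, sourceId = NULL) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    if (is.null(sourceId))
      sourceId <- sub("\\.(pdb|ent)$", "", basename(text))
    text <- readLines(text)
  }
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (is.null(sourceId)) sourceId <- "pdb-text"

  # first model only
  endm <- grep("^ENDMDL", text)
  if (length(endm)) text <- text[seq_len(endm[1] - 1L)]
  if (!any(grepl("^ATOM", text)))
    abort("no ATOM records found in PDB input", "claspParseError")

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(text, tf)
  pdb <- bio3d::read.pdb(tf, multi = FALSE, verbose = FALSE)
  a <- pdb$atom

  atoms <- data.frame(
    eleno = a$eleno,
    name = a$elety,
    altloc = ifelse(is.na(a$alt), "", a$alt),
    resid = a$resid,
    chain = ifelse(is.na(a$chain), " ", a$chain),
    resno = a$resno,
    icode = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o),
    het = a$type == "HETATM",
    element = ifelse(is.na(a$elesy), "", toupper(a$elesy)),
    stringsAsFactors = FALSE)

  atoms <- atoms[!(atoms$het & atoms$resid %in% c("HOH", "WAT", "DOD")), ,
                 drop = FALSE]
  if (!is.null(chain)) atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]
  if (!nrow(atoms))
    abort("no atoms left after chain selection", "claspParseError")

  # altloc resolution: keep highest occupancy, ties by altloc letter order
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$resid, atoms$name)
  if (anyDuplicated(key)) {
    ord <- order(key, -atoms$occ, atoms$altloc)
    keep <- !duplicated(key[ord])
    sel <- sort(seq_len(nrow(atoms))[ord][keep])
    atoms <- atoms[sel, , drop = FALSE]
  }
  rownames(atoms) <- NULL
  new("ClaspStructure", atoms = atoms, sourceId = sourceId, model = 1L)
}

#' Reactive-atom configuration
#'
#' Reads the residue-to-reactive-atom map. Format: one residue per line,
#' `RES atom1 [atom2 ...]` where later atom names are ordered fallbacks
#' (e.g. His NE2 with ND1 as fallback). The packaged default pins Ser OG,
#' Lys NZ and Arg NH1 and uses His NE2/ND1, Asp OD1/OD2, Glu OE1/OE2.
#'
#' @param path path to a config file; default is the packaged table.
#' @return named list mapping residue type to an ordered character vector of
#'   candidate atom names.
#' @export
readReactiveConfig <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reactive_atoms.conf", package = "clasp")
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "[[:space:]]+")
  cfg <- lapply(toks, function(t) toupper(t[-1]))
  names(cfg) <- toupper(vapply(toks, `[[`, "", 1L))
  if (anyDuplicated(names(cfg)))
    abort("duplicate residue in reactive-atom config", "claspConfigError")
  cfg
}

#' @rdname readReactiveConfig
#' @export
defaultReactiveConfig <- function() readReactiveConfig()

#' Resolve the reactive atom of one residue
#'
#' Returns the first configured atom name present in the residue, a pure
#' function of the residue contents and the configuration.
#'
#' @param residue data.frame of atom rows for a single residue (subset of
#'   [atoms()]).
#' @param cfg reactive-atom configuration from [readReactiveConfig()].
#' @return single atom row (data.frame).
#' @export
reactiveAtom <- function(residue, cfg = defaultReactiveConfig()) {
  rt <- unique(residue$resid)
  if (length(rt) != 1L)
    abort("residue view must contain exactly one residue type",
          "claspConfigError")
  wanted <- cfg[[toupper(rt)]]
  if (is.null(wanted))
    abort(sprintf("residue type %s has no reactive-atom entry", rt),
          "claspConfigError")
  for (nm in wanted) {
    hit <- which(residue$name == nm)
    if (length(hit)) return(residue[hit[1L], , drop = FALSE])
  }
  abort(sprintf("residue %s %s%s has none of the configured atoms (%s)",
                rt, residue$resno[1L], residue$chain[1L],
                paste(wanted, collapse = ", ")),
        "claspMissingAtomError")
}

# Residue-level view: one row per residue that has a resolvable reactive
# atom, with the reactive-atom coordinates. Used by the congruence search.
reactiveSites <- function(s, cfg = defaultReactiveConfig()) {
  a <- atoms(s)
  a <- a[toupper(a$resid) %in% names(cfg), , drop = FALSE]
  if (!nrow(a))
    return(data.frame(key = character(), chain = character(),
                      resid = character(), resno = integer(),
                      icode = character(), atom = character(),
                      x = numeric(), y = numeric(), z = numeric()))
  sp <- split(a, paste(a$chain, a$resno, a$icode, a$resid))
  rows <- lapply(sp, function(res) {
    hit <- NULL
    for (nm in cfg[[toupper(res$resid[1L])]]) {
      w <- which(res$name == nm)
      if (length(w)) { hit <- res[w[1L], ]; break }
    }
    if (is.null(hit)) return(NULL)
    data.frame(key = residueKey(hit$chain, hit$resid, hit$resno, hit$icode),
               chain = hit$chain, resid = hit$resid, resno = hit$resno,
               icode = hit$icode, atom = hit$name,
               x = hit$x, y = hit$y, z = hit$z, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chain, out$resno, out$icode), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Charge/radius parameter table
#'
#' Reads a whitespace-delimited table with columns residue, atom, charge (e)
#' and radius (A). Residue `*` marks backbone entries shared by all amino
#' acids; exact residue matches take precedence over `*`.
#'
#' @param path path to a table; default is the packaged PARSE-inspired
#'   heavy-atom table.
#' @return data.frame with columns `residue`, `atom`, `charge`, `radius`.
#' @export
readChargeTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "charge_radius_heavy.tsv",
                        package = "clasp")
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("residue", "atom", "charge",
                                         "radius"),
                           stringsAsFactors = FALSE)
  tab$residue <- toupper(tab$residue)
  tab$atom <- toupper(tab$atom)
  if (any(tab$radius <= 0))
    abort("non-positive radius in charge table", "claspConfigError")
  if (any(abs(tab$charge) > 2))
    abort("charge outside [-2, 2] e in charge table", "claspConfigError")
  tab
}

#' @rdname readChargeTable
#' @export
defaultChargeTable <- function() readChargeTable()

#' Assign charges and radii to every atom
#'
#' Static assignment depending only on (residue type, atom name): the OG atom
#' of Ser always receives -0.49 e regardless of position. Lookup prefers an
#' exact residue match, then the backbone wildcard `*`.
#'
#' @param s a [ClaspStructure-class].
#' @param table charge/radius table from [readChargeTable()].
#' @param policy "strict" errors on any uncovered atom (listing the offending
#'   residues); "skip" drops uncovered atoms with a warning.
#' @param excludeMetals drop flagged HETATM metal ions instead of
#'   parameterizing them with their formal charge.
#' @return the structure with `charge` and `radius` columns filled in.
#' @export
assignParameters <- function(s, table = defaultChargeTable(),
                             policy = c("strict", "skip"),
                             excludeMetals = FALSE) {
  policy <- match.arg(policy)
  a <- atoms(s)
  if (excludeMetals) a <- a[!a$het, , drop = FALSE]
  exact <- paste(toupper(a$resid), toupper(a$name))
  wild <- paste("*", toupper(a$name))
  tabKey <- paste(table$residue, table$atom)
  i <- match(exact, tabKey)
  miss <- is.na(i)
  i[miss] <- match(wild[miss], tabKey)
  uncovered <- is.na(i)
  if (any(uncovered)) {
    what <- unique(paste0(a$resid[uncovered], " ",
                          a$resno[uncovered], a$chain[uncovered]))
    if (policy == "strict")
      abort(paste("unparameterized atoms in residues:",
                  paste(what, collapse = ", ")),
            "claspParameterizationError")
    warning(sprintf("dropping %d unparameterized atom(s) in: %s",
                    sum(uncovered), paste(what, collapse = ", ")))
    a <- a[!uncovered, , drop = FALSE]
    i <- i[!uncovered]
  }
  a$charge <- table$charge[i]
  a$radius <- table$radius[i]
  rownames(a) <- NULL
  new("ClaspStructure", atoms = a, sourceId = s@sourceId, model = s@model)
}

#' Write and read PQR
#'
#' Whitespace-delimited PQR records: `ATOM serial name resName resNumber x y
#' z charge radius` (10 fields). Coordinates carry 3 decimals; charges and
#' radii 4, so a write/read round trip reproduces them exactly at that
#' precision. Chain identity is preserved via `REMARK CHAIN` header lines at
#' chain breaks.
#'
#' @param s parameterized [ClaspStructure-class] (see [assignParameters()]).
#' @return `writePQR`: character vector of PQR lines.
#' @export
writePQR <- function(s) {
  a <- atoms(s)
  header <- c("REMARK PQR generated by clasp",
              "REMARK charge in e, radius in A")
  if (!nrow(a)) return(header)
  if (!"charge" %in% names(a))
    abort("structure is not parameterized; run assignParameters first",
          "claspParameterizationError")
  lastChain <- ""
  out <- header
  for (i in seq_len(nrow(a))) {
    if (a$chain[i] != lastChain) {
      out <- c(out, sprintf("REMARK CHAIN %s", a$chain[i]))
      lastChain <- a$chain[i]
    }
    out <- c(out, sprintf("%s %5d %-4s %3s %5d %10.3f %10.3f %10.3f %8.4f %7.4f",
                          if (a$het[i]) "HETATM" else "ATOM",
                          a$eleno[i], a$name[i], a$resid[i], a$resno[i],
                          a$x[i], a$y[i], a$z[i], a$charge[i], a$radius[i]))
  }
  out
}

#' @rdname writePQR
#' @param lines character vector of PQR lines (or a file path).
#' @param sourceId identifier for the returned structure.
#' @return `readPQR`: parameterized [ClaspStructure-class].
#' @export
readPQR <- function(lines, sourceId = "pqr-text") {
  if (length(lines) == 1L && !grepl("\n", lines) && file.exists(lines))
    lines <- readLines(lines)
  if (length(lines) == 1L) lines <- strsplit(lines, "\n", fixed = TRUE)[[1]]
  chain <- " "
  rows <- list()
  for (ln in lines) {
    if (grepl("^REMARK CHAIN ", ln)) {
      chain <- sub("^REMARK CHAIN ", "", ln)
      next
    }
    if (!grepl("^(ATOM|HETATM)", ln)) next
    f <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(f) != 10L)
      abort("malformed PQR record (expected 10 fields)", "claspParseError")
    rows[[length(rows) + 1L]] <- data.frame(
      eleno = as.integer(f[2]), name = f[3], altloc = "", resid = f[4],
      chain = chain, resno = as.integer(f[5]), icode = "",
      x = as.numeric(f[6]), y = as.numeric(f[7]), z = as.numeric(f[8]),
      occ = 1, het = f[1] == "HETATM",
      element = substr(f[3], 1L, 1L),
      charge = as.numeric(f[9]), radius = as.numeric(f[10]),
      stringsAsFactors = FALSE)
  }
  atoms <- if (length(rows)) do.call(rbind, rows) else
    data.frame(eleno = integer(), name = character(), altloc = character(),
               resid = character(), chain = character(), resno = integer(),
               icode = character(), x = numeric(), y = numeric(),
               z = numeric(), occ = numeric(), het = logical(),
               element = character(), charge = numeric(), radius = numeric(),
               stringsAsFactors = FALSE)
  new("ClaspStructure", atoms = atoms, sourceId = sourceId, model = 1L)
}
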