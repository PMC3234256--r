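mini_pdb <- c(
  "ATOM      1  N   SER A  70      11.104   6.134  -6.504  1.00  0.00           N",
  "ATOM      2  CA  SER A  70      12.010   6.900  -7.401  1.00  0.00           C",
  "ATOM      3  OG  SER A  70      13.500   7.500  -8.100  1.00  0.00           O",
  "TER", "END")

test_that("parses handcrafted PDB text and enforces the record policies", {
  s <- readPDB(mini_pdb)
  expect_s4_class(s, "ClaspStructure")
  expect_equal(nrow(atoms(s)), 3L)
  expect_equal(unique(atoms(s)$resid), "SER")
  expect_equal(atoms(s)$x[1], 11.104)

  # altloc: keep highest occupancy, ties by letter
  alt <- c(
    "ATOM      1  OG ASER A  70       1.000   0.000   0.000  0.60  0.00           O",
    "ATOM      2  OG BSER A  70       2.000   0.000   0.000  0.40  0.00           O",
    "END")
  sa <- readPDB(alt)
  expect_equal(nrow(atoms(sa)), 1L)
  expect_equal(atoms(sa)$x, 1.0)
  expect_equal(atoms(sa)$altloc, "A")

  # first model only
  multi <- c("MODEL     1", mini_pdb[1:3], "ENDMDL", "MODEL     2",
             sub("11.104", "99.000", mini_pdb[1]), "ENDMDL", "END")
  expect_equal(nrow(atoms(readPDB(multi))), 3L)

  expect_error(readPDB(c("HEADER junk", "END")), class = "claspParseError")
})

test_that("reactive atoms resolve deterministically with fallbacks", {
  cfg <- defaultReactiveConfig()
  s <- fixtureStructure("trypsin-1a0j")
  a <- atoms(s)
  ser <- a[a$resid == "SER", ]
  his <- a[a$resid == "HIS", ]
  asp <- a[a$resid == "ASP", ]
  expect_equal(reactiveAtom(ser, cfg)$name, "OG")
  expect_equal(reactiveAtom(his, cfg)$name, "NE2")
  expect_equal(reactiveAtom(asp, cfg)$name, "OD1")
  # pure function: repeated calls agree
  expect_identical(reactiveAtom(ser, cfg), reactiveAtom(ser, cfg))
  # fallback: His lacking NE2 falls back to ND1
  expect_equal(reactiveAtom(his[his$name != "NE2", ], cfg)$name, "ND1")
  # truncated side chain
  expect_error(reactiveAtom(ser[ser$name != "OG", ], cfg),
               class = "claspMissingAtomError")
})

test_that("reactive atoms for Lys and Arg follow the configured table", {
  txt <- makeToyStructure(
    data.frame(resid = c("LYS", "ARG", "THR"),
               x = c(0, 8, 4), y = c(0, 0, 6), z = c(0, 0, 0)))
  a <- atoms(readPDB(txt))
  cfg <- defaultReactiveConfig()
  expect_equal(reactiveAtom(a[a$resid == "LYS", ], cfg)$name, "NZ")
  expect_equal(reactiveAtom(a[a$resid == "ARG", ], cfg)$name, "NH1")
  expect_equal(reactiveAtom(a[a$resid == "THR", ], cfg)$name, "OG1")
})

test_that("charge assignment is static, neutral-complete, and strict", {
  s <- fixtureStructure("trypsin-1a0j")
  sp <- assignParameters(s)
  a <- atoms(sp)
  expect_equal(unique(a$charge[a$resid == "SER" & a$name == "OG"]), -0.49)
  expect_true(all(a$radius > 0))
  expect_true(all(abs(a$charge) <= 2))

  # neutral fixture: all-neutral residue types sum to exactly zero
  txt <- makeToyStructure(
    data.frame(resid = c("SER", "ASN", "ALA"),
               x = c(0, 8, 4), y = c(0, 0, 7), z = 0))
  neutral <- assignParameters(readPDB(txt))
  expect_equal(sum(atoms(neutral)$charge), 0)

  # formal charges: Asp -1 per residue
  aspSum <- sum(a$charge[a$resid == "ASP" & !a$name %in%
                           c("N", "CA", "C", "O")])
  expect_equal(aspSum, -1)

  # position independence: translation changes no parameter
  st <- transformStructure(s, t = c(30, -12, 5))
  expect_identical(atoms(assignParameters(st))$charge, a$charge)
  expect_identical(atoms(assignParameters(st))$radius, a$radius)

  # strict policy errors on an unparameterized ligand, naming it
  lig <- c(mini_pdb[1:3],
    "HETATM    4  C1  LIG A 900       5.000   5.000   5.000  1.00  0.00           C",
    "END")
  expect_error(assignParameters(readPDB(lig)),
               regexp = "LIG", class = "claspParameterizationError")
  # skip policy drops it with a warning
  expect_warning(sk <- assignParameters(readPDB(lig), policy = "skip"))
  expect_equal(nrow(atoms(sk)), 3L)
})

test_that("metal ions are retained, flagged and parameterized (+2)", {
  zn <- c(mini_pdb[1:3],
    "HETATM    4 ZN    ZN A 901       6.000   6.000   6.000  1.00  0.00          ZN",
    "END")
  s <- readPDB(zn)
  expect_true(any(atoms(s)$het))
  sp <- assignParameters(s)
  expect_equal(atoms(sp)$charge[atoms(sp)$het], 2)
  # configurable exclusion
  expect_false(any(atoms(assignParameters(s, excludeMetals = TRUE))$het))
})

test_that("PQR round trip preserves coordinates, charges and radii", {
  s <- assignParameters(fixtureStructure("blactamase", decoys = 4L))
  expect_gt(nrow(atoms(s)), 50L)
  lines <- writePQR(s)
  back <- readPQR(lines)
  a0 <- atoms(s); a1 <- atoms(back)
  expect_equal(nrow(a1), nrow(a0))
  expect_equal(a1$x, round(a0$x, 3))
  expect_equal(a1$charge, round(a0$charge, 4))
  expect_equal(a1$radius, round(a0$radius, 4))
  expect_equal(a1$chain, a0$chain)
  # second round trip is the identity
  expect_identical(writePQR(back), lines)

  # empty input -> header only
  empty <- new("ClaspStructure", atoms = atoms(s)[0, ], sourceId = "e",
               model = 1L)
  expect_true(all(grepl("^REMARK", writePQR(empty))))

  # one atom -> one record with 10 whitespace-delimited fields
  one <- new("ClaspStructure", atoms = atoms(s)[1, ], sourceId = "o",
             model = 1L)
  rec <- grep("^ATOM", writePQR(one), value = TRUE)
  expect_length(rec, 1L)
  expect_length(strsplit(trimws(rec), "[[:space:]]+")[[1]], 10L)
})
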