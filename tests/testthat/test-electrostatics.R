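test_that("zero total charge gives an identically zero potential", {
  fx <- makeChargeFixture("monopole")
  fx$charge <- 0
  g <- solvePotential(fx, testGridParams(h = 0.8), uniformDielectric = TRUE)
  expect_equal(max(abs(g@phi)), 0)
})

test_that("uniform-dielectric monopole matches the analytic Coulomb law", {
  fx <- makeChargeFixture("monopole")
  params <- new("GridParams", h = 0.5, padding = 10)
  g <- solvePotential(fx, params, uniformDielectric = TRUE)
  C <- clasp:::coulombConstant(298)
  # between 5 h and the boundary margin, in several directions
  for (r in seq(2.5, 7.5, by = 1)) {
    for (p in list(c(r, 0, 0), c(0, r, 0), c(0, 0, r),
                   r * c(1, 1, 1) / sqrt(3))) {
      ana <- C / (78 * r)
      expect_lt(abs(potentialAt(g, p) - ana) / ana, 0.05)
    }
  }
})

test_that("dipole potential vanishes on the perpendicular bisector plane", {
  g <- solvePotential(makeChargeFixture("dipole"), testGridParams(h = 0.5),
                      uniformDielectric = TRUE)
  for (p in list(c(0, 0, 0), c(0, 3, 0), c(0, -2, 4), c(0, 5, 5)))
    expect_lt(abs(potentialAt(g, p)), 1e-3)
})

test_that("trilinear interpolation honours nodes, midpoints and bounds", {
  g <- solvePotential(makeChargeFixture("monopole"), testGridParams(h = 0.8),
                      uniformDielectric = TRUE)
  # exactly on a node
  expect_equal(potentialAt(g, g@origin + c(3, 4, 5) * g@h),
               g@phi[4, 5, 6])
  # midpoint of two adjacent nodes along one axis
  expect_equal(potentialAt(g, g@origin + c(3.5, 4, 5) * g@h),
               (g@phi[4, 5, 6] + g@phi[5, 5, 6]) / 2)
  # outside -> bounds error
  expect_error(potentialAt(g, g@origin - 1), class = "claspBoundsError")
  expect_error(pairPD(g, g@origin + 5, g@origin - 1),
               class = "claspBoundsError")
})

test_that("pair PD is exactly antisymmetric and zero on identical atoms", {
  g <- fixtureGrid("trypsin-1a0j")
  a <- c(2, 1, 0.5) + g@origin + 10
  b <- c(6, 4, 3) + g@origin + 10
  expect_identical(pairPD(g, a, a), 0)
  expect_identical(pairPD(g, a, b), -pairPD(g, b, a))
})

test_that("solution is linear in the charges and offset-invariant in PDs", {
  fx <- makeChargeFixture("random", seed = 4L)
  params <- testGridParams(h = 0.7)
  g1 <- solvePotential(fx, params)
  fx2 <- fx
  fx2$charge <- 2 * fx$charge
  g2 <- solvePotential(fx2, params)
  pa <- c(1.5, 0.5, -1); pb <- c(-2, 3, 2)
  pd1 <- pairPD(g1, pa, pb)
  expect_gt(abs(pd1), 1e-3)  # non-degenerate probe
  expect_equal(pairPD(g2, pa, pb), 2 * pd1, tolerance = 1e-3)

  g3 <- solvePotential(fx, params, boundaryOffset = 7)
  expect_equal(pairPD(g3, pa, pb), pd1, tolerance = 1e-3)
  # and the potential itself is shifted by (about) the offset
  expect_equal(potentialAt(g3, pa) - potentialAt(g1, pa), 7,
               tolerance = 0.05)
})

test_that("pair PDs are stable under grid refinement", {
  # on the Coulomb (uniform-dielectric) fixture: node potentials are
  # grid-sensitive but differences on the same grid are not
  fx <- makeChargeFixture("monopole")
  pa <- c(4, 0, 0); pb <- c(0, -7, 0)  # both beyond 5 h of the charge
  pdCoarse <- pairPD(solvePotential(fx, testGridParams(h = 0.8),
                                    uniformDielectric = TRUE), pa, pb)
  pdFine <- pairPD(solvePotential(fx, testGridParams(h = 0.4),
                                  uniformDielectric = TRUE), pa, pb)
  expect_lt(abs(pdFine - pdCoarse) / abs(pdFine), 0.05)
})

test_that("two-dielectric solve converges and tracks the dielectric map", {
  s <- assignParameters(fixtureStructure("trypsin-1a0j"))
  g <- fixtureGrid("trypsin-1a0j")
  expect_true(all(is.finite(g@phi)))
  expect_setequal(unique(as.vector(g@eps)), c(2, 78))
  # solute region exists around atoms, solvent at the boundary
  expect_equal(g@eps[1, 1, 1], 78)
  a1 <- atoms(s)[1, ]
  ii <- round((c(a1$x, a1$y, a1$z) - g@origin) / g@h) + 1
  expect_equal(g@eps[ii[1], ii[2], ii[3]], 2)
})

test_that("pKa shifts convert charging energies with the acid/base sign", {
  expect_equal(estimatePka(10.4, 0), 10.4)
  # +2.303 kT destabilizing the deprotonated acid raises pKa by one unit
  expect_equal(estimatePka(4.0, log(10), siteIsAcid = TRUE), 5.0)
  expect_equal(estimatePka(10.4, log(10), siteIsAcid = FALSE), 9.4)
  expect_equal(estimatePka(7.0, 1, TRUE), 7.0 + 1 / log(10))
})

test_that("OpenDX grids round-trip through write/read", {
  g <- solvePotential(makeChargeFixture("dipole"), testGridParams(h = 0.9),
                      uniformDielectric = TRUE)
  tf <- tempfile(fileext = ".dx")
  writeDX(g, tf)
  back <- readDX(tf)
  expect_equal(back@dims, g@dims)
  expect_equal(back@origin, g@origin, tolerance = 1e-6)
  expect_equal(back@h, g@h, tolerance = 1e-6)
  expect_equal(back@phi, g@phi, tolerance = 1e-5)
})

test_that("external backend declares itself and passes parameters through", {
  params <- new("GridParams", h = 0.5)
  txt <- apbsInputText(params, "q.pqr", "pot.dx", c(65L, 65L, 65L),
                       c(-16, -16, -16))
  expect_true(any(grepl("pdie 2.000", txt)))
  expect_true(any(grepl("sdie 78.000", txt)))
  expect_true(any(grepl("srad 1.400", txt)))
  expect_true(any(grepl("temp 298", txt)))
  expect_true(any(grepl("dime 65 65 65", txt)))
  if (!externalBackendAvailable()) {
    expect_error(externalGrid("ATOM ...", params),
                 class = "claspBackendUnavailableError")
  } else {
    g <- externalGrid(makeToyStructure(fixtureSites("trypsin-1a0j")),
                      params)
    expect_s4_class(g, "PotentialGrid")
  }
})
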