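# Geometry I/O, canonical orientation and dimer construction.

test_that("XYZ round trip preserves a fixture geometry", {
  bz <- fixtureMolecule(fixture("benzene"))
  expect_equal(nAtoms(bz), 12L)
  expect_equal(molecularFormula(bz), "C6H6")
  path <- tempfile(fileext = ".xyz")
  writeXYZ(bz, path)
  back <- readXYZ(path)
  expect_equal(elements(back), elements(bz))
  expect_equal(coords(back), coords(bz), tolerance = 1e-9)
})

test_that("minimal and malformed XYZ inputs are handled", {
  p <- tempfile(fileext = ".xyz")
  writeLines(c("1", "", "He 0 0 0"), p)
  m <- readXYZ(p)
  expect_equal(nAtoms(m), 1L)
  expect_equal(unname(coords(m)[1, ]), c(0, 0, 0))

  writeLines(c("5", "comment", "H 0 0 0", "H 1 0 0", "H 2 0 0", "H 3 0 0"), p)
  expect_error(readXYZ(p), "declares 5 atoms")
  writeLines(c("2", "comment", "H 0 0 0", "H 1 zero 0"), p)
  expect_error(readXYZ(p), "line 4")
  writeLines(c("1", "", "Xx 0 0 0"), p)
  expect_error(validObject(readXYZ(p)), "unknown element")
})

test_that("canonical orientation is idempotent and matches an inertia-tensor oracle", {
  pen <- fixtureMolecule(fixture("pentacene"))
  again <- canonicalOrient(pen)
  expect_lt(max(abs(coords(again) - coords(pen))), 1e-10)

  # arbitrary rotation of benzene: re-orientation must diagonalize the
  # independently computed inertia tensor (unit masses)
  bz <- fixtureMolecule(fixture("benzene"))
  set.seed(42)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  rot <- molecule(elements(bz), coords(bz) %*% t(Q))
  re <- canonicalOrient(rot)
  x <- sweep(coords(re), 2, colMeans(coords(re)))
  r2 <- rowSums(x^2)
  inertia <- diag(sum(r2), 3) - crossprod(x)  # sum_i (r^2 I - r r^T)
  offdiag <- inertia - diag(diag(inertia))
  expect_lt(max(abs(offdiag)), 1e-8)
  # long axis along x: x extent >= y extent >= z extent
  ext <- apply(x, 2, function(v) diff(range(v)))
  expect_true(ext[1] >= ext[2] - 1e-8 && ext[2] >= ext[3] - 1e-8)
})

test_that("non-planar molecules are rejected with the deviation reported", {
  nh3 <- molecule(c("N", "H", "H", "H"),
                  matrix(c(0, 0, 0.11, 0.94, 0, -0.27, -0.47, 0.81, -0.27,
                           -0.47, -0.81, -0.27), 4, 3, byrow = TRUE))
  expect_error(canonicalOrient(nh3), "not planar")
  expect_false(isPlanar(nh3))
})

test_that("dimer construction obeys the translation contract", {
  bz <- fixtureMolecule(fixture("benzene"))
  arr <- buildDimer(bz, 0, 0, 3.4)
  mob <- mobileMolecule(arr)
  d <- coords(mob) - coords(bz)
  expect_lt(max(abs(d[, 1:2])), 1e-12)          # cofacial: only z differs
  expect_equal(unique(round(d[, 3], 10)), 3.4)
  expect_equal(elements(mob), elements(bz))     # atom ordering preserved

  # translation additivity
  a1 <- buildDimer(bz, 1.0 + 0.5, 0.2 + 0.3, 3.4)
  a2 <- buildDimer(bz, 1.0, 0.2, 3.4)
  m2 <- translateMolecule(mobileMolecule(a2), c(0.5, 0.3, 0))
  expect_equal(coords(mobileMolecule(a1)), coords(m2), tolerance = 1e-12)

  # intramonomer distances conserved exactly
  dist0 <- dist(coords(bz))
  expect_equal(as.vector(dist(coords(mob))), as.vector(dist0),
               tolerance = 1e-12)

  expect_error(buildDimer(bz, 0, 0, 0), "dz must be positive")
  expect_error(buildDimer(bz, 0, 0, -1), "dz must be positive")
})

test_that("opposite x-shifts give mirror-equivalent arrangements", {
  # for a D2h monomer, (dx = -1) maps onto (dx = +1) under the sigma_yz
  # reflection of the monomer
  pen <- fixtureMolecule(fixture("pentacene"))
  plus <- mobileMolecule(buildDimer(pen, 1.0, 0, 3.4))
  minus <- mobileMolecule(buildDimer(pen, -1.0, 0, 3.4))
  flipped <- coords(minus) %*% diag(c(-1, 1, 1))
  # same point set (atom order may differ under the reflection)
  ref <- coords(plus)
  matched <- vapply(seq_len(nrow(ref)), function(i) {
    any(rowSums(abs(sweep(flipped, 2, ref[i, ]))) < 1e-8)
  }, logical(1))
  expect_true(all(matched))
})

test_that("scan grids enumerate start + k*step", {
  g <- scanGrid("x", 0, 14, 0.1, dz = 3.4)
  arrs <- makeGrid(fixtureMolecule(fixture("benzene")), g)
  expect_length(arrs, 141L)
  expect_equal(gridShifts(g)[2], 0.1)

  gy <- scanGrid("x_at_fixed_y", 0, 1, 0.5, fixedDy = 1.0, dz = 3.4)
  arrs <- makeGrid(fixtureMolecule(fixture("benzene")), gy)
  expect_true(all(vapply(arrs, function(a) shifts(a)["dy"], numeric(1)) == 1.0))

  g1 <- scanGrid("y", 2, 2, 0.1, dz = 3.4)
  expect_length(makeGrid(fixtureMolecule(fixture("benzene")), g1), 1L)

  expect_error(scanGrid("x", 0, 1, 0.1, fixedDy = 1.0), "fixedDy")
  expect_error(scanGrid("x_at_fixed_y", 0, 1, 0.1), "fixedDy")
  expect_error(scanGrid("x", 1, 0, 0.1), "start")
  expect_error(scanGrid("x", 0, 1, -0.1), "step")
})
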