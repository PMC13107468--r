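# Scan pipeline: grids, feature detection, determinism, SAPT ingestion.

test_that("features of a sampled sine are found at the analytic positions", {
  d <- data.frame(shift = seq(0, 4, 0.1))
  d$y <- sin(pi * d$shift / 2)
  fr <- findFeatures(d, "y")
  expect_equal(featurePositions(fr, "zero")[featurePositions(fr, "zero") > 0.5],
               2.00, tolerance = 0.01)
  expect_equal(featurePositions(fr, "maximum"), 1.00, tolerance = 0.01)
  expect_equal(featurePositions(fr, "minimum"), 3.00, tolerance = 0.01)
})

test_that("a constant curve yields an empty report", {
  d <- data.frame(shift = seq(0, 2, 0.1), y = 1.0)
  expect_equal(nrow(featureTable(findFeatures(d, "y"))), 0L)
})

test_that("feature positions are stable under grid refinement", {
  coarse <- pibCurve(pibSpec(15, 6), seq(0, 15, 0.1), type = "pair",
                     n = 6, m = 6)
  fine <- pibCurve(pibSpec(15, 6), seq(0, 15, 0.05), type = "pair",
                   n = 6, m = 6)
  zc <- featurePositions(findFeatures(coarse, "s_b_6_6"), "zero")
  zf <- featurePositions(findFeatures(fine, "s_b_6_6"), "zero")
  expect_equal(length(zc), length(zf))
  expect_lt(max(abs(zc - zf)), 0.02)
})

test_that("scans are deterministic and reuse one monomer SCF", {
  h2 <- h2Molecule()
  g <- scanGrid("x", 0, 1.5, 0.5, dz = 3.4)
  s1 <- runScan(h2, g, "s:1,1", "sto-3g", densityFitting = FALSE)
  s2 <- runScan(h2, g, "s:1,1", "sto-3g", densityFitting = FALSE)
  expect_identical(scanData(s1), scanData(s2))
  p1 <- tempfile(); p2 <- tempfile()
  exportScan(s1, p1); exportScan(s2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("opposite shifts give reflection-equal observables", {
  eth <- ethyleneMolecule()
  neg <- runScan(eth, scanGrid("x", -1.0, 0, 0.5, dz = 3.4), "s2:pipi",
                 "sto-3g", densityFitting = FALSE)
  pos <- runScan(eth, scanGrid("x", 0, 1.0, 0.5, dz = 3.4), "s2:pipi",
                 "sto-3g", densityFitting = FALSE)
  expect_equal(rev(scanData(neg)$s2_pipi), scanData(pos)$s2_pipi,
               tolerance = 1e-8)
})

test_that("x_at_fixed_y scans keep the requested dy and failures are reported", {
  h2 <- h2Molecule()
  g <- scanGrid("x_at_fixed_y", 0, 0.6, 0.3, fixedDy = 0.4, dz = 3.4)
  sc <- runScan(h2, g, "s:1,1", "sto-3g", densityFitting = FALSE)
  expect_equal(nrow(scanData(sc)), 3L)
  expect_length(sc@provenance$failed, 0L)

  ws <- capture_warnings(
    bad <- runScan(h2, scanGrid("x", 0, 0.4, 0.2, dz = 3.4), "s:9S,9S",
                   "sto-3g", densityFitting = FALSE))
  expect_true(all(grepl("failed", ws)))
  expect_equal(length(bad@provenance$failed), 3L)
})

test_that("the shipped SAPT component table passes additivity ingestion", {
  path <- system.file("extdata", "sapt", "acene_sapt0.csv",
                      package = "pistack")
  sapt <- ingestSAPTTable(path)
  t <- saptTable(sapt)
  expect_equal(nrow(t), 20L)
  ben <- t[t$system == "Ben2" & t$dx == 0 & t$dy == 0, ]
  expect_equal(ben$Eint, 2.84)
  expect_lte(abs(ben$Eint - (ben$Eel + ben$Eind + ben$Edsp + ben$Eexch)), 0.01 + 1e-9)
})

test_that("SAPT ingestion rejects non-additive rows and warns on empty files", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("dx,dy,E_int,E_el,E_ind,E_dsp,E_exch",
               "0,0,10.0,-14.86,-2.41,-42.09,62.21"), p)
  expect_error(ingestSAPTTable(p), "additivity")
  writeLines("dx,dy,E_int,E_el,E_ind,E_dsp,E_exch", p)
  expect_warning(out <- ingestSAPTTable(p), "empty")
  expect_equal(nrow(saptTable(out)), 0L)
})
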