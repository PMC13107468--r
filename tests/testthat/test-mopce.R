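# Orbital-pair exchange decomposition: oracle equivalence, exact
# identities, groupings, and physical limits.

test_that("every component matches the brute-force oracle on the small fixtures", {
  cases <- list(
    list(ctx = function(dz) he2Context(dz), dzs = c(2.5, 3.0, 4.0),
         pairs = list(c(1, 1))),
    list(ctx = function(dz) h2DimerContext(dz), dzs = c(3.0, 3.4, 4.5),
         pairs = list(c(1, 1))),
    list(ctx = function(dz) ethyleneContext(dz), dzs = 3.4,
         pairs = list(c(8, 8), c(1, 5), c(3, 3))))
  for (cs in cases) for (dz in cs$dzs) {
    ctx <- cs$ctx(dz)
    for (p in cs$pairs) {
      main <- pairComponents(p[1], p[2], ctx)
      orc <- naivePairSum(p[1], p[2], ctx)
      for (cn in componentCols)
        expect_lt(abs(main[[cn]] - orc[[cn]]), 1e-10)
      expect_lt(abs(main$sAb - orc$sAb), 1e-10)
    }
  }
})

test_that("the component sum identity holds pair by pair to 1e-12 Hartree", {
  for (ctx in list(he2Context(3.0), h2DimerContext(3.4), ethyleneContext())) {
    t <- pairTable(ctx)@table
    resid <- t$eTotal - (t$eXi + t$eXr2 + t$eXr3 + t$eXr4 + t$eXrb)
    expect_lt(max(abs(resid)), 1e-12)
    # and the direct (undecomposed) evaluation agrees
    expect_lt(max(abs(t$eTotal - t$eTotalDirect)), 1e-12)
  }
})

test_that("table sums equal the sum of entries exactly", {
  pt <- pairTable(ethyleneContext())
  expect_identical(unname(pt@sums["exr"]), sum(pt@table$eTotal))
  expect_identical(unname(pt@sums["exi"]), sum(pt@table$eXi))
})

test_that("symmetry-forbidden pi pairs reduce to the (negative) exchange integral", {
  ctx <- benzeneContextSto()  # dy = 0 arrangement
  t <- labelTable(ctx@labelsA)
  iS <- which(t$sigmaPi == "pi" & t$parityXZ == "S")[1]
  iA <- which(t$sigmaPi == "pi" & t$parityXZ == "A")[1]
  pc <- pairComponents(iS, iA, ctx)
  expect_lt(abs(pc$sAb), 1e-10)
  expect_lt(abs(pc$eTotal - pc$eXi), 1e-12)
  expect_lte(pc$eXi, 1e-12)
})

test_that("all components vanish at large separation", {
  far <- mopceContext(buildDimer(heMolecule(), 0, 0, 50), "cc-pvdz",
                      densityFitting = FALSE)
  t <- pairTable(far)@table
  expect_lt(max(abs(as.matrix(t[, componentCols]))), 1e-12)
})

test_that("the pair table of a cofacial identical-monomer dimer is exchange symmetric", {
  ctx <- ethyleneContext()
  m <- pistack:::.mopceMatrices(ctx)
  expect_lt(max(abs(m$total - t(m$total))), 1e-10)
})

test_that("the basis-set error term vanishes in the counterpoise basis", {
  ctxg <- h2DimerContext(3.4, mode = "dimer_ghost")
  pt <- pairTable(ctxg)
  expect_lt(sum(abs(pt@table$eXrb)), 1e-6)
  # and there the canonical and potential forms of the two-index term agree
  m <- pistack:::.mopceMatrices(ctxg)
  expect_lt(max(abs(m$exr2Canon - m$exr2)), 1e-10)
})

test_that("in the monomer basis the canonical two-index form differs from the potential form by exactly the basis-error term", {
  for (ctx in list(he2Context(3.0), ethyleneContext())) {
    m <- pistack:::.mopceMatrices(ctx)
    expect_lt(max(abs(m$exr2Canon - m$exr2 + m$exrb)), 1e-12)
  }
})

test_that("group sums partition the total exactly", {
  ctx <- benzeneContextSto()
  pt <- pairTable(ctx)
  gs <- groupSums(pt, ctx@labelsA, ctx@labelsB)
  expect_lt(abs(gs@ePiPi + gs@ePiSigma + gs@eSigmaSigma - gs@eTotal), 1e-10)
  expect_lt(abs(gs@ePiSPiS + gs@ePiAPiA + gs@ePiSPiA - gs@ePiPi), 1e-10)
  expect_lt(abs(gs@eTotal - exchangeRepulsion(pt) * 2625.499639), 1e-8)
})

test_that("squared-overlap sums are nonnegative and the diagonal dominates cofacially", {
  ctx <- benzeneContextSto()
  s2 <- squaredOverlapSums(ctx@Sab, ctx@labelsA, ctx@labelsB)
  expect_true(all(s2$s2 >= 0))
  cof <- ethyleneContext()
  t <- labelTable(cof@labelsA)
  a <- which(t$sigmaPi == "pi")[1]
  expect_equal(which.max(cof@Sab[a, ]^2), a)
})

test_that("single-orbital monomers reduce the four-index term to its closed form", {
  ctx <- h2DimerContext(3.4)
  pc <- pairComponents(1, 1, ctx)
  g <- ctx@mo$g; h <- ctx@mo$h
  s <- ctx@Sab[1, 1]
  expect_lt(abs(pc$eXr4 -
                2 * s * (4 * g[1, 1, 1, 1] - g[1, 1, 1, 1] - h[1, 1, 1, 1]) * s),
            1e-14)
})

test_that("the MOPCE total tracks the independent Heitler-London exchange", {
  for (cfg in list(list(he2Context(3.0)), list(he2Context(4.0)),
                   list(h2DimerContext(3.4)), list(h2DimerContext(4.5)))) {
    ctx <- cfg[[1]]
    hl <- hlS2Exchange(ctx)
    xr <- exchangeRepulsion(pairTable(ctx))
    expect_lt(abs(xr - hl) / abs(hl), 0.05)
    expect_identical(sign(xr), sign(hl))
  }
  # separated limit: both vanish
  far <- mopceContext(buildDimer(heMolecule(), 0, 0, 50), "cc-pvdz",
                      densityFitting = FALSE)
  expect_lt(abs(hlS2Exchange(far)), 1e-12)
  expect_lt(abs(exchangeRepulsion(pairTable(far))), 1e-12)
})

test_that("exchange repulsion decays monotonically with separation", {
  dzs <- c(3.0, 4.0, 5.0, 6.0)
  xr <- vapply(dzs, function(dz) exchangeRepulsion(pairTable(h2DimerContext(dz))),
               numeric(1))
  hl <- vapply(dzs, function(dz) hlS2Exchange(h2DimerContext(dz)), numeric(1))
  expect_true(all(diff(xr) < 0))
  expect_true(all(diff(hl) < 0))
})

test_that("the total exchange repulsion is positive at stacking distance", {
  for (ctx in list(he2Context(3.0), h2DimerContext(3.4), ethyleneContext(),
                   benzeneContextSto()))
    expect_gt(exchangeRepulsion(pairTable(ctx)), 0)
})

test_that("pair components reject out-of-range orbital indices", {
  ctx <- h2DimerContext(3.4)
  expect_error(pairComponents(0, 1, ctx), "out of the occupied range")
  expect_error(pairComponents(1, 5, ctx), "out of the occupied range")
})

test_that("the two-index term is proportional to the squared overlap along an x scan", {
  dxs <- seq(0, 2.5, 0.5)
  ctxs <- lapply(dxs, function(d) benzeneContextSto(d))
  t0 <- labelTable(ctxs[[1]]@labelsA)
  ipi <- which(t0$sigmaPi == "pi")
  for (a in ipi) {
    e2 <- vapply(ctxs, function(c) pairComponents(a, a, c)$eXr2, numeric(1))
    s2 <- vapply(ctxs, function(c) pairComponents(a, a, c)$sAbSq, numeric(1))
    expect_gt(cor(e2, s2), 0.99)
  }
})

test_that("density fitting changes no component beyond its error budget", {
  arr <- buildDimer(h2Molecule(), 0, 0, 3.4)
  conv <- pairTable(mopceContext(arr, "jun-cc-pvdz", densityFitting = FALSE))
  dfb <- pairTable(mopceContext(arr, "jun-cc-pvdz", densityFitting = TRUE))
  for (cn in componentCols)
    expect_lt(max(abs(conv@table[[cn]] - dfb@table[[cn]])), 1e-5)
})

test_that("pair table CSV export uses the documented schema", {
  path <- tempfile(fileext = ".csv")
  exportPairTable(pairTable(h2DimerContext(3.4)), path)
  out <- read.csv(path)
  expect_named(out, c("a_index", "b_index", "a_label", "b_label", "s_ab",
                      "s_ab_sq", "e_xi", "e_xr2", "e_xr3", "e_xr4", "e_xrb",
                      "e_total", "e_rep"))
})
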