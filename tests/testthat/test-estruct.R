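# Electronic-structure backend: SCF solutions, operator matrices and
# occupied-MO integrals.

test_that("RHF matches an independently coded textbook SCF on H2", {
  h2 <- h2Molecule()
  eng <- runRHF(h2, "sto-3g", densityFitting = FALSE)
  orc <- oracleRHF(h2, "sto-3g")
  expect_lt(abs(totalEnergy(eng) - orc$energy), 1e-8)
  expect_equal(nOccupied(eng), 1L)
  # occupied orbital energy too
  expect_lt(abs(orbitalEnergies(eng)[1] - orc$eps[1]), 1e-7)
})

test_that("occupied MOs are orthonormal under the AO overlap", {
  for (cfg in list(list(ethyleneMolecule(), "sto-3g"),
                   list(h2Molecule(), "cc-pvdz"))) {
    scf <- runRHF(cfg[[1]], cfg[[2]], densityFitting = FALSE)
    sh <- pistack:::buildShells(cfg[[1]]@elements, cfg[[1]]@coords, cfg[[2]])
    S <- pistack:::cpp_oneint(sh)$S
    C <- occupiedCoefficients(scf)
    expect_lt(max(abs(crossprod(C, S %*% C) - diag(ncol(C)))), 1e-8)
  }
})

test_that("electron counting fixes the occupied space", {
  expect_equal(nOccupied(benzeneScfSto()), 21L)
  expect_error(runRHF(molecule("H", matrix(0, 1, 3)), "sto-3g"),
               "even electron count")
  expect_error(runRHF(ethyleneMolecule(), "no-such-basis"), "unknown basis")
})

test_that("operator matrices satisfy their construction identities", {
  ctx <- ethyleneContext()
  ops <- ctx@ops
  # Hermiticity
  for (nm in c("S", "T", "vA", "vB", "JA", "KA", "JB", "KB", "F", "FA", "FB"))
    expect_lt(max(abs(slot(ops, nm) - t(slot(ops, nm)))), 1e-10)
  # F = FA + vB + 2 JB - KB elementwise
  expect_lt(max(abs(ops@F - (ops@FA + ops@vB + 2 * ops@JB - ops@KB))), 1e-12)
  # C_A' F_A C_A diagonal with the monomer orbital energies
  nbf <- nrow(ops@S)
  CA <- pistack:::.padOccupied(ctx@labelsA, nbf, "A")
  M <- crossprod(CA, ops@FA %*% CA)
  expect_lt(max(abs(M - diag(orbitalEnergies(ctx@scfA)))), 1e-7)
})

test_that("cross-monomer blocks vanish at large separation", {
  he <- heMolecule()
  arr <- buildDimer(he, 0, 0, 50)
  sh <- pistack:::.dimerShells(arr, "cc-pvdz")
  S <- pistack:::cpp_oneint(sh)$S
  n <- attr(sh, "nbf") / 2
  expect_lt(max(abs(S[seq_len(n), n + seq_len(n)])), 1e-12)
})

test_that("occupied ERI blocks match a naive loop transform and are positive on exchange diagonals", {
  ctx <- he2Context(3.0)
  blk <- occERIBlock(ctx@labelsA, ctx@labelsB, "cc-pvdz", ctx@arrangement,
                     densityFitting = FALSE)
  # independent path: oracle AO integrals + explicit four-index loops
  orc <- pistack:::.oracleDimerInts(ctx@arrangement, "cc-pvdz")
  perm <- pistack:::.oracleAOPerm(pistack:::.dimerShells(ctx@arrangement,
                                                        "cc-pvdz"))
  nbf <- orc$nbf
  CA <- pistack:::.padOccupied(ctx@labelsA, nbf, "A")
  CB <- pistack:::.padOccupied(ctx@labelsB, nbf, "B")
  CAo <- matrix(0, nbf, ncol(CA)); CAo[perm, ] <- CA
  CBo <- matrix(0, nbf, ncol(CB)); CBo[perm, ] <- CB
  gref <- 0
  for (mu in 1:nbf) for (nu in 1:nbf) for (la in 1:nbf) for (si in 1:nbf)
    gref <- gref + CAo[mu, 1] * CBo[nu, 1] * CAo[la, 1] * CBo[si, 1] *
      orc$eri[mu, nu, la, si]
  expect_lt(abs(blk@g[1, 1, 1, 1] - gref), 1e-10)
  # exchange diagonals (ab|ba) = (ab|ab) >= 0
  expect_gte(blk@g[1, 1, 1, 1], -1e-12)
  ctx2 <- ethyleneContext()
  gd <- vapply(seq_len(ctx2@mo$nA), function(a)
    min(vapply(seq_len(ctx2@mo$nB), function(b) ctx2@mo$g[a, b, a, b],
               numeric(1))), numeric(1))
  expect_true(all(gd >= -1e-12))
})

test_that("density fitting reproduces conventional occupied integrals within its tolerance", {
  h2 <- h2Molecule()
  arr <- buildDimer(h2, 0, 0, 3.4)
  scf <- runRHF(h2, "jun-cc-pvdz", densityFitting = FALSE)
  lab <- fixPhases(classifyOrbitals(scf))
  conv <- occERIBlock(lab, lab, "jun-cc-pvdz", arr, densityFitting = FALSE)
  dfb <- occERIBlock(lab, lab, "jun-cc-pvdz", arr, densityFitting = TRUE)
  expect_lt(max(abs(conv@g - dfb@g)), 1e-5)
  expect_lt(max(abs(conv@h - dfb@h)), 1e-5)
})

test_that("rigid translation of the whole dimer leaves MO quantities invariant", {
  he <- heMolecule()
  ctx1 <- mopceContext(buildDimer(he, 0, 0, 3.0), "cc-pvdz",
                       densityFitting = FALSE)
  shifted <- translateMolecule(he, c(1.3, -0.4, 0))
  ctx2 <- mopceContext(buildDimer(shifted, 0, 0, 3.0), "cc-pvdz",
                       densityFitting = FALSE)
  expect_lt(max(abs(ctx1@Sab - ctx2@Sab)), 1e-9)
  p1 <- pairComponents(1, 1, ctx1)
  p2 <- pairComponents(1, 1, ctx2)
  expect_lt(max(abs(unlist(p1[componentCols]) - unlist(p2[componentCols]))),
            1e-9)
})

test_that("the integral memory cap triggers a refusal with the estimate", {
  expect_error(
    pistack:::cpp_eri_packed(pistack:::buildShells(
      fixtureMolecule(fixture("benzene"))@elements,
      fixtureMolecule(fixture("benzene"))@coords, "sto-3g"), 1e-13, 1e-4),
    "GiB")
})
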