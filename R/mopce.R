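# Molecular Orbital-Pair Contributions to the Exchange repulsion (MOPCE).
#
# For occupied orbitals a (monomer A) and b (monomer B) the pair term is
#
#   E_xr(a,b) = -2(ab|ba) + 2 S_ab { -2(a|F|b) + sum_a' (a|F|a') S_a'b
#               + sum_b' S_ab' (b'|F|b)
#               + sum_a'b' [4(ab|a'b') - (ab'|a'b) - (aa'|bb')] S_a'b' }
#
# with F the dimer Fock operator built from the two frozen monomer
# densities.  The term decomposes exactly into the exchange-integral part
# E_xi, the two-index part E_xr2 (evaluated through the monomer effective
# potentials), the three-index part E_xr3, the four-index part E_xr4 and
# the basis-set error term E_xrb, which vanishes identically in the
# counterpoise (dimer_ghost) basis.  The pair attribution of the three- and
# four-index terms follows the outer S_ab factor.

#' Assemble a MOPCE evaluation context for one arrangement
#'
#' Runs (or reuses) the monomer SCF, classifies and phase-fixes the
#' occupied orbitals, and computes every occupied-MO operator block and
#' two-electron integral the pair decomposition needs, for one arrangement
#' and one basis mode.
#'
#' In the default `monomer` mode each monomer's orbitals are solved in its
#' own AO basis and embedded in the dimer basis by zero padding; the mobile
#' monomer's SCF is never recomputed -- its MO coefficients are the fixed
#' monomer's coefficients attached to the translated basis centers, which
#' makes cross-overlap signs well defined.  In `dimer_ghost`
#' (counterpoise) mode each monomer is solved in the full dimer basis with
#' ghost partner centers; the basis-set error term then vanishes.
#'
#' @param arrangement a [DimerArrangement].
#' @param basis a [BasisSpec] or basis name.
#' @param mode "monomer" (default) or "dimer_ghost".
#' @param densityFitting logical or NULL (auto: on above 150 dimer AO
#'   functions).
#' @param maxGb integral memory cap (GiB).
#' @return a [MOPCEContext].
#' @export
mopceContext <- function(arrangement, basis,
                         mode = c("monomer", "dimer_ghost"),
                         densityFitting = NULL, maxGb = 4) {
  mode <- match.arg(mode)
  if (!is(basis, "BasisSpec")) basis <- basisSpec(basis)
  mol <- arrangement@fixed
  mob <- mobileMolecule(arrangement)

  if (mode == "monomer") {
    scfA <- runRHFCached(mol, basis, densityFitting = densityFitting,
                         maxGb = maxGb)
    labA <- fixPhases(classifyOrbitals(scfA))
    scfB <- scfA  # translated copy shares coefficients and energies
    labB <- labA
  } else {
    scfA <- runRHFCached(mol, basis, ghost = mob, ghostFirst = FALSE,
                         densityFitting = densityFitting, maxGb = maxGb)
    scfB <- runRHFCached(mob, basis, ghost = mol, ghostFirst = TRUE,
                         densityFitting = densityFitting, maxGb = maxGb)
    labA <- fixPhases(classifyOrbitals(scfA, mol))
    labB <- fixPhases(classifyOrbitals(scfB, mob))
  }

  shells <- .dimerShells(arrangement, basis@name)
  nbf <- attr(shells, "nbf")
  df <- .useDF(basis, nbf, densityFitting)
  one <- cpp_oneint(shells)
  ZA <- elementZ(mol@elements)
  vA <- cpp_nucattr(shells, ZA, mol@coords * BOHR_PER_ANGSTROM)
  vB <- cpp_nucattr(shells, elementZ(mob@elements),
                    mob@coords * BOHR_PER_ANGSTROM)

  CA <- .padOccupied(labA, nbf, "A")
  CB <- .padOccupied(labB, nbf, "B")
  Cu <- cbind(CA, CB)
  nA <- ncol(CA); nB <- ncol(CB); K <- nA + nB
  iA <- seq_len(nA); iB <- nA + seq_len(nB)

  mo <- list(nA = nA, nB = nB, nbf = nbf, Cu = Cu,
             S = crossprod(Cu, one$S %*% Cu),
             T = crossprod(Cu, one$T %*% Cu),
             vA = crossprod(Cu, vA %*% Cu),
             vB = crossprod(Cu, vB %*% Cu),
             epsA = labA@table$energy, epsB = labB@table$energy,
             cache = new.env(parent = emptyenv()))
  ops <- NULL

  if (!df) {
    eri <- cpp_eri_packed(shells, 1e-13, maxGb)
    G <- .unpackERI(eri, nbf)
    umo <- .transformERI(G, Cu, Cu, Cu, Cu)
    JA <- KA <- JB <- KB <- matrix(0, K, K)
    for (a in iA) {
      JA <- JA + umo[, , a, a]
      KA <- KA + umo[, a, a, ]
    }
    for (b in iB) {
      JB <- JB + umo[, , b, b]
      KB <- KB + umo[, b, b, ]
    }
    mo$umo <- umo
    mo$g <- umo[iA, iB, iA, iB, drop = FALSE]
    mo$h <- umo[iA, iA, iB, iB, drop = FALSE]
    # AO-level operator matrices come for free on this route
    DA <- tcrossprod(CA); DB <- tcrossprod(CB)
    jkA <- cpp_jk_packed(eri, DA); jkB <- cpp_jk_packed(eri, DB)
    FAao <- one$T + vA + 2 * jkA$J - jkA$K
    FBao <- one$T + vB + 2 * jkB$J - jkB$K
    ops <- new("OperatorMatrices", S = one$S, T = one$T, vA = vA, vB = vB,
               JA = jkA$J, KA = jkA$K, JB = jkB$J, KB = jkB$K,
               F = FAao + vB + 2 * jkB$J - jkB$K, FA = FAao, FB = FBao,
               basisMode = mode, densityFitting = FALSE)
  } else {
    aux <- buildAuxShells(c(mol@elements, mob@elements),
                          rbind(mol@coords, mob@coords),
                          basis@name, basis@auxName)
    L <- .metricChol(cpp_metric2c(aux))
    V <- forwardsolve(L, .moPairsRaw(shells, aux, Cu, maxGb))
    # naux x K^2, col = x + (y-1) K
    colix <- function(x, y) x + (y - 1L) * K
    KA <- KB <- matrix(0, K, K)
    v0A <- rowSums(V[, vapply(iA, function(a) colix(a, a), integer(1)),
                     drop = FALSE])
    v0B <- rowSums(V[, vapply(iB, function(b) colix(b, b), integer(1)),
                     drop = FALSE])
    JA <- matrix(crossprod(V, v0A), K, K)
    JB <- matrix(crossprod(V, v0B), K, K)
    for (a in iA) KA <- KA + crossprod(V[, colix(seq_len(K), a), drop = FALSE])
    for (b in iB) KB <- KB + crossprod(V[, colix(seq_len(K), b), drop = FALSE])
    Vab <- V[, as.vector(outer(iA, iB, colix)), drop = FALSE]
    Vaa <- V[, as.vector(outer(iA, iA, colix)), drop = FALSE]
    Vbb <- V[, as.vector(outer(iB, iB, colix)), drop = FALSE]
    mo$g <- array(crossprod(Vab), c(nA, nB, nA, nB))
    mo$h <- array(crossprod(Vaa, Vbb), c(nA, nA, nB, nB))
  }
  mo$JA <- JA; mo$KA <- KA; mo$JB <- JB; mo$KB <- KB
  mo$FA <- mo$T + mo$vA + 2 * JA - KA
  mo$FB <- mo$T + mo$vB + 2 * JB - KB
  mo$F <- mo$FA + mo$vB + 2 * JB - KB

  new("MOPCEContext", arrangement = arrangement, basis = basis, mode = mode,
      densityFitting = df, scfA = scfA, scfB = scfB, labelsA = labA,
      labelsB = labB, Sab = mo$S[iA, iB, drop = FALSE], mo = mo, ops = ops)
}

setMethod("show", "MOPCEContext", function(object) {
  cat(sprintf(
    "MOPCEContext: %s dimer at (dx=%.2f, dy=%.2f, dz=%.2f) A, %s/%s mode,\n  %d x %d occupied pairs, density fitting %s\n",
    molecularFormula(object@arrangement@fixed), object@arrangement@dx,
    object@arrangement@dy, object@arrangement@dz, object@basis@name,
    object@mode, object@mo$nA, object@mo$nB,
    if (object@densityFitting) "on" else "off"))
})

# all pairwise component matrices (memoized on the context)
.mopceMatrices <- function(ctx) {
  cache <- ctx@mo$cache
  if (!is.null(cache$mat)) return(cache$mat)
  mo <- ctx@mo
  nA <- mo$nA; nB <- mo$nB
  iA <- seq_len(nA); iB <- nA + seq_len(nB)
  S <- ctx@Sab
  Tab <- mo$T[iA, iB, drop = FALSE]
  Fab <- mo$F[iA, iB, drop = FALSE]
  FAAu <- mo$F[iA, iA, drop = FALSE]
  FBBu <- mo$F[iB, iB, drop = FALSE]
  FA_ab <- mo$FA[iA, iB, drop = FALSE]
  FA_aa <- mo$FA[iA, iA, drop = FALSE]
  FB_ab <- mo$FB[iA, iB, drop = FALSE]
  FB_bb <- mo$FB[iB, iB, drop = FALSE]
  VA_ab <- FA_ab - Tab
  VB_ab <- FB_ab - Tab
  VB_aa <- mo$FB[iA, iA, drop = FALSE] - mo$T[iA, iA, drop = FALSE]
  VA_bb <- mo$FA[iB, iB, drop = FALSE] - mo$T[iB, iB, drop = FALSE]

  g <- mo$g; h <- mo$h
  gdiag <- matrix(0, nA, nB)
  X1 <- X2 <- X3 <- matrix(0, nA, nB)
  tS <- t(S)
  for (a in iA) for (b in seq_len(nB)) {
    gdiag[a, b] <- g[a, b, a, b]
    X1[a, b] <- sum(g[a, b, , ] * S)        # sum_{a'b'} (ab|a'b') S_a'b'
    X2[a, b] <- sum(g[a, , , b] * tS)       # sum_{a'b'} (ab'|a'b) S_a'b'
    X3[a, b] <- sum(h[a, , b, ] * S)        # sum_{a'b'} (aa'|bb') S_a'b'
  }
  X4 <- 4 * X1 - X2 - X3

  exi <- -2 * gdiag
  exr2 <- -2 * S * (VA_ab + VB_ab)                       # Eq of the monomer potentials
  exr3 <- 2 * S * (VB_aa %*% S + S %*% VA_bb)
  exrb <- 2 * S * (-FA_ab + FA_aa %*% S - FB_ab + S %*% FB_bb)
  exr4 <- 2 * S * X4
  total <- exi + exr2 + exr3 + exr4 + exrb
  totalDirect <- exi + 2 * S * (-2 * Fab + FAAu %*% S + S %*% FBBu + X4)

  # canonical two-index diagnostic: -2(eps_a+eps_b)S^2 + 2 S * (2 T_ab);
  # equals the potential form minus E_xrb exactly (E_xrb = 0 in the ghost
  # basis, where the two expressions therefore coincide)
  epsS <- outer(mo$epsA, mo$epsB, `+`)
  exr2Canon <- -2 * epsS * S^2 + 4 * S * Tab
  canonResidual <- exr2Canon - exr2 + exrb
  # with density fitting the monomer SCF and the dimer operators use
  # different (monomer vs dimer) fitting sets; allow the DF error budget
  canonTol <- if (ctx@densityFitting) 1e-5 else 1e-7
  if (max(abs(canonResidual)) > canonTol)
    stop(sprintf(
      "two-index consistency violated: max |canonical - potential - basis-error| = %.3e Hartree",
      max(abs(canonResidual))))

  cache$mat <- list(S = S, exi = exi, exr2 = exr2, exr3 = exr3, exr4 = exr4,
                    exrb = exrb, total = total, totalDirect = totalDirect,
                    exr2Canon = exr2Canon, erep = total - exi)
  cache$mat
}

#' Evaluate one orbital-pair contribution
#'
#' @param a,b occupied orbital indices (energy order) on monomers A and B.
#' @param ctx a [MOPCEContext].
#' @return one-row data.frame with s_ab, s_ab^2 and every component in
#'   Hartree (columns `eXi`, `eXr2`, `eXr3`, `eXr4`, `eXrb`, `eTotal`,
#'   `eRep`), plus diagnostics `eTotalDirect` (Eq-level direct evaluation)
#'   and `eXr2Canon` (orbital-energy form of the two-index term).
#' @export
pairComponents <- function(a, b, ctx) {
  mo <- ctx@mo
  if (a < 1 || a > mo$nA || b < 1 || b > mo$nB)
    stop("orbital indices out of the occupied range (a in 1..", mo$nA,
         ", b in 1..", mo$nB, ")")
  m <- .mopceMatrices(ctx)
  data.frame(a = a, b = b, sAb = m$S[a, b], sAbSq = m$S[a, b]^2,
             eXi = m$exi[a, b], eXr2 = m$exr2[a, b], eXr3 = m$exr3[a, b],
             eXr4 = m$exr4[a, b], eXrb = m$exrb[a, b],
             eTotal = m$total[a, b], eRep = m$erep[a, b],
             eTotalDirect = m$totalDirect[a, b],
             eXr2Canon = m$exr2Canon[a, b])
}

.designation <- function(tab) {
  ifelse(tab$sigmaPi == "pi" & !is.na(tab$classRank),
         paste0(tab$classRank, tab$parityXZ),
         ifelse(tab$sigmaPi == "pi", "pi", "sigma"))
}

#' Evaluate the full orbital-pair table
#'
#' All (a, b) occupied pairs in fixed row-major order (a outer, b inner);
#' the stored component sums are accumulated in the same order, so the
#' "sum of entries equals stored sum" identity is exact.
#'
#' @param ctx a [MOPCEContext].
#' @return a [MOPCEPairTable]; component columns in Hartree.
#' @export
pairTable <- function(ctx) {
  m <- .mopceMatrices(ctx)
  mo <- ctx@mo
  nA <- mo$nA; nB <- mo$nB
  a <- rep(seq_len(nA), each = nB)
  b <- rep(seq_len(nB), times = nA)
  ij <- cbind(a, b)
  dA <- .designation(ctx@labelsA@table)
  dB <- .designation(ctx@labelsB@table)
  tab <- data.frame(
    a = a, b = b,
    aClass = ctx@labelsA@table$sigmaPi[a], bClass = ctx@labelsB@table$sigmaPi[b],
    aDesig = dA[a], bDesig = dB[b],
    sAb = m$S[ij], sAbSq = m$S[ij]^2,
    eXi = m$exi[ij], eXr2 = m$exr2[ij], eXr3 = m$exr3[ij],
    eXr4 = m$exr4[ij], eXrb = m$exrb[ij], eTotal = m$total[ij],
    eRep = m$erep[ij], eTotalDirect = m$totalDirect[ij],
    stringsAsFactors = FALSE)
  sums <- c(exi = sum(tab$eXi), exr2 = sum(tab$eXr2), exr3 = sum(tab$eXr3),
            exr4 = sum(tab$eXr4), exrb = sum(tab$eXrb),
            exr = sum(tab$eTotal))
  new("MOPCEPairTable", table = tab, sums = sums, mode = ctx@mode,
      densityFitting = ctx@densityFitting)
}

#' @describeIn pairTable total exchange repulsion (Hartree)
#' @param x a MOPCEPairTable.
#' @export
exchangeRepulsion <- function(x) unname(x@sums["exr"])

setMethod("show", "MOPCEPairTable", function(object) {
  cat(sprintf(
    "MOPCEPairTable: %d orbital pairs (%s mode)\n  E_xr = %.6f Hartree = %.2f kJ/mol\n  components (kJ/mol): E_xi %.2f, E_xr2 %.2f, E_xr3 %.2f, E_xr4 %.2f, E_xrb %.2f\n",
    nrow(object@table), object@mode, object@sums["exr"],
    object@sums["exr"] * KJMOL_PER_HARTREE,
    object@sums["exi"] * KJMOL_PER_HARTREE,
    object@sums["exr2"] * KJMOL_PER_HARTREE,
    object@sums["exr3"] * KJMOL_PER_HARTREE,
    object@sums["exr4"] * KJMOL_PER_HARTREE,
    object@sums["exrb"] * KJMOL_PER_HARTREE))
})

#' Export the pair table as CSV (kJ/mol)
#'
#' @param x a [MOPCEPairTable].
#' @param path output path.
#' @return invisibly, the path.
#' @export
exportPairTable <- function(x, path) {
  t <- x@table
  out <- data.frame(a_index = t$a, b_index = t$b, a_label = t$aDesig,
                    b_label = t$bDesig, s_ab = t$sAb, s_ab_sq = t$sAbSq,
                    e_xi = t$eXi * KJMOL_PER_HARTREE,
                    e_xr2 = t$eXr2 * KJMOL_PER_HARTREE,
                    e_xr3 = t$eXr3 * KJMOL_PER_HARTREE,
                    e_xr4 = t$eXr4 * KJMOL_PER_HARTREE,
                    e_xrb = t$eXrb * KJMOL_PER_HARTREE,
                    e_total = t$eTotal * KJMOL_PER_HARTREE,
                    e_rep = t$eRep * KJMOL_PER_HARTREE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Group orbital-pair contributions into the class sums
#'
#' Produces the pi-pi / pi-sigma / sigma-sigma partition, the split of the
#' pi-pi part into symmetric/antisymmetric mirror classes, and the matching
#' grouped squared-overlap sums.  Energies are reported in kJ/mol.
#'
#' @param table a [MOPCEPairTable].
#' @param labA,labB the [LabeledOrbitals] the table was built from.
#' @return a [GroupedExchange].
#' @export
groupSums <- function(table, labA, labB) {
  t <- table@table
  nA <- max(t$a); nB <- max(t$b)
  if (nA != nrow(labA@table) || nB != nrow(labB@table))
    stop("label tables do not match the pair table dimensions")
  kj <- KJMOL_PER_HARTREE
  piA <- t$aClass == "pi"; piB <- t$bClass == "pi"
  pS <- labA@table$parityXZ[t$a] == "S" & labA@table$sigmaPi[t$a] == "pi"
  pA <- labA@table$parityXZ[t$a] == "A" & labA@table$sigmaPi[t$a] == "pi"
  qS <- labB@table$parityXZ[t$b] == "S" & labB@table$sigmaPi[t$b] == "pi"
  qA <- labB@table$parityXZ[t$b] == "A" & labB@table$sigmaPi[t$b] == "pi"
  new("GroupedExchange",
      ePiPi = sum(t$eTotal[piA & piB]) * kj,
      ePiSigma = sum(t$eTotal[xor(piA, piB)]) * kj,
      eSigmaSigma = sum(t$eTotal[!piA & !piB]) * kj,
      ePiSPiS = sum(t$eTotal[pS & qS]) * kj,
      ePiAPiA = sum(t$eTotal[pA & qA]) * kj,
      ePiSPiA = sum(t$eTotal[(pS & qA) | (pA & qS)]) * kj,
      s2PiPi = sum(t$sAbSq[piA & piB]),
      s2PiSPiS = sum(t$sAbSq[pS & qS]),
      s2PiAPiA = sum(t$sAbSq[pA & qA]),
      s2PiSPiA = sum(t$sAbSq[(pS & qA) | (pA & qS)]),
      eTotal = sum(t$eTotal) * kj)
}

setMethod("show", "GroupedExchange", function(object) {
  cat(sprintf(
    "GroupedExchange (kJ/mol): E_xr = %.2f\n  pi-pi %.2f | pi-sigma %.2f | sigma-sigma %.2f\n  piS-piS %.2f | piA-piA %.2f | piS-piA %.2f\n  S^2: pi-pi %.4f (SS %.4f, AA %.4f, SA %.4f)\n",
    object@eTotal, object@ePiPi, object@ePiSigma, object@eSigmaSigma,
    object@ePiSPiS, object@ePiAPiA, object@ePiSPiA, object@s2PiPi,
    object@s2PiSPiS, object@s2PiAPiA, object@s2PiSPiA))
})

#' Grouped squared-overlap sums
#'
#' Per-pair squared overlaps S^2(a,b) and their sums over the pi classes,
#' mirroring the energy groupings.
#'
#' @param S a [CrossOverlap] or the overlap matrix itself.
#' @param labA,labB [LabeledOrbitals] of the two monomers.
#' @return named list: matrix `s2` plus grouped sums `pipi`, `piSpiS`,
#'   `piApiA`, `piSpiA`, `all`.
#' @export
squaredOverlapSums <- function(S, labA, labB) {
  M <- if (is(S, "CrossOverlap")) S@S else as.matrix(S)
  s2 <- M^2
  tA <- labA@table; tB <- labB@table
  piA <- tA$sigmaPi == "pi"; piB <- tB$sigmaPi == "pi"
  SA <- piA & tA$parityXZ == "S"; AA <- piA & tA$parityXZ == "A"
  SB <- piB & tB$parityXZ == "S"; AB <- piB & tB$parityXZ == "A"
  list(s2 = s2,
       all = sum(s2),
       pipi = sum(s2[piA, piB]),
       piSpiS = sum(s2[SA, SB]),
       piApiA = sum(s2[AA, AB]),
       piSpiA = sum(s2[SA, AB]) + sum(s2[AA, SB]))
}
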