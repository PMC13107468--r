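# Operator matrices and occupied-MO two-electron integrals over the dimer
# AO basis.  Everything the MOPCE evaluation needs from the integral engine
# is collected here behind two entry points: operatorMatrices() (AO-level,
# conventional or density-fitted J/K) and occERIBlock() (occupied-only MO
# integrals).  The AO layout of a dimer is always [fixed monomer | mobile
# monomer].

CONVENTIONAL_NBF_CAP <- 150L  # above this, density fitting is the default

#' Engine shells of a dimer arrangement
#' @noRd
.dimerShells <- function(arr, basisName) {
  mob <- mobileMolecule(arr)
  buildShells(c(arr@fixed@elements, mob@elements),
              rbind(arr@fixed@coords, mob@coords), basisName)
}

.useDF <- function(basis, nbf, densityFitting = NULL) {
  if (!is.null(densityFitting)) return(isTRUE(densityFitting))
  if (!is.na(basis@densityFitting)) return(isTRUE(basis@densityFitting))
  nbf > CONVENTIONAL_NBF_CAP
}

# unpack a packed pair-pair ERI vector into the full 4-index array
.unpackERI <- function(eri, N) {
  pid <- function(i, j) {
    p <- pmax(i, j) - 1L; q <- pmin(i, j) - 1L
    p * (p + 1L) / 2L + q
  }
  idx <- seq_len(N)
  P <- outer(idx, idx, pid)
  G <- array(0, c(N, N, N, N))
  Pv <- as.vector(P)
  # eid for all (pairA, pairB)
  A <- rep(Pv, times = N * N)
  B <- rep(Pv, each = N * N)
  eid <- pmax(A, B) * (pmax(A, B) + 1) / 2 + pmin(A, B) + 1
  G[] <- eri[eid]
  G
}

# four-index MO transform of a full AO array (small systems)
.transformERI <- function(G, C1, C2, C3, C4) {
  N <- dim(G)[1]
  k1 <- ncol(C1); k2 <- ncol(C2); k3 <- ncol(C3); k4 <- ncol(C4)
  M <- matrix(G, N, N^3)
  G1 <- crossprod(C1, M)                      # k1 x N^3
  G1 <- array(G1, c(k1, N, N, N))
  G1 <- aperm(G1, c(2, 3, 4, 1))
  M <- matrix(G1, N, N * N * k1)
  G2 <- crossprod(C2, M)
  G2 <- array(G2, c(k2, N, N, k1))
  G2 <- aperm(G2, c(2, 3, 4, 1))
  M <- matrix(G2, N, N * k1 * k2)
  G3 <- crossprod(C3, M)
  G3 <- array(G3, c(k3, N, k1, k2))
  G3 <- aperm(G3, c(2, 3, 4, 1))
  M <- matrix(G3, N, k1 * k2 * k3)
  G4 <- crossprod(C4, M)
  G4 <- array(G4, c(k4, k1, k2, k3))
  aperm(G4, c(2, 3, 4, 1))                    # (k1, k2, k3, k4)
}

#' Build one- and two-electron operator matrices for a dimer
#'
#' Returns the AO overlap, kinetic, per-monomer nuclear-attraction and
#' Coulomb/exchange matrices over the dimer AO basis, together with the
#' monomer and dimer Fock matrices F_X = T + v_X + 2 J_X - K_X and
#' F = T + v_A + 2 J_A - K_A + v_B + 2 J_B - K_B.
#'
#' @param dimer a [DimerArrangement].
#' @param scfA,scfB [SCFResult] (or [LabeledOrbitals]) of the fixed and
#'   mobile monomer; coefficient matrices must share this basis.
#' @param basis a [BasisSpec] or basis name.
#' @param densityFitting logical or NULL (auto by size).
#' @param maxGb in-memory integral cap (GiB).
#' @return an [OperatorMatrices].
#' @export
operatorMatrices <- function(dimer, scfA, scfB, basis, densityFitting = NULL,
                             maxGb = 4) {
  if (!is(basis, "BasisSpec")) basis <- basisSpec(basis)
  labA <- if (is(scfA, "LabeledOrbitals")) scfA else NULL
  labB <- if (is(scfB, "LabeledOrbitals")) scfB else NULL
  sA <- if (is.null(labA)) scfA else labA@scf
  sB <- if (is.null(labB)) scfB else labB@scf
  if (!identical(sA@basisName, basis@name) ||
      !identical(sB@basisName, basis@name))
    stop("basis mismatch between SCF results (", sA@basisName, ", ",
         sB@basisName, ") and requested basis ", basis@name)
  if (!identical(sA@basisMode, sB@basisMode))
    stop("SCF results mix monomer and dimer_ghost basis modes")

  shells <- .dimerShells(dimer, basis@name)
  nbf <- attr(shells, "nbf")
  df <- .useDF(basis, nbf, densityFitting)
  one <- cpp_oneint(shells)
  mob <- mobileMolecule(dimer)
  ZA <- elementZ(dimer@fixed@elements)
  ZB <- elementZ(mob@elements)
  vA <- cpp_nucattr(shells, ZA, dimer@fixed@coords * BOHR_PER_ANGSTROM)
  vB <- cpp_nucattr(shells, ZB, mob@coords * BOHR_PER_ANGSTROM)

  CA <- .padOccupied(if (is.null(labA)) .asLabels(sA) else labA, nbf, "A")
  CB <- .padOccupied(if (is.null(labB)) .asLabels(sB) else labB, nbf, "B")
  DA <- tcrossprod(CA)
  DB <- tcrossprod(CB)

  if (df) {
    mobEls <- mob@elements
    aux <- buildAuxShells(c(dimer@fixed@elements, mobEls),
                          rbind(dimer@fixed@coords, mob@coords),
                          basis@name, basis@auxName)
    B <- cpp_3center(shells, aux, 1e-12, maxGb)
    L <- .metricChol(cpp_metric2c(aux))
    jkA <- cpp_df_jk(B, L, CA, DA)
    jkB <- cpp_df_jk(B, L, CB, DB)
  } else {
    eri <- cpp_eri_packed(shells, 1e-13, maxGb)
    jkA <- cpp_jk_packed(eri, DA)
    jkB <- cpp_jk_packed(eri, DB)
  }
  FA <- one$T + vA + 2 * jkA$J - jkA$K
  FB <- one$T + vB + 2 * jkB$J - jkB$K
  F <- FA + vB + 2 * jkB$J - jkB$K
  new("OperatorMatrices", S = one$S, T = one$T, vA = vA, vB = vB,
      JA = jkA$J, KA = jkA$K, JB = jkB$J, KB = jkB$K, F = F, FA = FA,
      FB = FB, basisMode = sA@basisMode, densityFitting = df)
}

# wrap an SCFResult as unlabeled orbitals (identity coefficients)
.asLabels <- function(scf) {
  new("LabeledOrbitals",
      table = data.frame(index = seq_len(scf@nOccupied),
                         energy = scf@orbitalEnergies,
                         sigmaPi = NA_character_, parityXZ = NA_character_,
                         parityValue = NA_real_, classRank = NA_integer_,
                         degenSet = NA_integer_),
      coefficients = scf@moCoefficients, scf = scf, phasesFixed = FALSE)
}

setMethod("show", "OperatorMatrices", function(object) {
  cat(sprintf(
    "OperatorMatrices: %d AO functions (%s mode, density fitting %s)\n",
    nrow(object@S), object@basisMode,
    if (object@densityFitting) "on" else "off"))
})

# raw (P|xy) over all MO pairs of C; streams the 3-center build in
# auxiliary-shell chunks when the full tensor would exceed the memory cap
.moPairsRaw <- function(shells, aux, C, maxGb = 4) {
  nbf <- attr(shells, "nbf")
  npair <- as.numeric(nbf) * (nbf + 1) / 2
  naux <- attr(aux, "nbf")
  full <- naux * npair * 8 / 2^30
  if (full <= 0.5 * maxGb)
    return(cpp_mo_pairs(cpp_3center(shells, aux, 1e-12, maxGb), C, C))
  budget <- max(1L, floor(0.25 * maxGb * 2^30 / (npair * 8)))  # aux fns/chunk
  K <- ncol(C)
  V <- matrix(0, naux, K * K)
  i <- 1L
  off <- 0L
  nsh <- length(aux)
  while (i <= nsh) {
    j <- i
    nfun <- 2L * aux[[j]]$l + 1L
    while (j < nsh && nfun + 2L * aux[[j + 1L]]$l + 1L <= budget) {
      j <- j + 1L
      nfun <- nfun + 2L * aux[[j]]$l + 1L
    }
    chunk <- aux[i:j]
    attr(chunk, "nbf") <- nfun
    Bc <- cpp_3center(shells, chunk, 1e-12, maxGb)
    V[off + seq_len(nfun), ] <- cpp_mo_pairs(Bc, C, C)
    off <- off + nfun
    i <- j + 1L
  }
  V
}

#' Occupied-only MO two-electron integrals of a dimer
#'
#' Computes the charge-density-notation blocks needed by the orbital-pair
#' exchange decomposition: g[a,b,a',b'] = (ab|a'b') and
#' h[a,a',b,b'] = (aa'|bb'), with a-type indices occupied on the fixed
#' monomer and b-type on the mobile one.
#'
#' @param scfA,scfB [SCFResult] or [LabeledOrbitals] of the monomers.
#' @param basis a [BasisSpec] or basis name.
#' @param dimer the [DimerArrangement].
#' @param densityFitting logical or NULL (auto by size).
#' @param maxGb memory cap (GiB); exceeded estimates raise an error.
#' @return an [OccERIBlock].
#' @export
occERIBlock <- function(scfA, scfB, basis, dimer, densityFitting = NULL,
                        maxGb = 4) {
  if (!is(basis, "BasisSpec")) basis <- basisSpec(basis)
  labA <- if (is(scfA, "LabeledOrbitals")) scfA else .asLabels(scfA)
  labB <- if (is(scfB, "LabeledOrbitals")) scfB else .asLabels(scfB)
  shells <- .dimerShells(dimer, basis@name)
  nbf <- attr(shells, "nbf")
  df <- .useDF(basis, nbf, densityFitting)
  CA <- .padOccupied(labA, nbf, "A")
  CB <- .padOccupied(labB, nbf, "B")
  if (df) {
    mob <- mobileMolecule(dimer)
    aux <- buildAuxShells(c(dimer@fixed@elements, mob@elements),
                          rbind(dimer@fixed@coords, mob@coords),
                          basis@name, basis@auxName)
    B <- cpp_3center(shells, aux, 1e-12, maxGb)
    M <- cpp_metric2c(aux)
    L <- .metricChol(M)
    Vab <- forwardsolve(L, cpp_mo_pairs(B, CA, CB))  # naux x (nA*nB)
    Vaa <- forwardsolve(L, cpp_mo_pairs(B, CA, CA))
    Vbb <- forwardsolve(L, cpp_mo_pairs(B, CB, CB))
    nA <- ncol(CA); nB <- ncol(CB)
    g <- array(crossprod(Vab), c(nA, nB, nA, nB))
    h <- array(crossprod(Vaa, Vbb), c(nA, nA, nB, nB))
  } else {
    eri <- cpp_eri_packed(shells, 1e-13, maxGb)
    G <- .unpackERI(eri, nbf)
    g <- .transformERI(G, CA, CB, CA, CB)
    h <- .transformERI(G, CA, CA, CB, CB)
  }
  new("OccERIBlock", g = g, h = h, densityFitting = df)
}

setMethod("show", "OccERIBlock", function(object) {
  d <- dim(object@g)
  cat(sprintf(
    "OccERIBlock: %d x %d occupied pairs (density fitting %s)\n",
    d[1], d[2], if (object@densityFitting) "on" else "off"))
})
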