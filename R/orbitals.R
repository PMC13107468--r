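# Occupied-orbital classification (pi/sigma, sigma_xz mirror parity),
# deterministic phase fixing, cross-monomer overlaps and pair counting.
#
# A planar molecule in the xy-plane has AO functions of definite parity
# under z -> -z: a real solid harmonic S_lm on an in-plane center carries
# parity (-1)^(l-|m|).  An occupied MO is pi when its norm fraction on the
# odd-parity block exceeds the purity threshold.  The sigma_xz (y -> -y)
# parity is evaluated through the AO representation matrix of the
# reflection; quasi-degenerate MO sets (benzene e-pairs) are first rotated
# to diagonalize the reflection so that individual labels are well defined.

PI_PURITY_THRESHOLD <- 0.98
PARITY_THRESHOLD <- 0.95
DEGENERACY_TOL <- 1e-6  # Hartree

# shells of the AO basis an SCFResult is expressed in (real + ghost centers)
.scfShells <- function(scf) {
  shellsReal <- buildShells(scf@molecule@elements, scf@molecule@coords,
                            scf@basisName)
  if (is.null(scf@ghost)) return(shellsReal)
  shellsGhost <- buildShells(scf@ghost@elements, scf@ghost@coords,
                             scf@basisName)
  shells <- if (scf@ghostFirst) c(shellsGhost, shellsReal)
            else c(shellsReal, shellsGhost)
  m1 <- attr(if (scf@ghostFirst) shellsGhost else shellsReal, "meta")
  m2 <- attr(if (scf@ghostFirst) shellsReal else shellsGhost, "meta")
  m2$ao <- m2$ao + max(m1$ao)
  m2$atom <- m2$atom + max(m1$atom)
  meta <- rbind(m1, m2)
  meta$real <- if (scf@ghostFirst)
    meta$ao > max(m1$ao) else meta$ao <= max(m1$ao)
  attr(shells, "meta") <- meta
  attr(shells, "nbf") <- attr(shellsReal, "nbf") + attr(shellsGhost, "nbf")
  shells
}

# signed AO permutation matrix of the y -> -y reflection, or NULL when the
# center set is not mirror symmetric
.reflectionMatrix <- function(shells) {
  meta <- attr(shells, "meta")
  centers <- t(vapply(shells, function(s) s$center, numeric(3)))
  refl <- centers
  refl[, 2] <- -refl[, 2]
  nsh <- length(shells)
  shmap <- integer(nsh)
  for (i in seq_len(nsh)) {
    d <- sqrt(rowSums(sweep(centers, 2, refl[i, ])^2))
    cand <- which(d < 1e-4 * BOHR_PER_ANGSTROM &
                  vapply(shells, function(s) s$l, integer(1)) == shells[[i]]$l &
                  vapply(shells, function(s)
                    length(s$exps) == length(shells[[i]]$exps) &&
                    max(abs(s$exps - shells[[i]]$exps)) < 1e-10, logical(1)))
    if (!length(cand)) return(NULL)
    shmap[i] <- cand[1]
  }
  nbf <- attr(shells, "nbf")
  R <- matrix(0, nbf, nbf)
  offs <- cumsum(c(0, vapply(shells, function(s) 2L * s$l + 1L,
                             integer(1))))
  for (i in seq_len(nsh)) {
    l <- shells[[i]]$l
    for (k in seq_len(2L * l + 1L)) {
      m <- k - l - 1L
      sgn <- if (m < 0) -1 else 1  # sine-type harmonics are odd in y
      R[offs[shmap[i]] + k, offs[i] + k] <- sgn
    }
  }
  R
}

#' Classify occupied monomer orbitals
#'
#' Labels each occupied MO as pi or sigma (parity under reflection through
#' the molecular plane) and, where the molecule is mirror-symmetric about
#' the xz-plane, as S (symmetric) or A (antisymmetric) under y -> -y.
#' Quasi-degenerate orbital sets are rotated to make the mirror parity
#' sharp; class ranks count pi-S and pi-A orbitals in increasing energy
#' (the nS / nA designations).
#'
#' @param scf an [SCFResult].
#' @param mol the (canonically oriented, planar) [Molecule]; defaults to
#'   the SCF molecule.
#' @param purity minimum norm fraction on one plane-parity block.
#' @return a [LabeledOrbitals] object.
#' @export
classifyOrbitals <- function(scf, mol = scf@molecule,
                             purity = PI_PURITY_THRESHOLD) {
  if (!isPlanar(mol))
    stop("pi/sigma classification requires a planar molecule (max deviation ",
         format(planarityDeviation(mol), digits = 3), " Angstrom)")
  shells <- .scfShells(scf)
  meta <- attr(shells, "meta")
  if (is.null(meta$real)) meta$real <- TRUE
  S <- cpp_oneint(shells)$S
  C <- scf@moCoefficients
  nocc <- ncol(C)

  realOdd <- meta$ao[meta$real & meta$zparity == -1]
  realEven <- meta$ao[meta$real & meta$zparity == 1]
  SC <- S %*% C

  Rm <- .reflectionMatrix(shells)
  Ssig <- if (is.null(Rm)) NULL else S %*% Rm

  # quasi-degenerate rotation for sharp mirror parity
  degen <- cumsum(c(1, diff(scf@orbitalEnergies) > DEGENERACY_TOL))
  if (!is.null(Ssig)) {
    for (g in unique(degen)) {
      idx <- which(degen == g)
      if (length(idx) < 2) next
      M <- t(C[, idx, drop = FALSE]) %*% Ssig %*% C[, idx, drop = FALSE]
      M <- (M + t(M)) / 2
      if (max(abs(M - diag(diag(M)))) > 1e-8) {
        ev <- eigen(M, symmetric = TRUE)
        C[, idx] <- C[, idx, drop = FALSE] %*% ev$vectors[, order(-ev$values)]
      }
    }
    SC <- S %*% C
  }

  sigmaPi <- character(nocc)
  parity <- rep("none", nocc)
  pval <- rep(NA_real_, nocc)
  for (i in seq_len(nocc)) {
    co <- C[realOdd, i]
    ce <- C[realEven, i]
    wodd <- sum(co * (S[realOdd, realOdd, drop = FALSE] %*% co))
    wevn <- sum(ce * (S[realEven, realEven, drop = FALSE] %*% ce))
    frac <- wodd / (wodd + wevn)
    if (frac >= purity) sigmaPi[i] <- "pi"
    else if (frac <= 1 - purity) sigmaPi[i] <- "sigma"
    else stop(sprintf(
      "occupied MO %d has mixed plane parity (pi fraction %.3f); the molecule may be mis-oriented or symmetry-broken",
      i, frac))
    if (!is.null(Ssig)) {
      p <- sum(C[, i] * (Ssig %*% C[, i]))
      pval[i] <- p
      if (p > PARITY_THRESHOLD) parity[i] <- "S"
      else if (p < -PARITY_THRESHOLD) parity[i] <- "A"
    }
  }

  rank <- rep(NA_integer_, nocc)
  for (cls in c("S", "A")) {
    sel <- which(sigmaPi == "pi" & parity == cls)
    rank[sel[order(scf@orbitalEnergies[sel])]] <- seq_along(sel)
  }

  tab <- data.frame(index = seq_len(nocc), energy = scf@orbitalEnergies,
                    sigmaPi = sigmaPi, parityXZ = parity,
                    parityValue = pval, classRank = rank, degenSet = degen,
                    stringsAsFactors = FALSE)
  new("LabeledOrbitals", table = tab, coefficients = C, scf = scf,
      phasesFixed = FALSE)
}

#' Fix molecular-orbital phases deterministically
#'
#' Scales each MO by +-1 so that its largest-magnitude AO coefficient is
#' positive; coefficient ties are resolved toward the lowest AO index.
#' Idempotent; all squared quantities are invariant.
#'
#' @param lab a [LabeledOrbitals] object.
#' @return the phase-fixed [LabeledOrbitals].
#' @export
fixPhases <- function(lab) {
  C <- lab@coefficients
  for (i in seq_len(ncol(C))) {
    j <- which.max(abs(C[, i]))  # lowest index wins ties
    if (C[j, i] < 0) C[, i] <- -C[, i]
  }
  initialize(lab, coefficients = C, phasesFixed = TRUE)
}

#' @describeIn classifyOrbitals label table accessor
#' @param lab a LabeledOrbitals object.
#' @export
labelTable <- function(lab) lab@table

#' @describeIn classifyOrbitals number of pi (or sigma) occupied MOs
#' @param which "pi" or "sigma".
#' @export
countClass <- function(lab, which = "pi") sum(lab@table$sigmaPi == which)

setMethod("show", "LabeledOrbitals", function(object) {
  t <- object@table
  cat(sprintf(
    "LabeledOrbitals: %d occupied (%d pi: %d S + %d A + %d unlabeled; %d sigma)\n",
    nrow(t), sum(t$sigmaPi == "pi"),
    sum(t$sigmaPi == "pi" & t$parityXZ == "S"),
    sum(t$sigmaPi == "pi" & t$parityXZ == "A"),
    sum(t$sigmaPi == "pi" & t$parityXZ == "none"), sum(t$sigmaPi == "sigma")))
})

#' Export an orbital classification report as CSV
#'
#' @param lab a [LabeledOrbitals] object.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
exportClassification <- function(lab, path) {
  t <- lab@table
  out <- data.frame(index = t$index, energy_hartree = t$energy,
                    class = t$sigmaPi, parity_xz = t$parityXZ,
                    class_rank = t$classRank,
                    designation = ifelse(is.na(t$classRank), "",
                                         paste0(t$classRank, t$parityXZ)))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cross-monomer occupied MO overlap matrix
#'
#' S_ab = C_A' S_AO C_B over the shared dimer AO basis, restricted to the
#' occupied orbitals of each monomer.
#'
#' @param labA,labB [LabeledOrbitals] of the fixed and mobile monomer.
#' @param ops an [OperatorMatrices] for the arrangement (its S slot is
#'   used), or the dimer AO overlap matrix itself.
#' @param arrangement the [DimerArrangement] the overlap belongs to.
#' @return a [CrossOverlap].
#' @export
crossOverlap <- function(labA, labB, ops, arrangement) {
  Sao <- if (is(ops, "OperatorMatrices")) ops@S else as.matrix(ops)
  CA <- .padOccupied(labA, nrow(Sao), "A")
  CB <- .padOccupied(labB, nrow(Sao), "B")
  new("CrossOverlap", S = t(CA) %*% Sao %*% CB, arrangement = arrangement)
}

# pad monomer-basis occupied coefficients into the dimer AO basis
# (block A first, block B second); ghost-mode coefficients already span it
.padOccupied <- function(lab, nbfDimer, block = c("A", "B")) {
  block <- match.arg(block)
  C <- lab@coefficients
  if (nrow(C) == nbfDimer) return(C)
  if (2L * nrow(C) != nbfDimer)
    stop("coefficient dimension ", nrow(C),
         " matches neither the dimer basis (", nbfDimer,
         ") nor a monomer block")
  out <- matrix(0, nbfDimer, ncol(C))
  rows <- if (block == "A") seq_len(nrow(C)) else nrow(C) + seq_len(nrow(C))
  out[rows, ] <- C
  out
}

#' @describeIn crossOverlap the overlap matrix
#' @param x a CrossOverlap.
#' @export
overlapMatrix <- function(x) x@S

#' Count occupied orbital pairs by class
#'
#' The pi-sigma filter counts both (pi, sigma) and (sigma, pi) orderings.
#'
#' @param labA,labB [LabeledOrbitals] of the two monomers.
#' @param classFilter one of "all", "pipi", "pisigma", "sigmasigma".
#' @return integer pair count.
#' @export
countPairs <- function(labA, labB,
                       classFilter = c("all", "pipi", "pisigma",
                                       "sigmasigma")) {
  classFilter <- match.arg(classFilter)
  nPiA <- countClass(labA, "pi"); nSgA <- countClass(labA, "sigma")
  nPiB <- countClass(labB, "pi"); nSgB <- countClass(labB, "sigma")
  switch(classFilter,
    all = (nPiA + nSgA) * (nPiB + nSgB),
    pipi = nPiA * nPiB,
    pisigma = nPiA * nSgB + nSgA * nPiB,
    sigmasigma = nSgA * nSgB)
}
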