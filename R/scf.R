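# Restricted Hartree-Fock with DIIS; conventional or density-fitted Fock
# builds.  Convergence targets are tight (energy 1e-10 Hartree, density RMS
# 1e-8) to stabilize 4-decimal orbital-energy reproduction.

.nuclearRepulsion <- function(Z, posBohr) {
  n <- length(Z)
  if (n < 2) return(0)
  e <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((posBohr[i, ] - posBohr[j, ])^2))
    e <- e + Z[i] * Z[j] / r
  }
  e
}

# Cholesky of the fitting metric with a minimal jitter fallback for
# near-linear-dependent auxiliary sets.
.metricChol <- function(M) {
  out <- tryCatch(t(chol(M)), error = function(e) NULL)
  if (is.null(out)) {
    jit <- 1e-10 * max(diag(M))
    out <- t(chol(M + diag(jit, nrow(M))))
  }
  out
}

#' Low-level RHF driver over prepared shells
#'
#' @param shells engine shell list (real + ghost centers).
#' @param Z nuclear charges of the real atoms.
#' @param posBohr real-atom positions (Bohr).
#' @param nelec electron count (must be even).
#' @param densityFitting logical.
#' @param auxShells auxiliary shells (required when densityFitting).
#' @param etol,dtol convergence thresholds (Hartree, density RMS).
#' @param maxiter iteration cap.
#' @param maxGb in-memory integral cap in GiB.
#' @return list with C, eps (all MOs), energy, nocc, converged, iterations.
#' @noRd
rhfCore <- function(shells, Z, posBohr, nelec, densityFitting = FALSE,
                    auxShells = NULL, etol = 1e-10, dtol = 1e-8,
                    maxiter = 200L, maxGb = 4) {
  if (nelec %% 2 != 0)
    stop("restricted SCF requires an even electron count (got ", nelec, ")")
  nocc <- nelec %/% 2
  one <- cpp_oneint(shells)
  S <- one$S; T <- one$T
  V <- cpp_nucattr(shells, Z, posBohr)
  H <- T + V
  Enuc <- .nuclearRepulsion(Z, posBohr)

  eri <- NULL; B <- NULL; Lchol <- NULL
  if (densityFitting) {
    if (is.null(auxShells)) stop("densityFitting requires auxiliary shells")
    B <- cpp_3center(shells, auxShells, 1e-12, maxGb)
    Lchol <- .metricChol(cpp_metric2c(auxShells))
  } else {
    eri <- cpp_eri_packed(shells, 1e-13, maxGb)
  }

  es <- eigen(S, symmetric = TRUE)
  keep <- es$values > 1e-10 * max(es$values)
  X <- es$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(es$values[keep]), sum(keep))

  fock <- function(D, Cocc) {
    if (densityFitting) {
      jk <- cpp_df_jk(B, Lchol, Cocc, D)
      # large per-iteration temporaries: keep the footprint flat
      gc(FALSE)
    } else {
      jk <- cpp_jk_packed(eri, D)
    }
    H + 2 * jk$J - jk$K
  }

  # diagonalize in the orthonormal basis; R's eigen() sorts descending
  diagF <- function(F) {
    ev <- eigen(t(X) %*% F %*% X, symmetric = TRUE)
    ord <- order(ev$values)
    list(eps = ev$values[ord], C = X %*% ev$vectors[, ord, drop = FALSE])
  }

  # generalized Wolfsberg-Helmholz guess: far more reliable than the bare
  # core Hamiltonian for extended conjugated systems
  Hgwh <- 0.875 * S * (matrix(diag(H), nrow(H), ncol(H)) +
                       matrix(diag(H), nrow(H), ncol(H), byrow = TRUE))
  diag(Hgwh) <- diag(H)
  ev <- diagF(Hgwh)
  C <- ev$C
  Cocc <- C[, seq_len(nocc), drop = FALSE]
  D <- tcrossprod(Cocc)

  Eold <- Inf
  fs <- list(); errs <- list()
  converged <- FALSE
  iter <- 0L
  eps <- ev$eps
  for (iter in seq_len(maxiter)) {
    F <- fock(D, Cocc)
    E <- sum(D * (H + F)) + Enuc
    err <- t(X) %*% (F %*% D %*% S - S %*% D %*% F) %*% X
    fs[[length(fs) + 1]] <- F
    errs[[length(errs) + 1]] <- err
    if (length(fs) > 8) { fs <- fs[-1]; errs <- errs[-1] }
    m <- length(fs)
    if (m >= 2) {
      Bm <- matrix(0, m + 1, m + 1)
      for (i in seq_len(m)) for (j in seq_len(m))
        Bm[i, j] <- sum(errs[[i]] * errs[[j]])
      Bm[m + 1, seq_len(m)] <- -1
      Bm[seq_len(m), m + 1] <- -1
      rhs <- c(rep(0, m), -1)
      cw <- tryCatch(solve(Bm, rhs)[seq_len(m)], error = function(e) NULL)
      if (!is.null(cw) && all(is.finite(cw))) {
        F <- Reduce(`+`, Map(`*`, fs, cw))
      }
    }
    ev <- diagF(F)
    eps <- ev$eps
    C <- ev$C
    Cocc <- C[, seq_len(nocc), drop = FALSE]
    Dnew <- tcrossprod(Cocc)
    rms <- sqrt(mean((Dnew - D)^2))
    dE <- abs(E - Eold)
    D <- Dnew
    Eold <- E
    if (dE < etol && rms < dtol) { converged <- TRUE; break }
  }
  # final consistent energy
  F <- fock(D, Cocc)
  E <- sum(D * (H + F)) + Enuc
  if (converged && nocc < length(eps) &&
      eps[nocc] > eps[nocc + 1] + 1e-10)
    stop(sprintf(
      "SCF converged to a non-aufbau state (HOMO %.6f above LUMO %.6f)",
      eps[nocc], eps[nocc + 1]))
  list(C = C, eps = eps, energy = E, nocc = nocc, converged = converged,
       iterations = iter, S = S, nbf = nrow(S))
}

#' Run a restricted Hartree-Fock calculation on a monomer
#'
#' Solves the closed-shell SCF problem for `mol`, optionally in the presence
#' of a ghost partner whose atoms contribute basis functions but no nuclei
#' or electrons (counterpoise / dimer basis).
#'
#' @param mol a [Molecule].
#' @param basis a [BasisSpec] or basis-set name.
#' @param ghost optional [Molecule] of ghost centers.
#' @param ghostFirst logical; place the ghost basis functions before the
#'   real ones in the AO ordering (used to keep a fixed dimer AO layout).
#' @param densityFitting logical or NULL; NULL defers to the BasisSpec
#'   (NA there means "on for more than 150 AO functions").
#' @param maxGb integral memory cap in GiB.
#' @param etol,dtol,maxiter SCF convergence controls.
#' @return an [SCFResult] carrying the occupied orbitals and energies.
#' @export
runRHF <- function(mol, basis, ghost = NULL, ghostFirst = FALSE,
                   densityFitting = NULL, maxGb = 4, etol = 1e-10,
                   dtol = 1e-8, maxiter = 200L) {
  if (!is(basis, "BasisSpec")) basis <- basisSpec(basis)
  validObject(mol)
  if (mol@multiplicity != 1L)
    stop("only closed-shell molecules are supported")
  shellsReal <- buildShells(mol@elements, mol@coords, basis@name)
  shells <- shellsReal
  if (!is.null(ghost)) {
    shellsGhost <- buildShells(ghost@elements, ghost@coords, basis@name)
    shells <- if (ghostFirst) c(shellsGhost, shellsReal)
              else c(shellsReal, shellsGhost)
    attr(shells, "nbf") <- attr(shellsReal, "nbf") + attr(shellsGhost, "nbf")
  }
  nbf <- attr(shells, "nbf")
  df <- if (!is.null(densityFitting)) isTRUE(densityFitting)
        else if (!is.na(basis@densityFitting)) isTRUE(basis@densityFitting)
        else nbf > 150L
  aux <- NULL
  if (df) {
    allEls <- c(if (!is.null(ghost) && ghostFirst) ghost@elements,
                mol@elements,
                if (!is.null(ghost) && !ghostFirst) ghost@elements)
    allPos <- rbind(if (!is.null(ghost) && ghostFirst) ghost@coords,
                    mol@coords,
                    if (!is.null(ghost) && !ghostFirst) ghost@coords)
    aux <- buildAuxShells(allEls, allPos, basis@name, basis@auxName)
  }
  Z <- elementZ(mol@elements)
  nelec <- sum(Z) - mol@charge
  res <- rhfCore(shells, Z, mol@coords * BOHR_PER_ANGSTROM, nelec,
                 densityFitting = df, auxShells = aux, etol = etol,
                 dtol = dtol, maxiter = maxiter, maxGb = maxGb)
  if (!res$converged)
    stop(sprintf(
      "SCF did not converge in %d iterations (last energy %.10f Hartree)",
      res$iterations, res$energy))
  new("SCFResult",
      moCoefficients = res$C[, seq_len(res$nocc), drop = FALSE],
      orbitalEnergies = res$eps[seq_len(res$nocc)],
      nOccupied = as.integer(res$nocc), totalEnergy = res$energy,
      converged = TRUE,
      basisMode = if (is.null(ghost)) "monomer" else "dimer_ghost",
      basisName = basis@name, molecule = mol, ghost = ghost,
      ghostFirst = isTRUE(ghostFirst) && !is.null(ghost),
      nbf = as.integer(res$nbf), iterations = as.integer(res$iterations))
}

#' @describeIn runRHF occupied MO coefficient matrix
#' @param scf an [SCFResult].
#' @export
occupiedCoefficients <- function(scf) scf@moCoefficients

#' @describeIn runRHF occupied orbital energies (Hartree)
#' @export
orbitalEnergies <- function(scf) scf@orbitalEnergies

#' @describeIn runRHF number of doubly occupied orbitals
#' @export
nOccupied <- function(scf) scf@nOccupied

#' @describeIn runRHF total SCF energy (Hartree)
#' @export
totalEnergy <- function(scf) scf@totalEnergy

setMethod("show", "SCFResult", function(object) {
  cat(sprintf(
    "SCFResult: %s/%s (%s basis mode)\n  %d AO functions, %d occupied MOs\n  E = %.10f Hartree (converged in %d iterations)\n  HOMO energy %.6f Hartree\n",
    molecularFormula(object@molecule), object@basisName, object@basisMode,
    object@nbf, object@nOccupied, object@totalEnergy, object@iterations,
    max(object@orbitalEnergies)))
})

# in-session SCF cache keyed by geometry/basis/mode
.scf_cache <- new.env(parent = emptyenv())

.geomKey <- function(mol)
  paste(paste(mol@elements, collapse = ","),
        paste(sprintf("%.9f", mol@coords), collapse = ","), sep = "|")

#' Cached monomer SCF
#' @noRd
runRHFCached <- function(mol, basis, ghost = NULL, ghostFirst = FALSE,
                         densityFitting = NULL, maxGb = 4) {
  if (!is(basis, "BasisSpec")) basis <- basisSpec(basis)
  key <- paste(.geomKey(mol), basis@name,
               if (is.null(ghost)) "" else .geomKey(ghost),
               ghostFirst, format(densityFitting), sep = "#")
  if (is.null(.scf_cache[[key]]))
    .scf_cache[[key]] <- runRHF(mol, basis, ghost = ghost,
                                ghostFirst = ghostFirst,
                                densityFitting = densityFitting,
                                maxGb = maxGb)
  .scf_cache[[key]]
}

#' Persist or restore the SCF result cache
#'
#' The in-session cache of converged SCF solutions (keyed by geometry,
#' basis and basis mode) can be saved to a single RDS container and
#' restored later, so that expensive monomer solutions survive across
#' sessions.
#'
#' @param path RDS file path.
#' @return invisibly, the path (save) or the number of restored entries
#'   (load).
#' @export
saveScfCache <- function(path) {
  saveRDS(as.list(.scf_cache), path)
  invisible(path)
}

#' @rdname saveScfCache
#' @export
loadScfCache <- function(path) {
  entries <- readRDS(path)
  for (k in names(entries)) .scf_cache[[k]] <- entries[[k]]
  invisible(length(entries))
}
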