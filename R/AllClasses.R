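# S4 classes for the package's central data objects.

#' Molecule: a rigid molecular geometry
#'
#' Atoms with Cartesian coordinates in Angstrom.  Only closed-shell
#' (multiplicity 1) molecules are supported; planarity (after canonical
#' orientation) is a precondition for pi/sigma orbital classification, not
#' for construction.
#'
#' @slot elements character vector of element symbols.
#' @slot coords numeric matrix (n x 3) of positions in Angstrom.
#' @slot charge integer total charge.
#' @slot multiplicity integer spin multiplicity (must be 1).
#' @exportClass Molecule
setClass("Molecule",
  representation(elements = "character", coords = "matrix",
                 charge = "integer", multiplicity = "integer"),
  prototype(charge = 0L, multiplicity = 1L),
  validity = function(object) {
    msg <- character()
    n <- length(object@elements)
    if (n < 1) msg <- c(msg, "molecule must contain at least one atom")
    if (!is.numeric(object@coords) || ncol(object@coords) != 3 ||
        nrow(object@coords) != n)
      msg <- c(msg, "coords must be a numeric n x 3 matrix matching elements")
    else if (!all(is.finite(object@coords)))
      msg <- c(msg, "coordinates must be finite")
    bad <- setdiff(unique(object@elements), names(.element_z))
    if (length(bad))
      msg <- c(msg, paste0("unknown element symbol(s): ",
                           paste(bad, collapse = ", ")))
    if (object@multiplicity != 1L)
      msg <- c(msg, "only closed-shell molecules (multiplicity 1) are supported")
    if (length(msg)) msg else TRUE
  }
)

#' DimerArrangement: a slip-stacked dimer built by rigid translation
#'
#' The fixed monomer lies in the xy-plane; the mobile monomer is an exact
#' translated copy shifted by (dx, dy, dz) Angstrom with dz > 0.
#'
#' @slot fixed the fixed [Molecule].
#' @slot dx,dy,dz numeric shifts in Angstrom.
#' @exportClass DimerArrangement
setClass("DimerArrangement",
  representation(fixed = "Molecule", dx = "numeric", dy = "numeric",
                 dz = "numeric"),
  validity = function(object) {
    msg <- character()
    for (s in c("dx", "dy", "dz"))
      if (length(slot(object, s)) != 1 || !is.finite(slot(object, s)))
        msg <- c(msg, paste(s, "must be a finite scalar"))
    if (length(object@dz) == 1 && is.finite(object@dz) && object@dz <= 0)
      msg <- c(msg, "dz must be positive")
    if (length(msg)) msg else TRUE
  }
)

#' ScanGrid: a one-dimensional grid of in-plane shifts
#'
#' @slot axis one of "x", "y", "x_at_fixed_y".
#' @slot start,stop,step numeric, Angstrom; grid points are start + k*step.
#' @slot fixedDy numeric, Angstrom (only for axis "x_at_fixed_y").
#' @slot dz numeric inter-planar distance, Angstrom.
#' @exportClass ScanGrid
setClass("ScanGrid",
  representation(axis = "character", start = "numeric", stop = "numeric",
                 step = "numeric", fixedDy = "numeric", dz = "numeric"),
  prototype(fixedDy = NA_real_),
  validity = function(object) {
    msg <- character()
    if (!object@axis %in% c("x", "y", "x_at_fixed_y"))
      msg <- c(msg, "axis must be one of 'x', 'y', 'x_at_fixed_y'")
    if (object@step <= 0) msg <- c(msg, "step must be positive")
    if (object@start > object@stop) msg <- c(msg, "start must be <= stop")
    if (object@dz <= 0) msg <- c(msg, "dz must be positive")
    if (identical(object@axis, "x_at_fixed_y") && !is.finite(object@fixedDy))
      msg <- c(msg, "fixedDy must be given for axis 'x_at_fixed_y'")
    if (!identical(object@axis, "x_at_fixed_y") && is.finite(object@fixedDy))
      msg <- c(msg, "fixedDy is only meaningful for axis 'x_at_fixed_y'")
    if (length(msg)) msg else TRUE
  }
)

#' BasisSpec: an atomic-orbital basis-set request
#'
#' @slot name basis-set identifier resolved against the shipped basis library
#'   (e.g. "sto-3g", "cc-pvdz", "jun-cc-pvdz").
#' @slot densityFitting logical; NA means "decide by system size".
#' @slot auxName auxiliary basis identifier; "autoaux" generates an
#'   even-tempered fitting basis from the orbital basis.
#' @exportClass BasisSpec
setClass("BasisSpec",
  representation(name = "character", densityFitting = "logical",
                 auxName = "character"),
  prototype(densityFitting = NA, auxName = "autoaux"),
  validity = function(object) {
    if (isTRUE(object@densityFitting) && !nzchar(object@auxName))
      "auxName is required when densityFitting is TRUE" else TRUE
  }
)

#' SCFResult: a converged restricted Hartree-Fock monomer solution
#'
#' Occupied molecular orbitals over the atomic-orbital basis actually used
#' (the monomer's own basis, or the full dimer basis when computed against
#' a ghost partner).
#'
#' @slot moCoefficients numeric matrix (nbf x nOccupied), occupied MOs.
#' @slot orbitalEnergies numeric, Hartree, one per occupied MO.
#' @slot nOccupied integer.
#' @slot totalEnergy numeric, Hartree.
#' @slot converged logical.
#' @slot basisMode "monomer" or "dimer_ghost".
#' @slot basisName character.
#' @slot molecule the [Molecule] (real atoms only).
#' @slot ghost the ghost partner [Molecule] or NULL.
#' @slot nbf integer, number of AO basis functions.
#' @slot iterations integer.
#' @exportClass SCFResult
setClass("SCFResult",
  representation(moCoefficients = "matrix", orbitalEnergies = "numeric",
                 nOccupied = "integer", totalEnergy = "numeric",
                 converged = "logical", basisMode = "character",
                 basisName = "character", molecule = "Molecule",
                 ghost = "ANY", ghostFirst = "logical", nbf = "integer",
                 iterations = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@converged) msg <- c(msg, "SCF did not converge")
    if (ncol(object@moCoefficients) != object@nOccupied)
      msg <- c(msg, "moCoefficients must have nOccupied columns")
    if (length(object@orbitalEnergies) != object@nOccupied)
      msg <- c(msg, "orbitalEnergies must have nOccupied entries")
    if (!object@basisMode %in% c("monomer", "dimer_ghost"))
      msg <- c(msg, "basisMode must be 'monomer' or 'dimer_ghost'")
    if (length(msg)) msg else TRUE
  }
)

#' OperatorMatrices: one- and two-electron operator matrices of a dimer
#'
#' All matrices are over the shared dimer AO basis.  The dimer Fock matrix
#' F = T + vA + 2 JA - KA + vB + 2 JB - KB holds by construction.
#'
#' @slot S,T,vA,vB,JA,KA,JB,KB,F,FA,FB numeric matrices.
#' @slot basisMode "monomer" or "dimer_ghost".
#' @slot densityFitting logical.
#' @exportClass OperatorMatrices
setClass("OperatorMatrices",
  representation(S = "matrix", T = "matrix", vA = "matrix", vB = "matrix",
                 JA = "matrix", KA = "matrix", JB = "matrix", KB = "matrix",
                 F = "matrix", FA = "matrix", FB = "matrix",
                 basisMode = "character", densityFitting = "logical"))

#' OccERIBlock: occupied-only molecular-orbital two-electron integrals
#'
#' Charge-density (Mulliken) notation.  `g[a, b, ap, bp]` holds (ab|a'b')
#' with a, a' occupied on monomer A and b, b' occupied on monomer B;
#' `h[a, ap, b, bp]` holds (aa'|bb').
#'
#' @slot g,h numeric 4-index arrays.
#' @slot densityFitting logical.
#' @exportClass OccERIBlock
setClass("OccERIBlock",
  representation(g = "array", h = "array", densityFitting = "logical"))

#' LabeledOrbitals: pi/sigma and mirror-parity labels of occupied MOs
#'
#' @slot table data.frame with columns index (energy order), energy,
#'   sigmaPi ("pi"/"sigma"), parityXZ ("S"/"A"/"none"), classRank
#'   (n within pi-S or pi-A ordered by energy; NA for sigma), degenSet
#'   (id of quasi-degenerate group).
#' @slot coefficients matrix of (possibly symmetry-rotated, phase-fixed)
#'   occupied MO coefficients consistent with the labels.
#' @slot scf the underlying [SCFResult].
#' @slot phasesFixed logical.
#' @exportClass LabeledOrbitals
setClass("LabeledOrbitals",
  representation(table = "data.frame", coefficients = "matrix",
                 scf = "SCFResult", phasesFixed = "logical"),
  prototype(phasesFixed = FALSE))

#' CrossOverlap: inter-monomer occupied MO overlap matrix
#'
#' @slot S numeric matrix, rows = occupied MOs of A, cols = occupied MOs of B.
#' @slot arrangement the [DimerArrangement] it belongs to.
#' @exportClass CrossOverlap
setClass("CrossOverlap",
  representation(S = "matrix", arrangement = "DimerArrangement"),
  validity = function(object) {
    if (any(abs(object@S) > 1 + 1e-9))
      "cross overlap matrix elements must satisfy |S_ab| <= 1" else TRUE
  }
)

#' MOPCEPairTable: all orbital-pair exchange-repulsion contributions
#'
#' One row per occupied orbital pair (a, b), components in Hartree in the
#' `*_h` columns and kJ/mol in the unsuffixed columns.  The stored component
#' sums are accumulated in fixed row-major (a, b) order so that "sum of
#' entries equals stored sum" holds exactly.
#'
#' @slot table data.frame of pair components.
#' @slot sums named numeric: exi, exr2, exr3, exr4, exrb, exr (Hartree).
#' @slot mode "monomer" or "dimer_ghost".
#' @slot densityFitting logical.
#' @exportClass MOPCEPairTable
setClass("MOPCEPairTable",
  representation(table = "data.frame", sums = "numeric", mode = "character",
                 densityFitting = "logical"))

#' GroupedExchange: class-resolved exchange repulsion sums
#'
#' Energies in kJ/mol; squared-overlap sums dimensionless.
#'
#' @slot ePiPi,ePiSigma,eSigmaSigma numeric.
#' @slot ePiSPiS,ePiAPiA,ePiSPiA numeric.
#' @slot s2PiPi,s2PiSPiS,s2PiAPiA,s2PiSPiA numeric.
#' @slot eTotal numeric (kJ/mol).
#' @exportClass GroupedExchange
setClass("GroupedExchange",
  representation(ePiPi = "numeric", ePiSigma = "numeric",
                 eSigmaSigma = "numeric", ePiSPiS = "numeric",
                 ePiAPiA = "numeric", ePiSPiA = "numeric",
                 s2PiPi = "numeric", s2PiSPiS = "numeric",
                 s2PiAPiA = "numeric", s2PiSPiA = "numeric",
                 eTotal = "numeric"))

#' PIBSpec: particle-in-a-box overlap model parameters
#'
#' @slot L box length, Angstrom.
#' @slot N number of occupied model orbitals.
#' @exportClass PIBSpec
setClass("PIBSpec",
  representation(L = "numeric", N = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@L <= 0) msg <- c(msg, "box length L must be positive")
    if (object@N < 1) msg <- c(msg, "N must be >= 1")
    if (length(msg)) msg else TRUE
  }
)

#' ScanResult: observables sampled over a shift grid
#'
#' @slot data data.frame; first column `shift` (Angstrom, strictly
#'   increasing), remaining columns named observables.
#' @slot axis character axis descriptor.
#' @slot units named character, unit per observable column.
#' @slot provenance list (basis, mode, geometry hash, ...).
#' @exportClass ScanResult
setClass("ScanResult",
  representation(data = "data.frame", axis = "character",
                 units = "character", provenance = "list"),
  validity = function(object) {
    s <- object@data$shift
    if (is.null(s)) return("data must contain a 'shift' column")
    if (any(diff(s) <= 0)) return("shifts must be strictly increasing")
    TRUE
  }
)

#' FeatureReport: zeros and extrema of scanned curves
#'
#' @slot features data.frame with columns observable, type ("zero",
#'   "minimum", "maximum"), position (Angstrom), value.
#' @slot method character refinement method tag.
#' @exportClass FeatureReport
setClass("FeatureReport",
  representation(features = "data.frame", method = "character"))

#' SAPTComponents: ingested external SAPT component energies
#'
#' @slot table data.frame with columns dx, dy, Eint, Eel, Eind, Edsp, Eexch
#'   (kJ/mol).
#' @exportClass SAPTComponents
setClass("SAPTComponents", representation(table = "data.frame"))

#' MOPCEContext: everything needed to evaluate MOPCE terms of one arrangement
#'
#' Internal aggregate built by [mopceContext()]; holds the monomer SCF
#' solutions, orbital labels, the cross-overlap matrix, occupied-MO operator
#' blocks and occupied-MO two-electron integrals for one arrangement and one
#' basis mode.
#'
#' @slot arrangement the [DimerArrangement].
#' @slot basis the [BasisSpec].
#' @slot mode "monomer" or "dimer_ghost".
#' @slot densityFitting logical.
#' @slot scfA,scfB SCFResult objects.
#' @slot labelsA,labelsB LabeledOrbitals.
#' @slot Sab cross-overlap matrix (occ A x occ B).
#' @slot mo list of occupied-MO operator blocks and integral tensors.
#' @slot ops OperatorMatrices or NULL (conventional route only).
#' @exportClass MOPCEContext
setClass("MOPCEContext",
  representation(arrangement = "DimerArrangement", basis = "BasisSpec",
                 mode = "character", densityFitting = "logical",
                 scfA = "SCFResult", scfB = "SCFResult",
                 labelsA = "LabeledOrbitals", labelsB = "LabeledOrbitals",
                 Sab = "matrix", mo = "list", ops = "ANY"))

#' Fixture: a named built-in test geometry
#'
#' @slot name character.
#' @slot molecule the [Molecule] in canonical orientation.
#' @slot recommendedBasis character.
#' @slot notes character, expected qualitative behavior.
#' @exportClass Fixture
setClass("Fixture",
  representation(name = "character", molecule = "Molecule",
                 recommendedBasis = "character", notes = "character"))
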