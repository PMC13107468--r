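# Basis-set handling: G94-format parser, shell construction for the integral
# engine, and automatic even-tempered auxiliary (density-fitting) bases.

#' Construct a basis-set request
#'
#' @param name basis-set identifier; resolved case-insensitively against the
#'   basis library shipped with the package ("sto-3g", "cc-pvdz",
#'   "jun-cc-pvdz").
#' @param densityFitting logical or NA.  NA (default) enables density
#'   fitting automatically for systems with more than 150 AO basis
#'   functions.
#' @param auxName auxiliary basis; "autoaux" (default) derives an
#'   even-tempered fitting basis from the orbital basis.
#' @return a [BasisSpec].
#' @export
basisSpec <- function(name, densityFitting = NA, auxName = "autoaux") {
  loadBasisSet(name)  # fails early for unresolvable names
  new("BasisSpec", name = tolower(name), densityFitting = densityFitting,
      auxName = auxName)
}

.basis_cache <- new.env(parent = emptyenv())

#' Parse a G94-format basis file
#' @return named list: element -> list of shells list(l, exps, coefs).
#' @noRd
parseBasisG94 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*!", lines)]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lmap <- c(S = 0L, P = 1L, D = 2L, F = 3L, G = 4L)
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    if (lines[i] == "****") { i <- i + 1; next }
    el <- strsplit(lines[i], "\\s+")[[1]][1]
    i <- i + 1
    shells <- list()
    while (i <= length(lines) && lines[i] != "****") {
      hdr <- strsplit(lines[i], "\\s+")[[1]]
      ltyp <- toupper(hdr[1])
      nprim <- as.integer(hdr[2])
      if (!ltyp %in% names(lmap))
        stop("unsupported shell type '", ltyp, "' in ", path)
      i <- i + 1
      ex <- numeric(nprim); cf <- numeric(nprim)
      for (k in seq_len(nprim)) {
        v <- as.numeric(strsplit(gsub("[dD]([+-])", "e\\1", lines[i]),
                                 "\\s+")[[1]])
        ex[k] <- v[1]; cf[k] <- v[2]
        i <- i + 1
      }
      shells[[length(shells) + 1]] <- list(l = lmap[[ltyp]], exps = ex,
                                           coefs = cf)
    }
    out[[el]] <- shells
  }
  out
}

#' Load a named basis set from the package library
#' @noRd
loadBasisSet <- function(name) {
  key <- tolower(name)
  if (!is.null(.basis_cache[[key]])) return(.basis_cache[[key]])
  path <- system.file("extdata", "basis", paste0(key, ".g94"),
                      package = "pistack")
  if (!nzchar(path)) {
    avail <- sub("\\.g94$", "",
                 list.files(system.file("extdata", "basis",
                                        package = "pistack"), "\\.g94$"))
    stop("unknown basis set '", name, "'; available: ",
         paste(avail, collapse = ", "))
  }
  b <- parseBasisG94(path)
  .basis_cache[[key]] <- b
  b
}

# double factorial (2l-1)!! with (-1)!! = 1
.dfact <- function(n) if (n <= 0) 1 else prod(seq(n, 1, by = -2))

# normalization of the (l,0,0) Cartesian primitive
.primNorm <- function(alpha, l)
  (2 * alpha / pi)^0.75 * (4 * alpha)^(l / 2) / sqrt(.dfact(2 * l - 1))

.qmat_cache <- new.env(parent = emptyenv())

# normalized solid-harmonic transform for a contracted shell
.shellQ <- function(l, exps, coefs, cachekey = NULL) {
  if (!is.null(cachekey) && !is.null(.qmat_cache[[cachekey]]))
    return(.qmat_cache[[cachekey]])
  nc <- (l + 1) * (l + 2) / 2
  Q0 <- solidHarmCoefs(l)
  raw <- list(l = l, exps = exps, coefs = coefs, center = c(0, 0, 0),
              Q = diag(nc))
  Scc <- cpp_cart_selfoverlap(raw)
  D <- Q0 %*% Scc %*% t(Q0)
  Q <- diag(1 / sqrt(diag(D)), nrow = nrow(Q0)) %*% Q0
  if (!is.null(cachekey)) .qmat_cache[[cachekey]] <- Q
  Q
}

#' Build integral-engine shells for a molecule
#'
#' @param elements element symbols (one per center; ghosts allowed).
#' @param coordsAng n x 3 coordinates in Angstrom.
#' @param basisName basis-set name.
#' @return list of shells (engine format) with attribute "meta", a
#'   data.frame describing every spherical AO function.
#' @noRd
buildShells <- function(elements, coordsAng, basisName) {
  bas <- loadBasisSet(basisName)
  shells <- list()
  meta <- NULL
  ao <- 0L
  for (ia in seq_along(elements)) {
    el <- elements[ia]
    if (is.null(bas[[el]]))
      stop("basis set '", basisName, "' has no entry for element ", el)
    for (isst in seq_along(bas[[el]])) {
      sh <- bas[[el]][[isst]]
      cf <- sh$coefs * vapply(sh$exps, .primNorm, numeric(1), l = sh$l)
      Q <- .shellQ(sh$l, sh$exps, cf,
                   cachekey = paste(basisName, el, isst, sep = "|"))
      shells[[length(shells) + 1]] <- list(
        l = sh$l, exps = sh$exps, coefs = cf,
        center = as.numeric(coordsAng[ia, ]) * BOHR_PER_ANGSTROM, Q = Q)
      ms <- seq(-sh$l, sh$l)
      meta <- rbind(meta, data.frame(
        ao = ao + seq_along(ms), atom = ia, element = el, l = sh$l, m = ms,
        zparity = (-1)^(sh$l - abs(ms))))
      ao <- ao + length(ms)
    }
  }
  attr(shells, "meta") <- meta
  attr(shells, "nbf") <- ao
  shells
}

# ------------------------------------------------------------------ autoaux
# Even-tempered automatic auxiliary basis for Coulomb/exchange fitting.
# For each element, candidate exponent ranges per auxiliary angular momentum
# come from sums of orbital-basis primitive exponent ranges of shell pairs
# whose product contains that angular momentum; a geometric sequence spans
# each range.  Shell counts per l are capped; the scheme is validated in the
# test suite against conventional integrals at the 1e-5 Hartree contract.

.AUTOAUX_NMAX <- c(16L, 12L, 10L, 6L, 4L)  # per laux = 0..4
.AUTOAUX_BETA <- c(2.4, 2.4, 2.8, 3.2, 3.5)
.AUTOAUX_HICAP <- c(Inf, 150, 40, 15, 8)   # exponent ceilings, laux >= 1
.AUTOAUX_LCAP <- 4L

.autoaux_element <- function(shells_el) {
  ls <- vapply(shells_el, function(s) s$l, integer(1))
  rng <- lapply(sort(unique(ls)), function(l) {
    ex <- unlist(lapply(shells_el[ls == l], function(s) s$exps))
    c(min(ex), max(ex))
  })
  names(rng) <- as.character(sort(unique(ls)))
  lmax <- max(ls)
  # products of functions on different centers carry angular momentum beyond
  # 2*lmax; allow two extra units (at least d) up to the g cap
  lcap <- min(max(2L, 2L * lmax), .AUTOAUX_LCAP)
  out <- list()
  for (laux in 0:lcap) {
    lo <- Inf; hi <- -Inf
    for (l1 in as.integer(names(rng))) for (l2 in as.integer(names(rng))) {
      if (laux > l1 + l2 + 2L) next
      r1 <- rng[[as.character(l1)]]; r2 <- rng[[as.character(l2)]]
      lo <- min(lo, r1[1] + r2[1])
      hi <- max(hi, r1[2] + r2[2])
    }
    if (!is.finite(lo)) next
    lo <- 0.5 * lo
    hi <- min(hi, .AUTOAUX_HICAP[laux + 1])
    b0 <- .AUTOAUX_BETA[laux + 1]
    nmax <- .AUTOAUX_NMAX[laux + 1]
    n <- if (hi / lo < 1.2) 1L else
      min(nmax, as.integer(ceiling(log(hi / lo) / log(b0))) + 1L)
    ex <- if (n == 1) sqrt(hi * lo) else
      exp(seq(log(hi), log(lo), length.out = n))
    for (e in ex) out[[length(out) + 1]] <- list(l = laux, exps = e, coefs = 1)
  }
  out
}

#' Build auxiliary (fitting) shells for a molecule
#' @noRd
buildAuxShells <- function(elements, coordsAng, basisName,
                           auxName = "autoaux") {
  if (!identical(tolower(auxName), "autoaux"))
    stop("unknown auxiliary basis '", auxName, "' (only 'autoaux' is provided)")
  bas <- loadBasisSet(basisName)
  tmpl <- list()
  shells <- list()
  nbf <- 0L
  for (ia in seq_along(elements)) {
    el <- elements[ia]
    if (is.null(tmpl[[el]])) tmpl[[el]] <- .autoaux_element(bas[[el]])
    for (isst in seq_along(tmpl[[el]])) {
      sh <- tmpl[[el]][[isst]]
      cf <- sh$coefs * .primNorm(sh$exps, sh$l)
      Q <- .shellQ(sh$l, sh$exps, cf,
                   cachekey = paste("aux", basisName, el, isst, sep = "|"))
      shells[[length(shells) + 1]] <- list(
        l = sh$l, exps = sh$exps, coefs = cf,
        center = as.numeric(coordsAng[ia, ]) * BOHR_PER_ANGSTROM, Q = Q)
      nbf <- nbf + 2L * sh$l + 1L
    }
  }
  attr(shells, "nbf") <- nbf
  shells
}

#' Rigidly translate an engine shell list (shift in Bohr)
#' @noRd
.translateShells <- function(shells, shiftBohr) {
  out <- lapply(shells, function(s) {
    s$center <- s$center + shiftBohr
    s
  })
  attributes(out) <- attributes(shells)
  out
}

#' Number of spherical AO basis functions for a molecule and basis
#' @param mol a [Molecule].
#' @param basis a [BasisSpec] or basis name.
#' @return integer.
#' @export
countBasisFunctions <- function(mol, basis) {
  name <- if (is(basis, "BasisSpec")) basis@name else tolower(basis)
  bas <- loadBasisSet(name)
  sum(vapply(mol@elements, function(el) {
    if (is.null(bas[[el]]))
      stop("basis set '", name, "' has no entry for element ", el)
    sum(vapply(bas[[el]], function(s) 2L * s$l + 1L, integer(1)))
  }, integer(1)))
}
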