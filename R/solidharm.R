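# Real solid harmonic <-> Cartesian monomial transformations.
#
# A shell of angular momentum l is computed in raw Cartesian monomials
# x^i y^j z^k exp(-a r^2) (x-major enumeration, matching the C++ engine) and
# transformed to real solid harmonics S_lm, m = -l..l.  The coefficient
# matrix is obtained by exact least squares against numerically evaluated
# real spherical harmonics on a deterministic spherical point set; overall
# normalization is fixed downstream against the engine's own self-overlap,
# so only the relative coefficients matter here.

.cart_components <- function(l) {
  out <- NULL
  for (lx in l:0) for (ly in (l - lx):0)
    out <- rbind(out, c(lx, ly, l - lx - ly))
  matrix(out, ncol = 3)
}

# associated Legendre P_l^m(x), m >= 0, WITHOUT the Condon-Shortley phase
# (chemistry convention: the l = 1 harmonics are +y, +z, +x)
.legendreP <- function(l, m, x) {
  pmm <- rep(1, length(x))
  if (m > 0) {
    somx2 <- sqrt(pmax(0, 1 - x^2))
    fact <- 1
    for (i in seq_len(m)) {
      pmm <- pmm * fact * somx2
      fact <- fact + 2
    }
  }
  if (l == m) return(pmm)
  pmmp1 <- x * (2 * m + 1) * pmm
  if (l == m + 1) return(pmmp1)
  pll <- NULL
  for (ll in (m + 2):l) {
    pll <- ((2 * ll - 1) * x * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
    pmm <- pmmp1
    pmmp1 <- pll
  }
  pll
}

# real spherical harmonic Y_lm at unit vectors (rows of pts)
.realY <- function(l, m, pts) {
  ct <- pts[, 3]
  phi <- atan2(pts[, 2], pts[, 1])
  am <- abs(m)
  K <- sqrt((2 * l + 1) / (4 * pi) * factorial(l - am) / factorial(l + am))
  P <- .legendreP(l, am, ct)
  if (m > 0) sqrt(2) * K * P * cos(am * phi)
  else if (m < 0) sqrt(2) * K * P * sin(am * phi)
  else K * P
}

.solidharm_cache <- new.env(parent = emptyenv())

#' Solid-harmonic coefficient matrix for angular momentum l
#'
#' Returns the (2l+1) x ncart matrix C with r^l Y_lm = sum_c C[m, c] * monomial_c
#' on the unit sphere (m ordered -l..l).
#' @noRd
solidHarmCoefs <- function(l) {
  key <- as.character(l)
  if (!is.null(.solidharm_cache[[key]])) return(.solidharm_cache[[key]])
  comps <- .cart_components(l)
  nc <- nrow(comps)
  npts <- 4 * nc + 20
  # deterministic Fibonacci sphere
  i <- seq_len(npts) - 0.5
  z <- 1 - 2 * i / npts
  r <- sqrt(pmax(0, 1 - z^2))
  gold <- pi * (3 - sqrt(5))
  pts <- cbind(r * cos(gold * i), r * sin(gold * i), z)
  M <- sapply(seq_len(nc), function(c)
    pts[, 1]^comps[c, 1] * pts[, 2]^comps[c, 2] * pts[, 3]^comps[c, 3])
  Y <- sapply(seq(-l, l), function(m) .realY(l, m, pts))
  C <- t(qr.solve(M, Y))           # (2l+1) x ncart
  C[abs(C) < 1e-12] <- 0
  # exactness check: harmonics are degree-l polynomials, residual ~ 0
  if (max(abs(M %*% t(C) - Y)) > 1e-8)
    stop("solid-harmonic coefficient construction failed for l = ", l)
  .solidharm_cache[[key]] <- C
  C
}
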