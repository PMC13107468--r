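# Particle-in-a-box overlap model for slip-stacked pi systems.
#
# The pi orbitals of a linear acene are approximated by one-dimensional
# box states psi_n(x) = sqrt(2/L) sin(pi n x / L) on [0, L]; the mobile
# monomer's states live on [dx, L + dx].  Carrying out the overlap
# integral S_B(n,m) = int_dx^L psi_A,n psi_B,m dx gives the closed form
# (a = dx / L, 0 <= a <= 1)
#
#   S_B(n,m) = (2/pi) [(-1)^(n+m) n sin(pi m a) - m sin(pi n a)] / (n^2 - m^2)   n != m
#   S_B(n,n) = (1 - a) cos(pi n a) + sin(pi n a) / (n pi)
#
# (note the parity factor multiplies only the n sin(pi m a) term; the
# form is verified against direct quadrature in the test suite).  The
# integral obeys S_B(n,m) = (-1)^(n+m) S_B(m,n).  For a >= 1 the boxes
# are disjoint and every overlap is exactly zero.

PIB_BOX_LENGTH_X <- 15.0  # Angstrom; long-axis extension of pentacene
PIB_BOX_LENGTH_Y <- 6.3   # Angstrom; short-axis model box

#' Construct a particle-in-a-box model specification
#'
#' @param L box length in Angstrom (the extension of the pi system along
#'   the scanned axis).
#' @param N number of occupied model orbitals.
#' @return a [PIBSpec].
#' @export
pibSpec <- function(L, N) new("PIBSpec", L = as.numeric(L), N = as.integer(N))

# real-valued evaluation path (the antiderivative before integer
# simplification); continuous in n and m, used for the continuity check.
# Not part of the public contract.
.pibOverlapReal <- function(n, m, a) {
  out <- numeric(length(a))
  inside <- a < 1
  ai <- a[inside]
  if (abs(n - m) < 1e-12) {
    out[inside] <- (1 - ai) * cos(pi * n * ai) + sin(pi * n * ai) / (n * pi)
  } else {
    out[inside] <-
      (sin((n - m) * pi + m * pi * ai) - sin(n * pi * ai)) / ((n - m) * pi) -
      (sin((n + m) * pi - m * pi * ai) - sin(n * pi * ai)) / ((n + m) * pi)
  }
  out
}

#' Particle-in-a-box overlap S_B(n, m)
#'
#' @param n,m positive integer quantum numbers (box states of monomers A
#'   and B respectively).
#' @param a dimensionless shift dx / L; values >= 1 give exactly 0.
#' @return numeric vector of overlaps, one per element of `a`.
#' @export
pibOverlap <- function(n, m, a) {
  if (length(n) != 1 || length(m) != 1 ||
      n != round(n) || m != round(m) || n < 1 || m < 1)
    stop("quantum numbers n, m must be positive integers")
  if (any(a < 0)) stop("the dimensionless shift a must be >= 0")
  out <- numeric(length(a))
  inside <- a < 1
  ai <- a[inside]
  out[inside] <- if (n == m) {
    (1 - ai) * cos(pi * n * ai) + sin(pi * n * ai) / (n * pi)
  } else {
    2 / pi * ((-1)^(n + m) * n * sin(pi * m * ai) - m * sin(pi * n * ai)) /
      (n^2 - m^2)
  }
  out
}

#' Summed squared box overlaps
#'
#' `pibSqSum` evaluates the N-orbital sum over all squared overlaps,
#' sum_{n,m<=N} S_B(n,m)^2; `pibSqSumMixed` is the two-set combination
#' S^2_N1 + S^2_N2 used for a pi space holding both mirror classes.
#'
#' @param N number of occupied model orbitals.
#' @param a dimensionless shift(s).
#' @return numeric vector, one value per element of `a`.
#' @export
pibSqSum <- function(N, a) {
  if (N != round(N) || N < 1) stop("N must be a positive integer")
  out <- numeric(length(a))
  for (n in seq_len(N)) for (m in seq_len(N))
    out <- out + pibOverlap(n, m, a)^2
  out
}

#' @rdname pibSqSum
#' @param N1,N2 orbital counts of the two classes (defaults 6 and 5).
#' @export
pibSqSumMixed <- function(a, N1 = 6L, N2 = 5L)
  pibSqSum(N1, a) + pibSqSum(N2, a)

#' Sample a particle-in-a-box overlap curve over shifts
#'
#' @param spec a [PIBSpec].
#' @param shifts shift values in Angstrom (>= 0); a = shift / L.
#' @param type "pair" (single S_B(n,m)^2 and S_B(n,m)), "sum" (S^2_N), or
#'   "mixed" (S^2_N + S^2_(N-1)).
#' @param n,m quantum numbers for type = "pair" (default the diagonal
#'   (N, N) element).
#' @return a [ScanResult] with the sampled curve(s).
#' @export
pibCurve <- function(spec, shifts, type = c("pair", "sum", "mixed"),
                     n = spec@N, m = spec@N) {
  type <- match.arg(type)
  if (any(shifts < 0)) stop("shifts must be >= 0")
  a <- shifts / spec@L
  d <- data.frame(shift = shifts)
  units <- c()
  if (type == "pair") {
    d[[sprintf("s_b_%d_%d", n, m)]] <- pibOverlap(n, m, a)
    d[[sprintf("s_b_sq_%d_%d", n, m)]] <- pibOverlap(n, m, a)^2
    units <- c("dimensionless", "dimensionless")
  } else if (type == "sum") {
    d[[sprintf("s_b_sq_sum_%d", spec@N)]] <- pibSqSum(spec@N, a)
    units <- "dimensionless"
  } else {
    d[[sprintf("s_b_sq_mixed_%d_%d", spec@N, spec@N - 1L)]] <-
      pibSqSumMixed(a, spec@N, spec@N - 1L)
    units <- "dimensionless"
  }
  names(units) <- setdiff(names(d), "shift")
  new("ScanResult", data = d, axis = "x",
      units = units,
      provenance = list(model = "particle_in_a_box", L = spec@L, N = spec@N))
}
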