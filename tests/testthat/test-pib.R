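# Particle-in-a-box overlap model.

quadOverlap <- function(n, m, a) {
  if (a >= 1) return(0)
  integrate(function(x) 2 * sin(n * pi * x) * sin(m * pi * (x - a)), a, 1,
            rel.tol = 1e-13)$value
}

test_that("the closed form reproduces direct quadrature", {
  worst <- 0
  for (n in 1:12) for (m in 1:12)
    for (a in c(0, 0.07, 0.25, 0.5, 0.81, 0.999, 1, 1.3)) {
      worst <- max(worst, abs(pibOverlap(n, m, a) - quadOverlap(n, m, a)))
    }
  expect_lt(worst, 1e-10)
})

test_that("orthonormality at zero shift and disjoint boxes beyond L", {
  for (n in 1:6) for (m in 1:6)
    expect_equal(pibOverlap(n, m, 0), as.numeric(n == m), tolerance = 1e-14)
  expect_identical(pibOverlap(3, 3, 1), 0)
  expect_identical(pibOverlap(2, 5, 1.7), 0)
  expect_equal(pibSqSum(6, 0), 6, tolerance = 1e-13)
  expect_identical(pibSqSum(4, 1), 0)
})

test_that("swap symmetry and boundedness hold on a grid", {
  ag <- seq(0, 1, 0.05)
  for (n in 1:12) for (m in 1:12) {
    v1 <- pibOverlap(n, m, ag)
    v2 <- pibOverlap(m, n, ag)
    expect_lt(max(abs(v1 - (-1)^(n + m) * v2)), 1e-13)
    expect_true(all(abs(v1) <= 1))
  }
})

test_that("the n != m branch is continuous at coinciding quantum numbers", {
  for (n in 1:6) for (a in c(0.1, 0.33, 0.77)) {
    lim <- pistack:::.pibOverlapReal(n, n + 1e-6, a)
    expect_lt(abs(lim - pibOverlap(n, n, a)), 1e-5)
  }
})

test_that("known special values are reproduced", {
  expect_equal(pibOverlap(1, 1, 0), 1)
  expect_equal(pibOverlap(2, 1, 0.5), -4 / (3 * pi), tolerance = 1e-13)
  expect_error(pibOverlap(0, 1, 0.5), "positive integers")
  expect_error(pibOverlap(1.5, 1, 0.5), "positive integers")
  expect_error(pibOverlap(1, 1, -0.1), ">= 0")
})

test_that("squared sums agree with brute-force quadrature", {
  for (a in c(0.1, 0.25, 0.6)) {
    ref <- 0
    for (n in 1:2) for (m in 1:2) ref <- ref + quadOverlap(n, m, a)^2
    expect_equal(pibSqSum(2, a), ref, tolerance = 1e-10)
  }
  expect_equal(pibSqSumMixed(0.3, 6, 5), pibSqSum(6, 0.3) + pibSqSum(5, 0.3))
})

test_that("curves scale with the box length and the diagonal has n-1 interior zeros", {
  cvA <- pibCurve(pibSpec(15, 6), seq(0, 15, 0.05), type = "pair",
                  n = 6, m = 6)
  zeros <- featurePositions(findFeatures(cvA, "s_b_6_6"), "zero")
  expect_length(zeros[zeros > 1e-9 & zeros < 15 - 1e-9], 5L)

  # value at shift d for box L equals value at d/2 for box L/2
  cvB <- pibCurve(pibSpec(7.5, 6), seq(0, 7.5, 0.025), type = "pair",
                  n = 6, m = 6)
  expect_equal(scanData(cvA)$s_b_6_6, scanData(cvB)$s_b_6_6,
               tolerance = 1e-12)

  # values identically zero beyond L
  cvC <- pibCurve(pibSpec(5, 3), seq(0, 8, 0.5), type = "sum")
  d <- scanData(cvC)
  expect_true(all(d[[2]][d$shift >= 5] == 0))
})
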