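test_that("formal derivative follows the calculus rules", {
  a <- c(2.5, -1.25, 7)
  p <- Poly(c(1, a))                       # x^3 + a1 x^2 + a2 x + a3
  expect_equal(polyDerivative(p)@coeffs, c(3, 2 * a[1L], a[2L]))
  expect_warning(d0 <- polyDerivative(Poly(5)), "constant")
  expect_equal(d0@coeffs, 0)
  set.seed(3)
  for (k in 1:20) {
    d <- sample(2:9, 1L)
    p <- Poly(c(runif(1, 0.5, 2), rnorm(d)))
    expect_equal(polyDegree(polyDerivative(p)), d - 1L)
  }
})

test_that("rPolynomial expands det(xI + J^2) with the right structure", {
  ## 2 x 2: x^2 + Tr(J^2) x + det(J^2)
  set.seed(21)
  for (k in 1:10) {
    J <- matrix(rnorm(4), 2)
    A <- J %*% J
    expect_equal(rPolynomial(J)@coeffs,
                 c(1, sum(diag(A)), det(A)), tolerance = 1e-9)
  }
  ## worked example: J^2 = [[-3, -4], [4, -3]]
  expect_equal(rPolynomial(matrix(c(-1, -2, 2, -1), 2))@coeffs,
               c(1, -6, 25))
  ## constant term is det(J)^2 >= 0
  for (k in 1:50) {
    n <- sample(2:6, 1L)
    J <- matrix(rnorm(n * n), n)
    cf <- rPolynomial(J)@coeffs
    expect_equal(cf[length(cf)], det(J)^2, tolerance = 1e-8)
    expect_gte(cf[length(cf)], 0)
  }
})

test_that("Sturm chains have the canonical structure", {
  ## x^2 - 1 -> (x^2 - 1, 2x, 1) up to positive scaling of each member
  ch <- sturmChain(Poly(c(1, 0, -1)))
  expect_length(ch@polys, 3L)
  expect_proportional(ch@polys[[1L]]@coeffs, c(1, 0, -1))
  expect_proportional(ch@polys[[2L]]@coeffs, c(2, 0))
  expect_proportional(ch@polys[[3L]]@coeffs, 1)
  expect_true(ch@exact)

  ## repeated root: chain stops at the nonconstant gcd, root counted once
  ch2 <- sturmChain(Poly(c(1, -2, 1)))     # (x - 1)^2
  expect_length(ch2@polys, 2L)
  expect_gt(polyDegree(ch2@polys[[2L]]), 0L)
  expect_equal(as.integer(countPositiveRoots(Poly(c(1, -2, 1)))), 1L)

  set.seed(17)
  for (k in 1:25) {
    d <- sample(2:8, 1L)
    p <- Poly(sample(c(-9:-1, 1:9), d + 1L, replace = TRUE))
    ch <- sturmChain(p)
    expect_lte(length(ch@polys), d + 1L)
    ## float path must agree with the exact path on the same polynomial
    chF <- sturmChain(p, exact = FALSE)
    expect_equal(signChangesAt(chF, "zero") - signChangesAt(chF, "inf"),
                 signChangesAt(ch, "zero") - signChangesAt(ch, "inf"))
  }
})

test_that("sign-change counting follows the Sturm conventions", {
  ch <- sturmChain(Poly(c(1, 0, -1)))      # roots -1 and 1
  expect_equal(signChangesAt(ch, "zero") - signChangesAt(ch, "inf"), 1L)
  ch2 <- sturmChain(Poly(c(1, 0, 1)))      # no real roots
  expect_equal(signChangesAt(ch2, "zero") - signChangesAt(ch2, "inf"), 0L)
  ## sigma is invariant under positive scaling of any chain member
  scaled <- new("SturmChain",
                polys = mapply(function(p, s) Poly(s * p@coeffs),
                               ch@polys, c(3, 0.5, 7)),
                exact = FALSE)
  for (at in list("zero", "inf", 0.5, 2))
    expect_equal(signChangesAt(scaled, at), signChangesAt(ch, at))
  ## finite evaluation points bracket the positive root of x^2 - 1
  expect_equal(signChangesAt(ch, 0.5) - signChangesAt(ch, 2), 1L)
})

test_that("positive-root counts are exact against the companion oracle", {
  ## factored constructions
  expect_equal(as.integer(countPositiveRoots(Poly(c(1, 0, -7, 6)))), 2L)
  # ^ (x-1)(x-2)(x+3)
  expect_equal(as.integer(countPositiveRoots(Poly(c(1, 0, 1)))), 0L)
  expect_error(countPositiveRoots(Poly(0)), "zero polynomial")
  ## root at zero is deflated and reported separately
  withZero <- countPositiveRoots(Poly(c(1, -1, 0)))   # x(x - 1)
  expect_equal(as.integer(withZero), 1L)
  expect_equal(attr(withZero, "nZeroRoots"), 1L)

  ## 500 random integer polynomials, degrees 2-8: zero mismatches
  set.seed(2024)
  mismatches <- 0L
  for (k in 1:500) {
    d <- sample(2:8, 1L)
    cf <- sample(c(-9:-1, 1:9), d + 1L, replace = TRUE)
    got <- as.integer(countPositiveRoots(Poly(cf)))
    want <- companionCountPositive(cf)
    if (got != want) mismatches <- mismatches + 1L
  }
  expect_identical(mismatches, 0L)
})

test_that("Descartes' bound dominates the exact count with equal parity", {
  expect_equal(descartesBound(Poly(c(1, -3, 2))), 2L)
  expect_equal(descartesBound(Poly(c(1, 1, 1))), 0L)
  set.seed(99)
  for (k in 1:500) {
    d <- sample(2:8, 1L)
    cf <- sample(c(-9:-1, 1:9), d + 1L, replace = TRUE)
    p <- Poly(cf)
    bound <- descartesBound(p)
    cnt <- as.integer(countPositiveRoots(p))
    expect_gte(bound, cnt)
    expect_equal((bound - cnt) %% 2L, 0L)
  }
})

test_that("mode counting isolates and classifies the minima of R", {
  ## R = x^2 - 6x + 25: R' = 2x - 6, single minimum at x = 3
  mc <- countResonantModes(matrix(c(-1, -2, 2, -1), 2))
  expect_equal(nModes(mc), 1L)
  cp <- criticalPoints(mc)
  expect_equal(cp$kind, "minimum")
  expect_equal(cp$x, 3, tolerance = 1e-8)
  expect_equal(resonantFrequencies(mc), sqrt(3), tolerance = 1e-8)

  ## three-species oscillatory regime: one mode, confirmed by direct grid
  ## minimization of det(J^2 + xI)
  J3 <- jacobianMatrix(autocatalyticNetwork(3, r = 1, alpha = 0.1,
                                            beta = 0.1))
  mc3 <- countResonantModes(J3)
  expect_equal(nModes(mc3), 1L)
  oracle <- gridCountMinima(J3, xmax = 10)
  expect_equal(oracle$count, 1L)
  expect_equal(resonantFrequencies(mc3)^2, oracle$x, tolerance = 1e-3)

  ## five-species two-resonance regime
  mc5 <- countResonantModes(autocatalyticNetwork(5, 4, 0.01, 0.01))
  expect_equal(nModes(mc5), 2L)
})

test_that("mode-count invariants hold on random stable systems", {
  for (s in 1:50) {
    n <- 2L + (s %% 5L)
    J <- jacobianMatrix(randomStableSystem(n, seed = 1000L + s))
    mc <- countResonantModes(J)
    expect_lte(nModes(mc), n %/% 2L)
    cf <- mc@rpoly@coeffs
    expect_gte(cf[length(cf)], 0)          # R(0) = det(J)^2 >= 0
    cp <- criticalPoints(mc)
    if (nrow(cp) && !any(cp$kind == "inflection")) {
      ## R -> +inf, so the largest critical point is a minimum and kinds
      ## alternate
      expect_equal(cp$kind[nrow(cp)], "minimum")
      expect_true(all(cp$kind[-nrow(cp)] !=
                        cp$kind[-1L]))
    }
  }
})

test_that("disconnected systems are analysed per component", {
  J1 <- matrix(c(-1, -2, 2, -1), 2)          # one mode
  J2 <- matrix(c(-2, 0.5, 0.5, -1), 2)       # connected, no modes
  J <- matrix(0, 4, 4)                       # block diagonal 4 x 4
  J[1:2, 1:2] <- J1
  J[3:4, 3:4] <- J2
  mc <- countResonantModes(J)
  expect_length(mc@components, 2L)
  expect_equal(nModes(mc), 1L)
  expect_equal(vapply(mc@components, nModes, integer(1L)), c(1L, 0L))
})

test_that("three-species resonance condition matches the exact machinery", {
  expect_equal(n3ResonanceCondition(0, 1), "no_resonance")
  expect_equal(n3ResonanceCondition(-3, 1), "resonance")
  ## quadratic-formula oracle over a grid of (a1, a2)
  a1s <- seq(-5, 5, length.out = 100L)
  a2s <- seq(-5, 5, length.out = 100L)
  for (a1 in a1s[seq(1, 100, by = 7)]) {
    for (a2 in a2s) {
      disc <- 4 * a1^2 - 12 * a2
      oracle <- if (disc > 0 && (-2 * a1 + sqrt(disc)) / 6 > 1e-12)
        "resonance" else "no_resonance"
      expect_equal(n3ResonanceCondition(a1, a2), oracle)
    }
  }
  ## and against countResonantModes on random stable 3 x 3 Jacobians
  for (s in 1:1000) {
    J <- jacobianMatrix(randomStableSystem(3, seed = 5000L + s))
    cf <- rPolynomial(J)@coeffs
    expect_equal(n3ResonanceCondition(cf[2L], cf[3L]) == "resonance",
                 nModes(countResonantModes(J)) >= 1L)
  }
})
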