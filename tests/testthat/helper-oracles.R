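## Independent oracles used across the suite.  These deliberately avoid the
## package's own code paths: root counting goes through companion-matrix
## eigenvalues, characteristic polynomials through determinant evaluation
## plus interpolation, Jacobians through finite differences, and cycle
## enumeration through brute force over vertex subsets and circular orders.

## Count distinct real roots > 0 of a polynomial given by descending
## coefficients, via the eigenvalues of its companion matrix.
companionCountPositive <- function(coeffs, tol = 1e-9) {
  cf <- coeffs / coeffs[1L]
  d <- length(cf) - 1L
  if (d == 0L) return(0L)
  C <- matrix(0, d, d)
  if (d > 1L) C[cbind(2:d, 1:(d - 1L))] <- 1
  C[1L, ] <- -cf[-1L]
  ev <- eigen(C, only.values = TRUE)$values
  re <- Re(ev[abs(Im(ev)) < tol & Re(ev) > tol])
  if (!length(re)) return(0L)
  re <- sort(re)
  as.integer(sum(c(TRUE, diff(re) > tol * pmax(1, re[-1L]))))
}

## Coefficients (descending) of det(xI + M) by evaluating the determinant
## at n+1 points and solving the Vandermonde system.
oracleCharCoeffs <- function(M) {
  n <- nrow(M)
  pts <- seq_len(n + 1L) - 1L
  vals <- vapply(pts, function(x) det(x * diag(n) + M), numeric(1L))
  V <- outer(pts, n:0, `^`)
  as.numeric(solve(V, vals))
}

## Central finite-difference Jacobian of f at x.
fdJacobian <- function(f, x, h = 1e-6) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- h
    J[, j] <- (f(x + e) - f(x - e)) / (2 * h)
  }
  J
}

## Safeguarded Newton iteration for a root of f inside the positive
## orthant (the rate equations are defined on nonnegative states):
## backtracking line search on max|f|, steps halved until they stay
## positive and decrease the residual.
newtonFixedPoint <- function(f, x0, tol = 1e-12, maxIt = 200L) {
  x <- x0
  nf <- max(abs(f(x)))
  for (it in seq_len(maxIt)) {
    if (nf < tol) break
    step <- solve(fdJacobian(f, x), f(x))
    t <- 1
    repeat {
      xn <- x - t * step
      if (all(xn > 0)) {
        nfn <- max(abs(f(xn)))
        if (nfn < nf || t < 1e-6) break
      }
      t <- t / 2
      if (t < 1e-8) { xn <- x; nfn <- nf; break }
    }
    x <- xn
    nf <- nfn
  }
  x
}

## All permutations of a vector (small n only).
permsOf <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in permsOf(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
  out
}

## Brute-force simple directed cycles of the graph with edge-weight matrix
## W (W[i, j] != 0 <=> edge i -> j): every vertex subset, anchored at its
## minimum, in every circular order.  Returns canonical vertex sequences.
bruteCycles <- function(W) {
  n <- nrow(W)
  out <- list()
  for (k in seq_len(n)) {
    subs <- utils::combn(n, k, simplify = FALSE)
    for (S in subs) {
      anchor <- S[1L]
      rest <- S[-1L]
      arrangements <- if (length(rest)) permsOf(rest) else list(integer(0L))
      for (arr in arrangements) {
        vs <- c(anchor, arr)
        edges <- cbind(vs, c(vs[-1L], vs[1L]))
        if (all(W[edges] != 0))
          out[[length(out) + 1L]] <- vs
      }
    }
  }
  out
}

## Brute-force factors of degree k: subsets of pairwise disjoint brute
## cycles covering exactly k vertices.  Returns the number found.
bruteFactorCount <- function(W, k) {
  cyc <- bruteCycles(W)
  cnt <- 0L
  pick <- function(start, used, covered) {
    if (covered == k) { cnt <<- cnt + 1L; return(invisible()) }
    if (start > length(cyc)) return(invisible())
    for (i in start:length(cyc)) {
      vs <- cyc[[i]]
      if (covered + length(vs) > k || any(used[vs])) next
      used[vs] <- TRUE
      pick(i + 1L, used, covered + length(vs))
      used[vs] <- FALSE
    }
  }
  pick(1L, logical(nrow(W)), 0L)
  cnt
}

## Matrix exponential action exp(J*t) %*% x0 through the eigendecomposition.
expmTimes <- function(J, t, x0) {
  e <- eigen(J)
  Re(e$vectors %*% (exp(e$values * t) * solve(e$vectors, x0)))
}

## Proportionality up to a positive scalar (Sturm chains are only defined
## up to positive scaling of each member).
expect_proportional <- function(got, want) {
  expect_equal(length(got), length(want))
  i <- which.max(abs(want))
  expect_gt(got[i] / want[i], 0)
  expect_equal(got / (got[i] / want[i]), want, tolerance = 1e-12)
}

## Count interior local minima of det(J^2 + x I) on a fine grid: the
## direct numeric oracle for mode counting.
gridCountMinima <- function(J, xmax, N = 20000L) {
  A <- J %*% J
  n <- nrow(A)
  xs <- seq(0, xmax, length.out = N)
  v <- vapply(xs, function(x) det(A + x * diag(n)), numeric(1L))
  i <- 2L:(N - 1L)
  idx <- which(v[i] < v[i - 1L] & v[i] <= v[i + 1L])
  list(count = length(idx), x = xs[i[idx]])
}
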