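## Largest integer magnitude allowed in the exact (fraction-free) Sturm
## pipeline; beyond this doubles can no longer represent integers exactly
## with headroom for one multiply-accumulate.
.EXACT_LIMIT <- 2^50

#' Construct a polynomial
#'
#' @param coeffs numeric coefficients in descending powers; exact leading
#'   zeros are trimmed
#' @return a \linkS4class{Poly}
#' @examples
#' Poly(c(1, -6, 25))   # x^2 - 6x + 25
#' @export
Poly <- function(coeffs) {
  coeffs <- as.numeric(coeffs)
  while (length(coeffs) > 1L && coeffs[1L] == 0) coeffs <- coeffs[-1L]
  new("Poly", coeffs = coeffs)
}

#' Polynomial degree
#' @param p a \linkS4class{Poly}
#' @return integer degree (0 for constants, including the zero polynomial)
#' @export
polyDegree <- function(p) length(p@coeffs) - 1L

#' Evaluate a polynomial
#' @param p a \linkS4class{Poly}
#' @param x numeric vector of evaluation points
#' @return numeric vector, Horner evaluation
#' @export
polyEval <- function(p, x) {
  out <- rep(0, length(x))
  for (c_i in p@coeffs) out <- out * x + c_i
  out
}

#' Formal derivative
#'
#' @param p a \linkS4class{Poly} of degree >= 1; a constant input yields
#'   the zero polynomial with a warning
#' @return a \linkS4class{Poly} of degree one less
#' @export
polyDerivative <- function(p) {
  d <- polyDegree(p)
  if (d == 0L) {
    warning("derivative of a constant polynomial is zero")
    return(Poly(0))
  }
  Poly(p@coeffs[seq_len(d)] * (d:1))
}

setMethod("show", "Poly", function(object) {
  cf <- object@coeffs
  d <- length(cf) - 1L
  terms <- character(0L)
  for (i in seq_along(cf)) {
    pw <- d - i + 1L
    if (cf[i] == 0 && d > 0L) next
    mono <- if (pw == 0L) "" else if (pw == 1L) "x" else sprintf("x^%d", pw)
    terms <- c(terms, paste0(format(cf[i], digits = 6), mono))
  }
  cat("Poly:", paste(terms, collapse = " + "), "\n")
})

## --- internal coefficient-vector helpers (descending powers) ------------

.trimLead <- function(v, tol = 0) {
  if (tol > 0) {
    s <- max(abs(v), 0)
    while (length(v) > 1L && abs(v[1L]) <= tol * s) v <- v[-1L]
  } else {
    while (length(v) > 1L && v[1L] == 0) v <- v[-1L]
  }
  v
}

.isZeroVec <- function(v, tol = 0) all(abs(v) <= tol)

## gcd of integer-valued doubles
.igcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

.content <- function(v) {
  g <- 0
  for (x in v) { g <- .igcd(g, x); if (g == 1) break }
  if (g == 0) 1 else g
}

.isIntegerPoly <- function(v) {
  all(v == round(v)) && max(abs(v)) < .EXACT_LIMIT
}

## Floating remainder of polynomial long division f / g, descending coeffs.
.polyRem <- function(f, g) {
  dg <- length(g) - 1L
  r <- f
  while (length(r) - 1L >= dg && !.isZeroVec(r)) {
    q <- r[1L] / g[1L]
    k <- length(r) - length(g)
    r[seq_len(length(g))] <- r[seq_len(length(g))] - q * g
    r[1L] <- 0
    r <- r[-1L]
    if (!length(r)) r <- 0
  }
  r
}

## --- internal Sturm-chain machinery on plain coefficient vectors --------
## (the hot path of phase-diagram scans; S4 wrappers sit on top)

## Fraction-free Sturm step: returns the next chain member as a positive
## multiple of -rem(f, g), in integer arithmetic, or NULL on overflow.
.sturmStepExact <- function(f, g) {
  dg <- length(g) - 1L
  lcg <- g[1L]
  r <- f
  m <- 0L
  while (length(r) - 1L >= dg && !all(r == 0)) {
    if (abs(lcg) * max(abs(r)) > .EXACT_LIMIT ||
        abs(r[1L]) * max(abs(g)) > .EXACT_LIMIT)
      return(NULL)
    gpad <- c(g, rep(0, length(r) - length(g)))
    rnew <- lcg * r - r[1L] * gpad
    if (max(abs(rnew)) > .EXACT_LIMIT) return(NULL)
    rnew[1L] <- 0
    r <- .trimLead(rnew[-1L])
    if (!length(r)) r <- 0
    m <- m + 1L
  }
  if (all(r == 0)) return(numeric(0L))        # zero remainder: chain ends
  r <- -r * sign(lcg)^m                       # sign of true -rem(f, g)
  r / .content(r)
}

#' Sturm chain of a polynomial
#'
#' Builds \eqn{p_0 = p}, \eqn{p_1 = p'},
#' \eqn{p_{i+1} = -\mathrm{rem}(p_{i-1}, p_i)} until the remainder
#' vanishes.  For a polynomial with repeated roots the chain terminates
#' early at a nonconstant gcd; sign-change counting then still counts
#' distinct roots.  Integer-coefficient input is processed fraction-free in
#' exact arithmetic (chain members are positive integer multiples of the
#' canonical ones, which leaves all sign counts unchanged); other input, or
#' integer input whose intermediate coefficients would overflow exact
#' double-precision integers, uses floating arithmetic with a relative
#' zero tolerance.
#'
#' @param p a \linkS4class{Poly} of degree >= 1
#' @param exact force (\code{TRUE}) or forbid (\code{FALSE}) the exact
#'   path; \code{NA} (default) chooses automatically
#' @param zeroTol relative tolerance below which floating coefficients are
#'   treated as zero
#' @return a \linkS4class{SturmChain}
#' @examples
#' sturmChain(Poly(c(1, 0, -1)))   # x^2 - 1 -> (x^2 - 1, 2x, 1)
#' @export
sturmChain <- function(p, exact = NA, zeroTol = 1e-12) {
  stopifnot(is(p, "Poly"))
  if (polyDegree(p) < 1L) stop("need degree >= 1")
  cf <- p@coeffs
  useExact <- if (is.na(exact)) .isIntegerPoly(cf) else isTRUE(exact)
  if (useExact && !.isIntegerPoly(cf))
    stop("exact = TRUE requires integer coefficients within 2^50")
  ch <- .chainBuild(cf, useExact, zeroTol)
  new("SturmChain", polys = lapply(ch$chain, Poly), exact = ch$exact)
}

## Build a Sturm chain as a list of coefficient vectors.
.chainBuild <- function(cf, useExact, zeroTol = 1e-12) {
  d <- length(cf) - 1L
  if (useExact) {
    chain <- list(cf / .content(cf))
    dv <- cf[seq_len(d)] * (d:1)
    chain[[2L]] <- dv / .content(dv)
    ok <- TRUE
    repeat {
      nxt <- .sturmStepExact(chain[[length(chain) - 1L]],
                             chain[[length(chain)]])
      if (is.null(nxt)) { ok <- FALSE; break }   # overflow: redo in float
      if (!length(nxt)) break
      chain[[length(chain) + 1L]] <- nxt
      if (length(nxt) == 1L) break
    }
    if (ok) return(list(chain = chain, exact = TRUE))
  }
  norm1 <- function(v) v / max(abs(v))
  chain <- list(norm1(cf))
  chain[[2L]] <- norm1(cf[seq_len(d)] * (d:1))
  repeat {
    f <- chain[[length(chain) - 1L]]
    g <- chain[[length(chain)]]
    r <- .polyRem(f, g)
    if (.isZeroVec(r, zeroTol * max(abs(f)))) break
    r <- .trimLead(r, zeroTol)
    chain[[length(chain) + 1L]] <- norm1(-r)
    if (length(r) == 1L) break
  }
  list(chain = chain, exact = FALSE)
}

.hornerVec <- function(cf, x) {
  out <- 0
  for (c_i in cf) out <- out * x + c_i
  out
}

## sign changes of a raw chain at a numeric point / zero / infinity
.chainSigns <- function(chain, at, zeroTol = 1e-12) {
  vals <- if (identical(at, "inf")) {
    vapply(chain, function(v) v[1L], numeric(1L))
  } else if (identical(at, "zero")) {
    vapply(chain, function(v) v[length(v)], numeric(1L))
  } else {
    vapply(chain, function(v) {
      y <- .hornerVec(v, at)
      if (abs(y) <= zeroTol * max(abs(v))) 0 else y
    }, numeric(1L))
  }
  .signChanges(vals)
}

setMethod("show", "SturmChain", function(object) {
  cat(sprintf("SturmChain of length %d (%s arithmetic)\n",
              length(object@polys),
              if (object@exact) "exact integer" else "floating"))
  for (p in object@polys) show(p)
})

## sign changes in a numeric sequence, zeros skipped
.signChanges <- function(v) {
  s <- sign(v)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(s[-1L] != s[-length(s)])
}

#' Sign changes of a Sturm chain at a point
#'
#' At \code{"inf"} the chain member signs are those of the leading
#' coefficients; at \code{"zero"} those of the constant terms; at a finite
#' numeric point the members are evaluated.  Zero values are skipped.
#'
#' @param chain a \linkS4class{SturmChain}
#' @param at \code{"zero"}, \code{"inf"}, or a single finite number
#' @param zeroTol relative tolerance for treating a floating evaluation as
#'   zero
#' @return integer number of sign changes
#' @export
signChangesAt <- function(chain, at, zeroTol = 1e-12) {
  stopifnot(is(chain, "SturmChain"))
  if (!identical(at, "inf") && !identical(at, "zero") &&
      !(is.numeric(at) && length(at) == 1L && is.finite(at)))
    stop("'at' must be \"zero\", \"inf\" or a finite number")
  .chainSigns(lapply(chain@polys, function(p) p@coeffs), at, zeroTol)
}

#' Exact count of distinct positive real roots
#'
#' Sturm's theorem with endpoints \eqn{a = 0}, \eqn{b = \infty}.  A root
#' exactly at zero is deflated first (the count concerns the open interval
#' \eqn{(0, \infty)}); its multiplicity is reported in the
#' \code{nZeroRoots} attribute.
#'
#' @param p a \linkS4class{Poly}, not identically zero
#' @param exact,zeroTol passed to [sturmChain()]
#' @return integer count with attribute \code{nZeroRoots}
#' @examples
#' countPositiveRoots(Poly(c(1, -3, 2)))   # (x-1)(x-2): 2
#' countPositiveRoots(Poly(c(1, 0, 1)))    # x^2 + 1: 0
#' @export
countPositiveRoots <- function(p, exact = NA, zeroTol = 1e-12) {
  stopifnot(is(p, "Poly"))
  cf <- p@coeffs
  if (all(cf == 0)) stop("zero polynomial has no well-defined root count")
  scale <- max(abs(cf))
  nz <- 0L
  while (length(cf) > 1L && abs(cf[length(cf)]) <= zeroTol * scale) {
    cf <- cf[-length(cf)]
    nz <- nz + 1L
  }
  if (length(cf) == 1L) {            # p was c * x^k
    out <- 0L
    attr(out, "nZeroRoots") <- nz
    return(out)
  }
  useExact <- if (is.na(exact)) .isIntegerPoly(cf) else isTRUE(exact)
  ch <- .chainBuild(cf, useExact, zeroTol)$chain
  out <- .chainSigns(ch, "zero", zeroTol) - .chainSigns(ch, "inf", zeroTol)
  attr(out, "nZeroRoots") <- nz
  out
}

#' Descartes' bound on positive roots
#'
#' The number of sign changes among consecutive nonzero coefficients in
#' descending order: an upper bound on the number of positive real roots,
#' attained up to an even difference (multiple roots counted with
#' multiplicity).
#' @param p a nonzero \linkS4class{Poly}
#' @return integer bound
#' @export
descartesBound <- function(p) {
  stopifnot(is(p, "Poly"))
  if (all(p@coeffs == 0)) stop("zero polynomial")
  .signChanges(p@coeffs)
}

#' Spectrum denominator R as a polynomial in x = omega^2
#'
#' Computes \eqn{R(x) = \det(xI + J^2)} by the Faddeev--LeVerrier
#' recursion on \eqn{A = J^2} (exact for integer matrices within
#' double-precision integer range).  \eqn{R} equals the characteristic
#' polynomial of \eqn{J^2} under \eqn{\omega^2 = -\lambda}; its leading
#' coefficient is 1 and its constant term is \eqn{\det(J)^2 \ge 0}.
#'
#' @param x a square matrix (taken as J), a \linkS4class{JacobianSystem}
#'   or an \linkS4class{AutocatalyticNetwork}
#' @return a monic \linkS4class{Poly} of degree \code{n}
#' @examples
#' rPolynomial(matrix(c(-1, -2, 2, -1), 2))   # x^2 - 6x + 25
#' @export
rPolynomial <- function(x) {
  J <- jacobianMatrix(x)
  if (nrow(J) != ncol(J)) stop("Jacobian must be square")
  A <- J %*% J
  n <- nrow(A)
  ## Faddeev-LeVerrier: det(xI - A) = x^n + c1 x^(n-1) + ... + cn
  cvec <- numeric(n)
  M <- A
  cvec[1L] <- -sum(diag(M))
  if (n > 1L) for (k in 2:n) {
    M <- A %*% (M + cvec[k - 1L] * diag(n))
    cvec[k] <- -sum(diag(M)) / k
  }
  ## det(xI + A) = sum_k e_k(lambda) x^(n-k), e_k = (-1)^k c_k
  a <- (-1)^(seq_len(n)) * cvec
  Poly(c(1, a))
}

## Cauchy root bound: all real roots lie in [-B, B].
.cauchyBound <- function(p) {
  cf <- if (is(p, "Poly")) p@coeffs else p
  1 + max(abs(cf[-1L] / cf[1L]), 0)
}

## Geometric scale of the roots of a coefficient vector (|a_m/a_0|^(1/m)
## over the trailing nonzero coefficient): substituting x = s*y makes the
## typical root O(1), which keeps the floating Sturm chain well
## conditioned when all critical points are far from 1 in magnitude.
.rootScale <- function(cf) {
  nz <- which(cf != 0)
  m <- nz[length(nz)]
  if (m == 1L) return(1)
  s <- abs(cf[m] / cf[1L])^(1 / (m - 1))
  if (!is.finite(s) || s <= 0) 1 else s
}

## p(s*y) as a coefficient vector in y, normalized to unit max coefficient
.rescaleCoeffs <- function(cf, s) {
  d <- length(cf) - 1L
  v <- cf * s^(d:0)
  v / max(abs(v))
}

## Isolate the distinct roots of chain[[1]] in (0, bound] into intervals
## each holding exactly one root, then refine by count-bisection.
## `chain` is a raw coefficient-vector chain (roots assumed O(1)).
.isolatePositiveRoots <- function(chain, bound, relTol = 1e-10,
                                  maxDepth = 200L) {
  p0 <- chain[[1L]]
  cntIn <- function(a, b) .chainSigns(chain, a) - .chainSigns(chain, b)
  ## nudge an evaluation point off a root of p0
  nudge <- function(t, h) {
    k <- 0L
    while (abs(.hornerVec(p0, t)) <= 1e-13 && k < 60L) {
      t <- t + h * 2^-(k + 1L)
      k <- k + 1L
    }
    t
  }
  stack <- list(c(0, bound))
  found <- list()
  while (length(stack)) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    cnt <- cntIn(iv[1L], iv[2L])
    if (cnt <= 0L) next
    if (cnt == 1L) { found[[length(found) + 1L]] <- iv; next }
    mid <- nudge(mean(iv), diff(iv) / 64)
    stack[[length(stack) + 1L]] <- c(iv[1L], mid)
    stack[[length(stack) + 1L]] <- c(mid, iv[2L])
  }
  out <- lapply(found, function(iv) {
    a <- iv[1L]; b <- iv[2L]
    fa <- .hornerVec(p0, a); fb <- .hornerVec(p0, b)
    depth <- 0L
    if (fa * fb < 0) {
      ## simple root: ordinary sign bisection (one evaluation per step)
      while ((b - a) > relTol * max(1, b) && depth < maxDepth) {
        mid <- (a + b) / 2
        fm <- .hornerVec(p0, mid)
        if (fm == 0) { a <- b <- mid; break }
        if (fa * fm < 0) { b <- mid; fb <- fm } else { a <- mid; fa <- fm }
        depth <- depth + 1L
      }
    } else {
      ## even multiplicity: fall back to Sturm-count bisection
      while ((b - a) > relTol * max(1, b) && depth < maxDepth) {
        mid <- nudge((a + b) / 2, (b - a) / 64)
        if (cntIn(a, mid) >= 1L) b <- mid else a <- mid
        depth <- depth + 1L
      }
    }
    c(a, b)
  })
  out[order(vapply(out, mean, numeric(1L)))]
}

#' @describeIn countResonantModes workhorse on a plain Jacobian matrix.
#'   When the graph of \code{J} is disconnected, each weakly connected
#'   component (a diagonal block of \code{J} up to relabelling) is analysed
#'   separately; the returned object sums the per-component mode counts and
#'   keeps the per-component results in \code{@components}.
#' @param zeroTol relative tolerance for structural zeros of \code{J}
#' @param refineTol relative width to which each critical point is
#'   isolated
#' @export
setMethod("countResonantModes", "matrix",
          function(x, zeroTol = 1e-12, refineTol = 1e-10, ...) {
  J <- x
  if (nrow(J) != ncol(J)) stop("Jacobian must be square")
  comps <- .weakComponents(J, zeroTol)
  if (length(comps) > 1L) {
    parts <- lapply(comps, function(idx)
      countResonantModes(J[idx, idx, drop = FALSE],
                         zeroTol = zeroTol, refineTol = refineTol))
    cp <- do.call(rbind, lapply(parts, criticalPoints))
    cp <- cp[order(cp$x), , drop = FALSE]
    rownames(cp) <- NULL
    return(new("ModeCount",
               nModes = sum(vapply(parts, nModes, integer(1L))),
               criticalPoints = cp, rpoly = rPolynomial(J),
               nSpecies = nrow(J), method = "sturm",
               components = parts))
  }
  Rp <- rPolynomial(J)
  dcf <- Rp@coeffs[seq_len(length(Rp@coeffs) - 1L)] *
    ((length(Rp@coeffs) - 1L):1L)
  cp <- data.frame(x = numeric(0L), omega = numeric(0L),
                   kind = character(0L), stringsAsFactors = FALSE)
  ## rescale x = s*y so the critical points are O(1), then count, isolate
  ## and classify in y (positive scaling preserves signs and order)
  s <- .rootScale(dcf)
  ycf <- .rescaleCoeffs(dcf, s)
  m <- 0L
  if (length(ycf) >= 2L) {     # R' non-constant (n >= 2)
    ch <- .chainBuild(ycf, .isIntegerPoly(ycf), zeroTol)$chain
    m <- .chainSigns(ch, "zero") - .chainSigns(ch, "inf")
  }
  if (m > 0L) {
    ivs <- .isolatePositiveRoots(ch, .cauchyBound(ycf), relTol = refineTol)
    roots <- vapply(ivs, mean, numeric(1L))
    ## classify by the sign of R' at separators between consecutive roots:
    ## robust because the separators are far (half a root gap) from every
    ## root, unlike points just outside the refined interval
    sep <- c(roots[1L] / 2,
             if (length(roots) > 1L)
               (roots[-length(roots)] + roots[-1L]) / 2,
             roots[length(roots)] + max(1, roots[length(roots)]))
    sgn <- sign(vapply(sep, function(t) .hornerVec(ycf, t), numeric(1L)))
    rows <- lapply(seq_along(roots), function(i) {
      kind <- if (sgn[i] < 0 && sgn[i + 1L] > 0) "minimum"
              else if (sgn[i] > 0 && sgn[i + 1L] < 0) "maximum"
              else "inflection"
      xr <- s * roots[i]
      data.frame(x = xr,
                 omega = if (kind == "minimum") sqrt(xr) else NA_real_,
                 kind = kind, stringsAsFactors = FALSE)
    })
    cp <- do.call(rbind, rows)
    if (any(cp$kind == "inflection"))
      warning("degenerate critical point of R classified as inflection; ",
              "excluded from the mode count")
    ## R -> +infinity, so the largest critical point must be a minimum
    ## whenever all critical points are simple
    if (!any(cp$kind == "inflection") &&
        cp$kind[nrow(cp)] != "minimum")
      warning("largest critical point is not a minimum; ",
              "numerical trouble likely (small Sturm coefficients)")
  }
  new("ModeCount", nModes = sum(cp$kind == "minimum"),
      criticalPoints = cp, rpoly = Rp, nSpecies = nrow(J),
      method = "sturm", components = list())
})

#' @describeIn countResonantModes on a wrapped system
#' @export
setMethod("countResonantModes", "JacobianSystem",
          function(x, ...) countResonantModes(jacobianMatrix(x), ...))

#' @describeIn countResonantModes on the autocatalytic family (closed-form
#'   Jacobian at the steady state)
#' @export
setMethod("countResonantModes", "AutocatalyticNetwork",
          function(x, ...) countResonantModes(jacobianMatrix(x), ...))

#' @describeIn nModes number of resonant modes found
#' @export
setMethod("nModes", "ModeCount", function(object) object@nModes)

#' @describeIn criticalPoints critical points with classification
#' @export
setMethod("criticalPoints", "ModeCount",
          function(object) object@criticalPoints)

#' @describeIn resonantFrequencies \eqn{\omega_R = \sqrt{x}} at each
#'   minimum of R
#' @export
setMethod("resonantFrequencies", "ModeCount", function(object) {
  cp <- object@criticalPoints
  cp$omega[cp$kind == "minimum"]
})

setMethod("show", "ModeCount", function(object) {
  cat(sprintf("ModeCount: %d resonant mode%s for an %d-species system\n",
              object@nModes, if (object@nModes == 1L) "" else "s",
              object@nSpecies))
  if (nrow(object@criticalPoints)) {
    cat("  critical points of R(omega^2):\n")
    print(object@criticalPoints, row.names = FALSE)
  } else cat("  R has no positive critical points (flat spectrum)\n")
})

#' Mode-count report as a list (JSON-ready)
#' @param object a \linkS4class{ModeCount}
#' @return list with fields \code{n_species}, \code{n_modes},
#'   \code{critical_points}, \code{coefficients}, \code{method}
#' @export
modeReport <- function(object) {
  stopifnot(is(object, "ModeCount"))
  cp <- object@criticalPoints
  list(n_species = object@nSpecies,
       n_modes = object@nModes,
       critical_points = lapply(seq_len(nrow(cp)), function(i)
         list(x = cp$x[i], omega = cp$omega[i], kind = cp$kind[i])),
       coefficients = object@rpoly@coeffs,
       method = object@method)
}

#' Closed-form resonance condition for a three-species system
#'
#' For \eqn{R(x) = x^3 + a_1 x^2 + a_2 x + a_3} the critical points solve
#' \eqn{R'(x) = 3x^2 + 2a_1 x + a_2 = 0}.  A resonance exists exactly when
#' the Sturm chain of \eqn{R'} shows a sign-change difference of one or two
#' between 0 and \eqn{\infty}: since \eqn{R(0) = \det(J)^2 \ge 0} and
#' \eqn{R \to +\infty}, a maximum exists iff a minimum exists beyond it,
#' so one positive critical point already implies a minimum.
#'
#' @param a1,a2 coefficients of \eqn{x^2} and \eqn{x} in R
#' @return \code{"resonance"} or \code{"no_resonance"}
#' @examples
#' n3ResonanceCondition(0, 1)    # no positive critical point
#' n3ResonanceCondition(-3, 1)   # resonance
#' @export
n3ResonanceCondition <- function(a1, a2) {
  dR <- Poly(c(3, 2 * a1, a2))
  if (polyDegree(dR) < 1L) return("no_resonance")
  ch <- sturmChain(dR)
  diffSigma <- signChangesAt(ch, "zero") - signChangesAt(ch, "inf")
  if (diffSigma %in% c(1L, 2L)) "resonance" else "no_resonance"
}

## Weakly connected components of the digraph of J (indices list).
.weakComponents <- function(J, zeroTol = 1e-12) {
  n <- nrow(J)
  s <- max(abs(J))
  A <- (abs(J) > zeroTol * max(s, .Machine$double.xmin)) |
       t(abs(J) > zeroTol * max(s, .Machine$double.xmin))
  diag(A) <- TRUE
  seen <- logical(n)
  comps <- list()
  for (v in seq_len(n)) {
    if (seen[v]) next
    q <- v; seen[v] <- TRUE; comp <- integer(0L)
    while (length(q)) {
      u <- q[1L]; q <- q[-1L]
      comp <- c(comp, u)
      nb <- which(A[u, ] & !seen)
      seen[nb] <- TRUE
      q <- c(q, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}
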