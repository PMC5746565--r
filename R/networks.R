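## Cyclic index helper: wrap i into 1..n.
cyc <- function(i, n) ((i - 1L) %% n) + 1L

#' Construct a cyclic autocatalytic network
#'
#' @param n integer number of species, at least 2
#' @param r positive replication (autocatalysis) rate
#' @param alpha positive migration-in rate
#' @param beta positive migration-out rate
#' @return an \linkS4class{AutocatalyticNetwork}
#' @examples
#' net <- autocatalyticNetwork(3, r = 1, alpha = 0.1, beta = 0.1)
#' steadyState(net)
#' @export
autocatalyticNetwork <- function(n, r, alpha, beta) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n != round(n))
    stop("'n' must be a single integer")
  new("AutocatalyticNetwork", n = as.integer(n), r = as.numeric(r),
      alpha = as.numeric(alpha), beta = as.numeric(beta))
}

#' Wrap a user-supplied Jacobian
#'
#' @param jacobian square numeric matrix; the Jacobian of a dynamical
#'   system evaluated at a steady state
#' @param label optional free-text label
#' @param warnUnstable warn when some eigenvalue has nonnegative real part
#'   (the method assumes a stable steady state)
#' @return a \linkS4class{JacobianSystem}
#' @export
jacobianSystem <- function(jacobian, label = "", warnUnstable = TRUE) {
  jacobian <- as.matrix(jacobian)
  storage.mode(jacobian) <- "double"
  obj <- new("JacobianSystem", jacobian = jacobian,
             label = as.character(label))
  if (warnUnstable && !isStable(jacobian))
    warning("Jacobian has an eigenvalue with nonnegative real part; ",
            "the steady state is not stable and resonant-mode analysis ",
            "assumes stability")
  obj
}

#' Read a Jacobian matrix from a text file
#'
#' Accepts a whitespace- or comma-separated square numeric matrix with no
#' header.
#' @param file path to the matrix file
#' @param label optional label (defaults to the file name)
#' @return a \linkS4class{JacobianSystem}
#' @export
readJacobian <- function(file, label = basename(file)) {
  if (!file.exists(file)) stop("matrix file not found: ", file)
  ln <- readLines(file, warn = FALSE)
  ln <- ln[nzchar(trimws(ln))]
  rows <- lapply(ln, function(l) {
    v <- strsplit(trimws(l), "[,[:space:]]+")[[1L]]
    suppressWarnings(as.numeric(v))
  })
  len <- unique(vapply(rows, length, integer(1L)))
  if (length(len) != 1L || any(vapply(rows, anyNA, logical(1L))))
    stop("malformed matrix file: need equal-length numeric rows")
  J <- do.call(rbind, rows)
  if (nrow(J) != ncol(J)) stop("matrix file is not square")
  jacobianSystem(J, label = label)
}

#' Spectral stability of a matrix
#' @param J square numeric matrix
#' @param tol eigenvalues with real part below \code{-tol} count as stable
#' @return TRUE when every eigenvalue has negative real part
#' @export
isStable <- function(J, tol = 0) {
  max(Re(eigen(J, only.values = TRUE)$values)) < -tol
}

#' Deterministic right-hand side of the autocatalytic rate equations
#'
#' Evaluates \eqn{\dot x_i = \alpha - \beta x_i + r x_i (x_{i-1} - x_{i+1})}
#' (indices cyclic) at a concentration vector.
#' @param spec an \linkS4class{AutocatalyticNetwork}
#' @param state numeric vector of length \code{n}, entries >= 0
#' @return the derivative vector
#' @export
odeRHS <- function(spec, state) {
  stopifnot(is(spec, "AutocatalyticNetwork"))
  n <- spec@n
  if (length(state) != n)
    stop("'state' must have length ", n, ", got ", length(state))
  if (any(state < 0)) stop("'state' entries must be nonnegative")
  xm <- state[cyc(seq_len(n) - 1L, n)]
  xp <- state[cyc(seq_len(n) + 1L, n)]
  spec@alpha - spec@beta * state + spec@r * state * (xm - xp)
}

#' @describeIn steadyState closed form \eqn{x_i^* = \alpha/\beta} for the
#'   uniform family (the cyclic autocatalysis terms cancel at a uniform
#'   state)
#' @export
setMethod("steadyState", "AutocatalyticNetwork", function(x) {
  rep(x@alpha / x@beta, x@n)
})

#' @describeIn jacobianMatrix circulant closed form at the uniform steady
#'   state: diagonal \eqn{-\beta}, sub-diagonal \eqn{+r x^*}, super-diagonal
#'   \eqn{-r x^*} (cyclic); for \code{n = 2} predecessor and successor
#'   coincide and the off-diagonal terms cancel
#' @export
setMethod("jacobianMatrix", "AutocatalyticNetwork", function(x) {
  n <- x@n
  xs <- x@alpha / x@beta
  J <- matrix(0, n, n)
  for (i in seq_len(n)) {
    J[i, i] <- J[i, i] - x@beta
    J[i, cyc(i - 1L, n)] <- J[i, cyc(i - 1L, n)] + x@r * xs
    J[i, cyc(i + 1L, n)] <- J[i, cyc(i + 1L, n)] - x@r * xs
  }
  J
})

#' @describeIn jacobianMatrix the stored matrix
#' @export
setMethod("jacobianMatrix", "JacobianSystem", function(x) x@jacobian)

#' @describeIn jacobianMatrix a plain square matrix passes through
#' @export
setMethod("jacobianMatrix", "matrix", function(x) {
  if (nrow(x) != ncol(x)) stop("matrix must be square")
  x
})

#' @describeIn nSpecies species count of the family
#' @export
setMethod("nSpecies", "AutocatalyticNetwork", function(x) x@n)

#' @describeIn nSpecies matrix dimension
#' @export
setMethod("nSpecies", "JacobianSystem", function(x) nrow(x@jacobian))

#' @describeIn nSpecies matrix dimension
#' @export
setMethod("nSpecies", "matrix", function(x) nrow(x))

#' Squared Jacobian
#'
#' Resonant modes depend on the network only through \eqn{J^2}: the
#' spectrum denominator is \eqn{\det(J^2 + \omega^2 I)}.
#' @param x a system or square matrix
#' @return the matrix product \eqn{J \cdot J}
#' @export
squaredJacobian <- function(x) {
  J <- jacobianMatrix(x)
  J %*% J
}

#' Random stable linear system (test fixture generator)
#'
#' Draws a dense Gaussian matrix and shifts its diagonal so that the
#' spectral abscissa is strictly negative; reproducible by seed.
#' @param n matrix dimension, >= 2
#' @param seed integer seed
#' @param margin positive shift applied beyond the spectral abscissa
#' @return a \linkS4class{JacobianSystem}
#' @export
randomStableSystem <- function(n, seed, margin = 0.5) {
  stopifnot(n >= 2)
  set.seed(seed)
  A <- matrix(stats::rnorm(n * n), n, n)
  shift <- max(Re(eigen(A, only.values = TRUE)$values))
  A <- A - (shift + margin) * diag(n)
  jacobianSystem(A, label = sprintf("random stable system (seed %d)", seed))
}

setMethod("show", "AutocatalyticNetwork", function(object) {
  cat(sprintf(
    "AutocatalyticNetwork: n = %d species, r = %g, alpha = %g, beta = %g\n",
    object@n, object@r, object@alpha, object@beta))
  cat(sprintf("  uniform steady state x* = %g\n",
              object@alpha / object@beta))
})

setMethod("show", "JacobianSystem", function(object) {
  n <- nrow(object@jacobian)
  cat(sprintf("JacobianSystem: %d x %d%s\n", n, n,
              if (nzchar(object@label))
                paste0(" (", object@label, ")") else ""))
  cat(sprintf("  spectral abscissa: %.6g\n",
              max(Re(eigen(object@jacobian, only.values = TRUE)$values))))
})
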