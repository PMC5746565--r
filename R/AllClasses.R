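#' @import methods
NULL

#' Cyclic autocatalytic network family
#'
#' Parameters of the uniform-rate cyclic autocatalytic reaction scheme on
#' \code{n} species: each species catalyses its successor
#' (\eqn{X_i + X_{i+1} \to 2X_{i+1}} at rate \code{r}, indices cyclic), and
#' every species migrates in at rate \code{alpha} and out at rate
#' \code{beta}.  The deterministic rate equations are
#' \deqn{\dot x_i = \alpha - \beta x_i + r x_i (x_{i-1} - x_{i+1}),}
#' with a single steady state \eqn{x^* = \alpha/\beta} that is linearly
#' stable for all positive parameters.  For \code{n = 3} this is the
#' Rock--Paper--Scissors game.
#'
#' @slot n integer, number of species (>= 2)
#' @slot r positive replication (autocatalysis) rate
#' @slot alpha positive migration-in rate
#' @slot beta positive migration-out rate
#' @seealso [autocatalyticNetwork()], [steadyState()], [jacobianMatrix()]
#' @export
setClass("AutocatalyticNetwork",
         representation(n = "integer", r = "numeric",
                        alpha = "numeric", beta = "numeric"))

setValidity("AutocatalyticNetwork", function(object) {
  msg <- character()
  if (length(object@n) != 1L || is.na(object@n) || object@n < 2L)
    msg <- c(msg, "'n' must be a single integer >= 2")
  for (s in c("r", "alpha", "beta")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive number", s))
  }
  if (length(msg)) msg else TRUE
})

#' Generic dynamical system given by its Jacobian
#'
#' Wraps a user-supplied square Jacobian matrix evaluated at a stable
#' steady state.  Resonant-mode analysis only needs this matrix (through
#' its square \eqn{J^2}), so any system describable by a linear Langevin
#' equation \eqn{\dot{\mathbf x} = J \mathbf x + \boldsymbol\eta} can enter
#' the pipeline here.  Stability (all eigenvalues with negative real part)
#' is a precondition of the method; the constructor warns, but does not
#' fail, when it is violated.
#'
#' @slot jacobian square numeric matrix
#' @slot label free-text description
#' @seealso [jacobianSystem()], [readJacobian()], [countResonantModes()]
#' @export
setClass("JacobianSystem",
         representation(jacobian = "matrix", label = "character"))

setValidity("JacobianSystem", function(object) {
  J <- object@jacobian
  if (!is.numeric(J) || nrow(J) != ncol(J))
    return("'jacobian' must be a square numeric matrix")
  if (any(!is.finite(J)))
    return("'jacobian' must have finite entries")
  TRUE
})

#' Univariate real polynomial
#'
#' Coefficients are stored in descending powers of the variable \code{x};
#' throughout the package \code{x} stands for the squared angular frequency
#' \eqn{\omega^2}, so that the spectrum denominator
#' \eqn{R(\omega^2) = \det(J^2 + \omega^2 I)} is a \linkS4class{Poly} of
#' degree \code{n}.
#'
#' @slot coeffs numeric coefficients, descending powers, nonzero leading
#'   coefficient (unless the polynomial is identically zero)
#' @seealso [Poly()], [rPolynomial()], [sturmChain()]
#' @export
setClass("Poly", representation(coeffs = "numeric"))

setValidity("Poly", function(object) {
  cf <- object@coeffs
  if (length(cf) < 1L) return("'coeffs' must be non-empty")
  if (any(!is.finite(cf))) return("'coeffs' must be finite")
  if (length(cf) > 1L && cf[1L] == 0)
    return("leading coefficient must be nonzero (trim before construction)")
  TRUE
})

#' Sturm chain of a polynomial
#'
#' The sequence \eqn{p_0 = p}, \eqn{p_1 = p'},
#' \eqn{p_{i+1} = -\mathrm{rem}(p_{i-1}, p_i)}, terminating at the zero
#' remainder.  The difference in the number of sign changes of the chain
#' evaluated at two points \eqn{a < b} equals the number of distinct real
#' roots of \eqn{p} in \eqn{(a, b]}.  Chains over integer coefficients are
#' computed fraction-free (exactly); floating input uses a relative zero
#' tolerance, since tiny Sturm coefficients are the known numerical failure
#' mode of the method.
#'
#' @slot polys list of \linkS4class{Poly}, strictly decreasing degree
#' @slot exact logical, whether the chain was computed in exact integer
#'   arithmetic
#' @seealso [sturmChain()], [signChangesAt()], [countPositiveRoots()]
#' @export
setClass("SturmChain", representation(polys = "list", exact = "logical"))

setValidity("SturmChain", function(object) {
  if (!length(object@polys)) return("empty chain")
  if (!all(vapply(object@polys, is, logical(1L), "Poly")))
    return("'polys' must be a list of Poly objects")
  d <- vapply(object@polys, function(p) length(p@coeffs) - 1L, integer(1L))
  if (length(d) > 1L && any(diff(d) >= 0L))
    return("chain degrees must be strictly decreasing")
  TRUE
})

#' Resonant-mode count of a system
#'
#' Result of the exact Sturm-chain analysis of the spectrum denominator
#' \eqn{R(\omega^2) = \det(J^2 + \omega^2 I)}: every distinct positive
#' critical point of \eqn{R} is isolated and classified, and each local
#' minimum at \eqn{x = \omega_R^2} is a resonant mode with resonant
#' frequency \eqn{\omega_R = \sqrt{x}}.  An \eqn{n}-species system has at
#' most \code{floor(n/2)} modes.
#'
#' @slot nModes integer, number of minima of R on the positive axis
#' @slot criticalPoints data.frame with columns \code{x}, \code{omega},
#'   \code{kind} (\code{"minimum"}, \code{"maximum"} or
#'   \code{"inflection"})
#' @slot rpoly the \linkS4class{Poly} R used
#' @slot nSpecies integer, dimension of the Jacobian
#' @slot method character, \code{"sturm"}
#' @slot components per-component results when the graph of J is
#'   disconnected (empty list otherwise)
#' @seealso [countResonantModes()], [nModes()], [resonantFrequencies()]
#' @export
setClass("ModeCount",
         representation(nModes = "integer", criticalPoints = "data.frame",
                        rpoly = "Poly", nSpecies = "integer",
                        method = "character", components = "list"))

setValidity("ModeCount", function(object) {
  cp <- object@criticalPoints
  need <- c("x", "omega", "kind")
  if (!all(need %in% names(cp)))
    return("criticalPoints needs columns x, omega, kind")
  if (nrow(cp) && any(cp$x <= 0))
    return("critical points must be strictly positive")
  if (object@nModes != sum(cp$kind == "minimum"))
    return("nModes must equal the number of minima")
  if (object@nModes > object@nSpecies %/% 2L)
    return("nModes exceeds floor(n/2)")
  TRUE
})

#' Weighted digraph of a square matrix
#'
#' The directed graph whose adjacency matrix is \code{M} (in practice the
#' squared Jacobian \eqn{J^2}): there is an edge \eqn{i \to j} whenever
#' \eqn{M_{ji} \neq 0} (note the index order), with weight \eqn{M_{ji}};
#' self-loops are drawn whenever a diagonal entry is nonzero, the sign
#' living in the weight.  Directed simple cycles of this graph and their
#' disjoint unions (factors) reconstruct the coefficients of
#' \eqn{\det(xI + M)}.
#'
#' @slot n integer, number of vertices
#' @slot weights numeric matrix; \code{weights[i, j]} is the weight of the
#'   edge \eqn{i \to j}, 0 when absent
#' @slot matrix the original matrix M
#' @seealso [interactionGraph()], [enumerateCycles()], [enumerateFactors()]
#' @export
setClass("InteractionGraph",
         representation(n = "integer", weights = "matrix", matrix = "matrix"))

setValidity("InteractionGraph", function(object) {
  if (object@n < 1L) return("need at least one vertex")
  if (!all(dim(object@weights) == object@n))
    return("'weights' must be n x n")
  TRUE
})

#' Phase diagram of resonant-mode counts
#'
#' Integer mode counts on a two-dimensional parameter grid for the cyclic
#' autocatalytic family, on the \eqn{\alpha = \beta} slice by default.
#' Rows index \code{alpha}, columns index \code{r}.  The eigenvalue-pair
#' approximation is evaluated alongside for comparison.
#'
#' @slot modes integer matrix of Sturm mode counts (alpha x r)
#' @slot eigenModes integer matrix of eigenvalue-criterion counts
#' @slot alpha numeric vector of migration-in rates (row coordinates)
#' @slot r numeric vector of replication rates (column coordinates)
#' @slot beta numeric vector of migration-out rates (equal to \code{alpha}
#'   on the default slice)
#' @slot n integer, species count
#' @slot unstable logical matrix flagging grid points with an unstable
#'   steady state (none occur for this family)
#' @seealso [scanPhaseDiagram()], [connectedRegions()], [compareMethods()]
#' @export
setClass("PhaseDiagram",
         representation(modes = "matrix", eigenModes = "matrix",
                        alpha = "numeric", r = "numeric", beta = "numeric",
                        n = "integer", unstable = "matrix"))

setValidity("PhaseDiagram", function(object) {
  if (!all(dim(object@modes) == c(length(object@alpha), length(object@r))))
    return("'modes' must be length(alpha) x length(r)")
  if (any(object@modes < 0L) || any(object@modes > object@n %/% 2L))
    return("mode counts must lie in [0, floor(n/2)]")
  TRUE
})

#' Ensemble of Langevin trajectories
#'
#' Euler--Maruyama sample paths of the linear Langevin equation
#' \eqn{\dot{\mathbf x} = J\mathbf x + \boldsymbol\eta} about a stable
#' steady state, stored as a time x species x repetition array at the
#' recorded sampling interval.
#'
#' @slot times recorded time points
#' @slot states array (time x species x repetitions)
#' @slot dtSample spacing of recorded samples
#' @slot transientFraction initial fraction to discard in spectral
#'   estimates
#' @slot seed integer seed used
#' @seealso [simulateLangevin()], [averagedSpectrum()]
#' @export
setClass("LangevinTrajectories",
         representation(times = "numeric", states = "array",
                        dtSample = "numeric", transientFraction = "numeric",
                        seed = "integer"))

#' Power-spectrum estimate
#'
#' Per-species power on an angular-frequency grid, either a
#' repetition-averaged periodogram of simulated trajectories or the
#' analytic spectrum from the resolvent of \eqn{J}.  When
#' \code{normalized}, each species' spectrum has unit area under the
#' trapezoid rule on its grid.
#'
#' @slot omega angular-frequency grid (increasing, > 0)
#' @slot power matrix (frequency x species), nonnegative
#' @slot nReps number of repetitions averaged (0 for analytic curves)
#' @slot normalized logical, unit-area flag
#' @seealso [averagedSpectrum()], [analyticSpectrum()], [detectPeaks()]
#' @export
setClass("SpectrumEstimate",
         representation(omega = "numeric", power = "matrix",
                        nReps = "integer", normalized = "logical"))

setValidity("SpectrumEstimate", function(object) {
  if (length(object@omega) != nrow(object@power))
    return("'power' must have one row per frequency")
  if (any(object@power < 0)) return("power must be nonnegative")
  if (is.unsorted(object@omega, strictly = TRUE))
    return("'omega' must be strictly increasing")
  TRUE
})
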