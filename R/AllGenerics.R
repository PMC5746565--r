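#' Number of species (matrix dimension) of a system
#' @param x an \linkS4class{AutocatalyticNetwork},
#'   \linkS4class{JacobianSystem} or square matrix
#' @return integer
#' @export
setGeneric("nSpecies", function(x) standardGeneric("nSpecies"))

#' Jacobian of a system at its steady state
#'
#' For the autocatalytic family this is the closed-form circulant Jacobian
#' evaluated at the uniform steady state \eqn{x^* = \alpha/\beta}; for a
#' generic system it is the stored matrix.
#' @param x an \linkS4class{AutocatalyticNetwork} or
#'   \linkS4class{JacobianSystem}
#' @return square numeric matrix
#' @examples
#' jacobianMatrix(autocatalyticNetwork(3, r = 1, alpha = 0.1, beta = 0.1))
#' @export
setGeneric("jacobianMatrix", function(x) standardGeneric("jacobianMatrix"))

#' Steady state of a network
#' @param x an \linkS4class{AutocatalyticNetwork}
#' @return numeric vector of steady-state concentrations (all equal to
#'   \eqn{\alpha/\beta} for the uniform family)
#' @export
setGeneric("steadyState", function(x) standardGeneric("steadyState"))

#' Count resonant modes from the squared Jacobian
#'
#' The central operation: forms \eqn{R(x) = \det(xI + J^2)} (with
#' \eqn{x = \omega^2}), counts the distinct positive roots of \eqn{R'} with
#' a Sturm chain, isolates each by Sturm-guided bisection, classifies it as
#' a minimum, maximum or inflection of \eqn{R}, and reports the minima as
#' resonant modes with frequencies \eqn{\omega_R = \sqrt{x}}.
#'
#' @param x a square matrix (the Jacobian), a
#'   \linkS4class{JacobianSystem} or an \linkS4class{AutocatalyticNetwork}
#' @param ... passed on; see the matrix method for \code{tol} and
#'   \code{refineTol}
#' @return a \linkS4class{ModeCount}
#' @examples
#' countResonantModes(matrix(c(-1, -2, 2, -1), 2))       # one mode at sqrt(3)
#' countResonantModes(autocatalyticNetwork(5, 4, 0.01, 0.01))  # two modes
#' @export
setGeneric("countResonantModes",
           function(x, ...) standardGeneric("countResonantModes"))

#' Mode count accessor
#' @param object a \linkS4class{ModeCount} or \linkS4class{PhaseDiagram}
#' @return integer (matrix of integers for a phase diagram)
#' @export
setGeneric("nModes", function(object) standardGeneric("nModes"))

#' Critical points of the spectrum denominator
#' @param object a \linkS4class{ModeCount}
#' @return data.frame with columns \code{x}, \code{omega}, \code{kind}
#' @export
setGeneric("criticalPoints",
           function(object) standardGeneric("criticalPoints"))

#' Resonant frequencies of a mode count
#' @param object a \linkS4class{ModeCount}
#' @return numeric vector of \eqn{\omega_R} values (one per minimum)
#' @export
setGeneric("resonantFrequencies",
           function(object) standardGeneric("resonantFrequencies"))
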