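#' Sweep a parameter grid and count resonant modes
#'
#' For each grid point of the autocatalytic family, builds the closed-form
#' Jacobian at the steady state and runs the Sturm-chain mode count, plus
#' the complex-eigenvalue-pair approximation for comparison.  The default
#' window is the \eqn{\alpha = \beta} slice, \eqn{\alpha} log-spaced over
#' \eqn{[10^{-3}, 1]} and \eqn{r} log-spaced over \eqn{[0.1, 10]}, which
#' contains the worked parameter points (0.1, 1) and (0.01, 4).
#'
#' @param n species count of the family
#' @param alphaRange length-2 positive range of the migration-in rate
#' @param rRange length-2 positive range of the replication rate
#' @param steps length-2 integer vector (alpha steps, r steps), each >= 2;
#'   a single value is recycled
#' @param scale \code{"log"} (default) or \code{"linear"} grid spacing
#' @param beta optional fixed migration-out rate; by default the sweep runs
#'   on the \eqn{\alpha = \beta} slice
#' @return a \linkS4class{PhaseDiagram}
#' @examples
#' pd <- scanPhaseDiagram(3, steps = c(12, 12))
#' connectedRegions(pd)$nRegions   # 2: oscillatory and flat
#' @export
scanPhaseDiagram <- function(n, alphaRange = c(1e-3, 1),
                             rRange = c(0.1, 10), steps = c(60L, 60L),
                             scale = c("log", "linear"), beta = NULL) {
  scale <- match.arg(scale)
  steps <- as.integer(rep_len(steps, 2L))
  if (any(steps < 1L)) stop("'steps' must be >= 1 in each direction")
  if (any(c(alphaRange, rRange) <= 0))
    stop("rate-parameter ranges must be positive")
  gridOf <- function(rng, k) {
    if (k == 1L) return(rng[1L])    # degenerate single-point axis
    if (scale == "log") exp(seq(log(rng[1L]), log(rng[2L]), length.out = k))
    else seq(rng[1L], rng[2L], length.out = k)
  }
  alpha <- gridOf(alphaRange, steps[1L])
  r <- gridOf(rRange, steps[2L])
  betaVec <- if (is.null(beta)) alpha else rep(beta, length(alpha))
  modes <- eig <- matrix(0L, steps[1L], steps[2L])
  unstable <- matrix(FALSE, steps[1L], steps[2L])
  for (i in seq_len(steps[1L])) {
    for (j in seq_len(steps[2L])) {
      J <- jacobianMatrix(autocatalyticNetwork(n, r[j], alpha[i],
                                               betaVec[i]))
      if (!isStable(J)) unstable[i, j] <- TRUE
      modes[i, j] <- nModes(countResonantModes(J))
      eig[i, j] <- eigenvalueModePrediction(J)
    }
  }
  new("PhaseDiagram", modes = modes, eigenModes = eig, alpha = alpha,
      r = r, beta = betaVec, n = as.integer(n), unstable = unstable)
}

#' @describeIn nModes matrix of Sturm mode counts over the grid
#' @export
setMethod("nModes", "PhaseDiagram", function(object) object@modes)

setMethod("show", "PhaseDiagram", function(object) {
  cat(sprintf("PhaseDiagram: n = %d, %d x %d grid (alpha x r)\n",
              object@n, nrow(object@modes), ncol(object@modes)))
  cat("  mode counts present:",
      paste(sort(unique(as.vector(object@modes))), collapse = ", "), "\n")
  if (any(object@unstable))
    cat("  ", sum(object@unstable), "grid points flagged unstable\n")
})

#' Connected equal-count regions of a phase diagram
#'
#' Labels the grid by flood fill with 4-neighbour (edge-adjacent)
#' connectivity over cells carrying the same mode count, the conservative
#' connectivity choice.  Cells flagged unstable are excluded from the
#' labelling (they receive label \code{NA}); none occur for the
#' autocatalytic family, which is stable everywhere.
#'
#' @param pd a \linkS4class{PhaseDiagram}
#' @return list with \code{nRegions}, the integer \code{labels} matrix, and
#'   a \code{regions} data.frame (label, mode count, number of cells, index
#'   bounding box)
#' @export
connectedRegions <- function(pd) {
  stopifnot(is(pd, "PhaseDiagram"))
  M <- pd@modes
  n1 <- nrow(M); n2 <- ncol(M)
  lab <- matrix(NA_integer_, n1, n2)
  skip <- pd@unstable
  k <- 0L
  for (s1 in seq_len(n1)) for (s2 in seq_len(n2)) {
    if (skip[s1, s2] || !is.na(lab[s1, s2])) next
    k <- k + 1L
    queue <- matrix(c(s1, s2), ncol = 2L)
    lab[s1, s2] <- k
    while (nrow(queue)) {
      cur <- queue[nrow(queue), ]
      queue <- queue[-nrow(queue), , drop = FALSE]
      for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
        p1 <- cur[1L] + d[1L]; p2 <- cur[2L] + d[2L]
        if (p1 < 1L || p1 > n1 || p2 < 1L || p2 > n2) next
        if (skip[p1, p2] || !is.na(lab[p1, p2])) next
        if (M[p1, p2] != M[cur[1L], cur[2L]]) next
        lab[p1, p2] <- k
        queue <- rbind(queue, c(p1, p2))
      }
    }
  }
  regions <- do.call(rbind, lapply(seq_len(k), function(lb) {
    idx <- which(lab == lb, arr.ind = TRUE)
    data.frame(region = lb, modes = M[idx[1L, 1L], idx[1L, 2L]],
               cells = nrow(idx),
               rowMin = min(idx[, 1L]), rowMax = max(idx[, 1L]),
               colMin = min(idx[, 2L]), colMax = max(idx[, 2L]))
  }))
  list(nRegions = k, labels = lab, regions = regions)
}

#' Eigenvalue-pair approximation of the mode count
#'
#' The approximation predicts one resonance for every complex-conjugate
#' eigenvalue pair \eqn{\lambda, \bar\lambda} of \eqn{J} with
#' \eqn{\Im(\lambda)^2 - \Re(\lambda)^2 > 0}.  It is fast but can produce
#' false positives relative to the exact Sturm count, because it inspects
#' one quadratic factor of the characteristic polynomial of \eqn{J^2} at a
#' time while the other factors can wash a shallow minimum out.
#'
#' @param J square matrix, \linkS4class{JacobianSystem} or
#'   \linkS4class{AutocatalyticNetwork}
#' @param tol imaginary parts below \code{tol} count as real
#' @return integer number of qualifying conjugate pairs
#' @examples
#' eigenvalueModePrediction(matrix(c(-1, -2, 2, -1), 2))   # 1
#' eigenvalueModePrediction(matrix(c(-2, -1, 1, -2), 2))   # 0
#' @export
eigenvalueModePrediction <- function(J, tol = 1e-9) {
  J <- jacobianMatrix(J)
  ev <- eigen(J, only.values = TRUE)$values
  ## each conjugate pair contributes exactly one eigenvalue with Im > tol
  sum(Im(ev) > tol & Im(ev)^2 > Re(ev)^2)
}

#' Compare the Sturm count with the eigenvalue approximation on a grid
#'
#' Returns the per-cell comparison in long format together with summary
#' counts.  On the autocatalytic family the eigenvalue criterion
#' over-predicts: every cell where the Sturm method finds a mode also
#' satisfies the eigenvalue criterion, while the converse fails in a band
#' near the region boundary (the false positives).
#'
#' @param pd a \linkS4class{PhaseDiagram} (stores both counts)
#' @return data.frame with columns \code{alpha}, \code{beta}, \code{r},
#'   \code{sturm}, \code{eigen}, \code{agree}; summary counts in attribute
#'   \code{"summary"} (\code{nCells}, \code{nAgree},
#'   \code{eigenOverSturm}, \code{sturmOverEigen},
#'   \code{sturmPositiveEigenZero})
#' @export
compareMethods <- function(pd) {
  stopifnot(is(pd, "PhaseDiagram"))
  grid <- expand.grid(i = seq_along(pd@alpha), j = seq_along(pd@r))
  out <- data.frame(alpha = pd@alpha[grid$i], beta = pd@beta[grid$i],
                    r = pd@r[grid$j],
                    sturm = pd@modes[cbind(grid$i, grid$j)],
                    eigen = pd@eigenModes[cbind(grid$i, grid$j)])
  out$agree <- out$sturm == out$eigen
  attr(out, "summary") <- list(
    nCells = nrow(out),
    nAgree = sum(out$agree),
    eigenOverSturm = sum(out$eigen > out$sturm),
    sturmOverEigen = sum(out$sturm > out$eigen),
    sturmPositiveEigenZero = sum(out$sturm >= 1L & out$eigen == 0L))
  out
}

#' Phase diagram in long format
#' @param pd a \linkS4class{PhaseDiagram}
#' @param labels optional precomputed [connectedRegions()] result
#' @return data.frame with columns \code{alpha}, \code{beta}, \code{r},
#'   \code{n_modes}, \code{eigen_modes}, \code{region_id}
#' @export
phaseDiagramTable <- function(pd, labels = NULL) {
  stopifnot(is(pd, "PhaseDiagram"))
  if (is.null(labels)) labels <- connectedRegions(pd)
  grid <- expand.grid(i = seq_along(pd@alpha), j = seq_along(pd@r))
  data.frame(alpha = pd@alpha[grid$i], beta = pd@beta[grid$i],
             r = pd@r[grid$j],
             n_modes = pd@modes[cbind(grid$i, grid$j)],
             eigen_modes = pd@eigenModes[cbind(grid$i, grid$j)],
             region_id = labels$labels[cbind(grid$i, grid$j)])
}
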