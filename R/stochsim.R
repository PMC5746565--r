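#' Euler--Maruyama integration of the linear Langevin equation
#'
#' Simulates fluctuations about a stable steady state,
#' \eqn{x_{t+\mathrm{d}t} = x_t + J x_t \,\mathrm{d}t + L\sqrt{\mathrm{d}t}\,\xi_t}
#' with \eqn{\xi_t} standard normal and \eqn{L} a symmetric square root of
#' the noise covariance \eqn{B}.  By default \eqn{B = I/\Omega}, the
#' identity scaled by the system size: the number and location of resonant
#' modes is generically independent of the noise covariances, so the
#' uninformative default suffices for validating peak structure; a
#' user-supplied \eqn{B} is accepted for fidelity to a specific reaction
#' scheme.
#'
#' All repetitions are advanced simultaneously (the state is an
#' n x nReps matrix), and only every \code{recordEvery}-th step is stored,
#' so a stiff oscillatory system can be integrated at a small \code{dt}
#' while the recorded sampling interval stays compatible with spectral
#' estimation.
#'
#' @param J square matrix, \linkS4class{JacobianSystem} or
#'   \linkS4class{AutocatalyticNetwork}; a warning is issued when unstable
#' @param B noise covariance matrix (symmetric positive semidefinite);
#'   default \code{diag(n)/omegaSystem}
#' @param omegaSystem system size \eqn{\Omega} scaling the default noise
#' @param dt integration time step; a warning is issued when
#'   \eqn{|1 + \mathrm{d}t\,\lambda| \ge 1} for some eigenvalue (the
#'   explicit scheme then amplifies that mode)
#' @param tEnd total simulated time
#' @param nReps number of independent repetitions
#' @param seed integer seed (reproducibility contract)
#' @param recordEvery store every k-th step (recorded spacing
#'   \code{k * dt})
#' @param transientFraction initial fraction flagged for discarding by
#'   [averagedSpectrum()]
#' @param x0 initial fluctuation vector (default 0)
#' @return a \linkS4class{LangevinTrajectories}
#' @examples
#' J <- matrix(c(-1, -2, 2, -1), 2)
#' tr <- simulateLangevin(J, nReps = 3, tEnd = 50, seed = 1)
#' dim(tr@states)
#' @export
simulateLangevin <- function(J, B = NULL, omegaSystem = 1, dt = 0.01,
                             tEnd = 200, nReps = 1L, seed = 1L,
                             recordEvery = 1L, transientFraction = 0.1,
                             x0 = NULL) {
  J <- jacobianMatrix(J)
  n <- nrow(J)
  stopifnot(dt > 0, tEnd > dt, nReps >= 1L, recordEvery >= 1L)
  if (!isStable(J))
    warning("Jacobian is not stable; trajectories will not be stationary")
  ev <- eigen(J, only.values = TRUE)$values
  if (max(abs(1 + dt * ev)) >= 1)
    warning(sprintf(
      "dt = %g is too large for explicit Euler-Maruyama on this system ",
      dt), "(|1 + dt*lambda| >= 1); reduce dt (use recordEvery to keep ",
      "the recorded spacing)")
  if (is.null(B)) B <- diag(n) / omegaSystem
  B <- as.matrix(B)
  if (!isTRUE(all.equal(B, t(B), tolerance = 1e-8)))
    stop("noise covariance B must be symmetric")
  eB <- eigen((B + t(B)) / 2, symmetric = TRUE)
  if (min(eB$values) < -1e-12 * max(abs(eB$values), 1))
    stop("noise covariance B must be positive semidefinite")
  L <- eB$vectors %*% (sqrt(pmax(eB$values, 0)) * t(eB$vectors))
  noiseFree <- all(B == 0)

  nSteps <- ceiling(tEnd / dt)
  nRec <- nSteps %/% recordEvery
  set.seed(as.integer(seed))
  x <- if (is.null(x0)) matrix(0, n, nReps)
       else matrix(rep(as.numeric(x0), nReps), n, nReps)
  states <- array(0, dim = c(nRec, n, nReps))
  sdt <- sqrt(dt)
  rec <- 0L
  for (step in seq_len(nSteps)) {
    x <- x + (J %*% x) * dt
    if (!noiseFree)
      x <- x + sdt * (L %*% matrix(stats::rnorm(n * nReps), n, nReps))
    if (step %% recordEvery == 0L) {
      rec <- rec + 1L
      states[rec, , ] <- x
    }
  }
  new("LangevinTrajectories",
      times = (seq_len(nRec)) * dt * recordEvery,
      states = states, dtSample = dt * recordEvery,
      transientFraction = transientFraction, seed = as.integer(seed))
}

setMethod("show", "LangevinTrajectories", function(object) {
  d <- dim(object@states)
  cat(sprintf(
    "LangevinTrajectories: %d samples x %d species x %d repetitions\n",
    d[1L], d[2L], d[3L]))
  cat(sprintf("  sampling interval %g, t in (0, %g]\n",
              object@dtSample, max(object@times)))
})

#' Repetition-averaged unit-area power spectrum
#'
#' Discards the transient fraction, computes the per-species periodogram of
#' every repetition on the recorded samples, averages across repetitions,
#' and (by default) normalizes each species' spectrum to unit area under
#' the trapezoid rule.  Frequencies are angular
#' (\eqn{\omega = 2\pi j / T}); the zero-frequency bin is dropped.
#'
#' @param traj a \linkS4class{LangevinTrajectories}
#' @param normalize unit-area normalization flag
#' @return a \linkS4class{SpectrumEstimate}
#' @export
averagedSpectrum <- function(traj, normalize = TRUE) {
  stopifnot(is(traj, "LangevinTrajectories"))
  d <- dim(traj@states)
  drop <- floor(d[1L] * traj@transientFraction)
  keep <- (drop + 1L):d[1L]
  N <- length(keep)
  if (N < 2L) stop("need at least 2 post-transient samples")
  nFreq <- N %/% 2L
  omega <- 2 * pi * seq_len(nFreq) / (N * traj@dtSample)
  power <- matrix(0, nFreq, d[2L])
  for (rep in seq_len(d[3L])) {
    for (sp in seq_len(d[2L])) {
      ft <- stats::fft(traj@states[keep, sp, rep])
      power[, sp] <- power[, sp] + Mod(ft[2L:(nFreq + 1L)])^2
    }
  }
  power <- power * traj@dtSample / (2 * pi * N * d[3L])
  spec <- new("SpectrumEstimate", omega = omega, power = power,
              nReps = as.integer(d[3L]), normalized = FALSE)
  if (normalize) spec <- normalizeSpectrum(spec)
  spec
}

#' Normalize a spectrum to unit area
#' @param spec a \linkS4class{SpectrumEstimate}
#' @return the spectrum with each species' trapezoid integral scaled to 1
#' @export
normalizeSpectrum <- function(spec) {
  stopifnot(is(spec, "SpectrumEstimate"))
  area <- apply(spec@power, 2L, function(p) .trapz(spec@omega, p))
  if (any(area <= 0)) stop("cannot normalize a zero spectrum")
  new("SpectrumEstimate", omega = spec@omega,
      power = sweep(spec@power, 2L, area, "/"),
      nReps = spec@nReps, normalized = TRUE)
}

.trapz <- function(x, y) sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)

#' Analytic power spectrum from the resolvent
#'
#' For the linear Langevin equation the spectrum of species \eqn{k} is
#' \deqn{P_k(\omega) = \frac{Q_k(\omega^2)}{R(\omega^2)}
#'   = \left[(-i\omega I - J)^{-1} B (-i\omega I - J)^{-\dagger}\right]_{kk},}
#' with common denominator
#' \eqn{R(\omega^2) = |\det(-i\omega I - J)|^2 = \det(J^2 + \omega^2 I)}.
#' Implemented by complex linear solves per frequency rather than symbolic
#' adjugates, which stays exact in structure for any \eqn{n}.
#'
#' @param J square matrix, \linkS4class{JacobianSystem} or
#'   \linkS4class{AutocatalyticNetwork} (must be stable)
#' @param omega angular-frequency grid, strictly increasing and positive
#' @param B noise covariance (default \code{diag(n)/omegaSystem})
#' @param omegaSystem system size scaling the default noise
#' @param normalize unit-area normalization flag
#' @return a \linkS4class{SpectrumEstimate} with \code{nReps = 0}
#' @examples
#' analyticSpectrum(matrix(-2, 1, 1), omega = c(0.5, 1, 2))@power  # Lorentzian b/(a^2+w^2)
#' @export
analyticSpectrum <- function(J, omega, B = NULL, omegaSystem = 1,
                             normalize = FALSE) {
  J <- jacobianMatrix(J)
  n <- nrow(J)
  if (!isStable(J)) stop("analytic spectrum requires a stable Jacobian")
  if (is.null(B)) B <- diag(n) / omegaSystem
  B <- as.matrix(B)
  power <- matrix(0, length(omega), n)
  In <- diag(n)
  for (i in seq_along(omega)) {
    M <- -1i * omega[i] * In - J
    S <- solve(M)
    power[i, ] <- pmax(Re(diag(S %*% B %*% Conj(t(S)))), 0)
  }
  spec <- new("SpectrumEstimate", omega = omega, power = power,
              nReps = 0L, normalized = FALSE)
  if (normalize) spec <- normalizeSpectrum(spec)
  spec
}

setMethod("show", "SpectrumEstimate", function(object) {
  cat(sprintf(
    "SpectrumEstimate: %d frequencies x %d species (%s%s)\n",
    length(object@omega), ncol(object@power),
    if (object@nReps > 0L) sprintf("average of %d repetitions",
                                   object@nReps) else "analytic",
    if (object@normalized) ", unit area" else ""))
})

#' Detect spectral peaks
#'
#' Interior local maxima whose topographic prominence (height above the
#' deepest saddle separating the peak from higher terrain) exceeds a
#' threshold relative to the spectrum median, the practical criterion for
#' separating resonance peaks from the noise floor of an averaged
#' periodogram.  Simulation-averaged spectra are smoothed with a short
#' moving average first (bin noise of a periodogram averaged over \eqn{m}
#' repetitions is \eqn{1/\sqrt{m}} of the level, so raw 3-point maxima are
#' meaningless); analytic spectra are left untouched.
#'
#' @param spec a \linkS4class{SpectrumEstimate}
#' @param species which species' spectrum to scan (peak structure is a
#'   network property, so any species shows the same peaks generically)
#' @param prominence multiple of the median power the peak prominence must
#'   exceed
#' @param relFloor fraction of the maximum power the prominence must also
#'   exceed; the median alone is a poor yardstick for steep spectra, whose
#'   far tail pulls it orders of magnitude below the resonant structure
#' @param smooth odd moving-average window in bins; default 9 for
#'   simulation estimates (\code{nReps > 0}), 1 (none) for analytic curves
#' @return numeric vector of peak angular frequencies (possibly empty)
#' @export
detectPeaks <- function(spec, species = 1L, prominence = 3,
                        relFloor = 0.01, smooth = NULL) {
  stopifnot(is(spec, "SpectrumEstimate"))
  p <- spec@power[, species]
  if (is.null(smooth)) smooth <- if (spec@nReps > 0L) 9L else 1L
  smooth <- as.integer(smooth)
  if (smooth > 1L) {
    if (smooth %% 2L == 0L) smooth <- smooth + 1L
    k <- rep(1 / smooth, smooth)
    p <- as.numeric(stats::filter(p, k, sides = 2L))
    half <- smooth %/% 2L
    n <- length(p)
    p[seq_len(half)] <- p[half + 1L]            # pad the filter edges
    p[(n - half + 1L):n] <- p[n - half]
  }
  n <- length(p)
  if (n < 3L) return(numeric(0L))
  i <- which(p[2L:(n - 1L)] > p[1L:(n - 2L)] &
             p[2L:(n - 1L)] >= p[3L:n]) + 1L
  if (!length(i)) return(numeric(0L))
  thr <- max(prominence * stats::median(p), relFloor * max(p))
  keep <- vapply(i, function(j) {
    ## saddle on each side: minimum until higher terrain (or the edge)
    lseg <- p[seq_len(j - 1L)]
    higherL <- which(lseg > p[j])
    sadL <- min(lseg[seq.int(if (length(higherL)) max(higherL) else 1L,
                             j - 1L)])
    rseg <- p[seq.int(j + 1L, n)]
    higherR <- which(rseg > p[j])
    sadR <- min(rseg[seq_len(if (length(higherR)) min(higherR)
                             else length(rseg))])
    (p[j] - max(sadL, sadR)) > thr
  }, logical(1L))
  spec@omega[i[keep]]
}
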