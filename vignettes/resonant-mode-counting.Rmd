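---
title: "Counting resonant modes of stochastic interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting resonant modes of stochastic interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quasimodes)
```

## The problem

A deterministic reaction system with a stable fixed point can still
oscillate when molecule numbers are finite: intrinsic (demographic) noise
is resonantly amplified at particular frequencies, producing sustained
noisy cycles ("quasi-cycles") even though the deterministic model shows no
Hopf bifurcation.  Near a stable steady state the fluctuations obey a
linear Langevin equation

$$\dot{\mathbf{x}} = J\mathbf{x} + \boldsymbol{\eta}, \qquad
\langle \eta_i(t)\,\eta_j(t')\rangle = B_{ij}\,\delta(t - t'),$$

where $J$ is the Jacobian at the fixed point.  The power spectrum of every
species is a rational function with the *common* denominator

$$R(\omega^2) = \det\!\left(J^2 + \omega^2 I\right),$$

which is the characteristic polynomial of $J^2$ under
$\omega^2 = -\lambda$.  A *resonant mode* is an angular frequency
$\omega_R$ at which $R$ attains a local minimum: there the spectra of all
species peak simultaneously (generically — the species-specific numerators
$Q_k$ can in principle suppress a peak, which this package, like the
approximation it implements, does not model).  Two consequences shape the
whole design:

* resonance is a property of the *network* ($J^2$), not of individual
  species, and
* the noise covariance $B$ does not enter the location or number of
  modes, so the tedious derivation of $B$ from a master equation can be
  skipped entirely.

`quasimodes` determines the number of modes **exactly**: the minima of $R$
on $(0, \infty)$ are counted by applying Sturm's theorem to $R'$, not
estimated from eigenvalue heuristics or from scanning spectra.

## Exact root counting

Descartes' rule of signs bounds the number of positive roots of $R'$ by
the sign changes of its coefficients (`descartesBound()`); the bound is
attained up to an even difference.  The exact count comes from the Sturm
chain

$$p_0 = R', \quad p_1 = R'', \quad p_{i+1} = -\mathrm{rem}(p_{i-1}, p_i),$$

terminating at the zero remainder (`sturmChain()`).  If $\sigma(a)$ counts
the sign changes of the chain evaluated at $a$, then
$\sigma(a) - \sigma(b)$ is the number of distinct real roots in $(a, b]$;
with $a = 0$, $b = \infty$ it counts all distinct positive roots
(`countPositiveRoots()`).  Each root is then isolated by Sturm-count
bisection, refined, and classified as a minimum, maximum or inflection of
$R$ from the sign of $R'$ on either side; the minima are the modes and
$\omega_R = \sqrt{x}$ (`countResonantModes()`).

Numerical choices, all of which matter in practice:

* **Arithmetic.**  Integer-coefficient polynomials are processed
  *fraction-free*: pseudo-remainders with positive scaling and integer
  content removal give a chain whose members are positive integer
  multiples of the canonical ones, so every sign count is exact.  No
  arbitrary-precision library is available in this environment, so
  exactness is bounded by double-precision integers: coefficients are
  guarded against $2^{50}$ and the chain falls back to floating arithmetic
  on overflow.  Floating chains normalize each member to unit maximum
  coefficient and treat coefficients below a relative $10^{-12}$ as zero —
  small Sturm coefficients are the known failure mode of the method.
* **Scaling.**  Before isolation the variable is rescaled $x = s\,y$ with
  $s = |a_m/a_0|^{1/m}$ (the geometric mean of the root magnitudes), so
  the critical points are $O(1)$.  Without this, systems whose resonances
  sit at $x \sim 10^{-2}$ or $10^{2}$ lose several digits in the chain and
  can be misclassified.
* **Classification.**  Roots are classified from the sign of $R'$ at
  *separator points* halfway between consecutive roots (and at half the
  smallest root, and one unit past the largest), never at points just
  outside the refined interval: separators are far from every root, so the
  sign evaluation is unconditionally stable.  Sturm counts distinct roots,
  so a double root of $R'$ (a degenerate saddle of $R$) appears once, is
  classified "inflection", excluded from the mode count, and triggers a
  warning.
* **Boundary roots.**  $R(0) = \det(J)^2 \ge 0$; a root of $R'$ exactly at
  zero is deflated and reported separately rather than counted.
* Since $R \to +\infty$ and $R(0) \ge 0$, minima and maxima alternate and
  the largest critical point is a minimum; this invariant is checked on
  every result.

For three-species systems `n3ResonanceCondition(a1, a2)` evaluates the
closed-form condition on the coefficients of
$R = x^3 + a_1 x^2 + a_2 x + a_3$: a resonance exists exactly when the
Sturm chain of $R' = 3x^2 + 2a_1 x + a_2$ shows a sign-change difference
of one or two between $0$ and $\infty$ (one positive critical point
already implies a minimum, because a maximum can only occur below a
minimum).

## Coefficients from the graph of $J^2$

$J^2$ is read as the adjacency matrix of a weighted digraph: an edge
$i \to j$ whenever $(J^2)_{ji} \neq 0$, with that entry as its weight, and
a self-loop wherever a diagonal entry is nonzero (the sign lives in the
weight; squared Jacobians rarely have sign-definite diagonals).  A *cycle*
is a directed simple cycle; its weight is the product of its edge weights;
a *factor* of degree $k$ is a set of pairwise vertex-disjoint cycles
covering exactly $k$ vertices, with cardinality $|f_k|$ equal to its
number of cycles.  The coefficient of $x^{n-k}$ in $\det(xI + A)$ is

$$a_k = \sum_{f_k} (-1)^{k - |f_k|} \prod_{c \in f_k} A[c],$$

so that $a_1 = \operatorname{Tr} A$ and $a_n = \det A$.  The sign
convention is pinned by a mandatory test against direct determinant
expansion, not by transcription.  This route exposes *which* interaction
motifs drive each coefficient — often only one or two coefficients can
change sign, and those decide the phase boundaries.

Cycle enumeration is depth-first with the smallest vertex as anchor
(canonical form: a cycle starts at its minimum vertex and preserves
direction, so $\{1,2,3\}$ and $\{1,3,2\}$ are distinct); factor
enumeration recurses over the cycle list in fixed order.  Squared
Jacobians are generically dense, so both enumerations face combinatorial
growth: factor finding is the practical bottleneck, and the intended range
is $n \lesssim 8$.

## The worked model family

The package ships the cyclic autocatalytic family used for all worked
examples: $n$ species where each catalyses its successor,
$X_i + X_{i+1} \to 2X_{i+1}$ at rate $r$ (indices cyclic), plus migration
in and out of the system at rates $\alpha$ and $\beta$.  The rate
equations are

$$\dot x_i = \alpha - \beta x_i + r\,x_i\,(x_{i-1} - x_{i+1}),$$

with the single steady state $x_i^* = \alpha/\beta$ (the autocatalytic
terms cancel at any uniform state).  The Jacobian there is circulant —
diagonal $-\beta$, sub-diagonal $+r x^*$, super-diagonal $-r x^*$ — with
eigenvalues $-\beta + 2 i r x^* \sin(2\pi k/n)$, so the steady state is
stable for *all* positive parameters and the deterministic model never
oscillates persistently; every sustained oscillation in this family is
noise-induced.  For $n = 3$ this is the Rock–Paper–Scissors game; $n = 2$
degenerates (predecessor and successor coincide) to uncoupled relaxation.

```{r worked}
countResonantModes(autocatalyticNetwork(3, r = 1, alpha = 0.1, beta = 0.1))
countResonantModes(autocatalyticNetwork(5, r = 4, alpha = 0.01, beta = 0.01))
```

## Phase diagrams and the eigenvalue approximation

`scanPhaseDiagram()` sweeps the $\alpha = \beta$ slice (the slice on which
$x^* = 1$, so the two axes are damping and interaction strength) and
stores the exact mode count per cell; `connectedRegions()` labels
equal-count regions by 4-neighbour flood fill, the conservative
connectivity.  The default window, $\alpha \in [10^{-3}, 1]$ and
$r \in [10^{-1}, 10]$ both log-spaced, was chosen once to contain the two
worked parameter points $(0.1, 1)$ and $(0.01, 4)$ with generous margin;
the plotted ranges of the original figures are not recorded, so region
counts are always accompanied by a refinement check (the count must be
unchanged when the resolution doubles — a thin one-mode band exists for
$n = 5$ that very coarse grids can fragment).

The classical shortcut (`eigenvalueModePrediction()`) predicts one
resonance per complex-conjugate eigenvalue pair of $J$ with
$\Im(\lambda)^2 > \Re(\lambda)^2$.  It inspects one quadratic factor of
$R$ at a time, so other factors can wash out a shallow minimum: it
over-predicts near phase boundaries.  `compareMethods()` quantifies this
on a grid; on the five-species window the eigenvalue criterion fires in a
visible band of cells where the exact count is smaller, while the reverse
(an exact mode the criterion misses) does not occur on this family.

## Simulation validation

`simulateLangevin()` integrates the Langevin equation with Euler–Maruyama,
all repetitions advanced simultaneously; `averagedSpectrum()` averages
per-repetition periodograms (after discarding a 10% transient) and
normalizes each species' spectrum to unit area; `analyticSpectrum()`
evaluates $P_k(\omega)$ by complex linear solves of
$(-i\omega I - J)$ per frequency, never symbolic adjugates.

Choices a user should know about:

* **Noise covariance.**  $B$ is *not* part of the mode prediction and its
  derivation is exactly what this method avoids, so the default is the
  uninformative $B = I/\Omega$ with $\Omega$ the system size.  Peak
  *locations* are the validated quantity; peak *shapes* depend on the true
  $B$ of a concrete reaction scheme, which can be supplied.  The simulated
  spectra therefore validate peak count and position, not curve shape.
* **Step size.**  Explicit Euler–Maruyama requires
  $|1 + \Delta t\,\lambda| < 1$ for every eigenvalue; a warning is issued
  otherwise.  The five-species two-resonance system ($\omega_R \approx
  7.6$, damping $0.01$) is stiff in this sense: the spectral defaults
  ($\Delta t = 0.01$) would amplify the resonance exponentially.  The
  validation runs use $\Delta t = 2\times10^{-4}$ with `recordEvery = 50`,
  which keeps the recorded spacing (and hence the frequency grid) at
  $0.01$ while restoring stability.  Aliasing from the unrecorded steps
  folds white noise onto a flat background and does not move peaks.
* **Peak detection.**  A periodogram averaged over $m$ repetitions has
  relative bin noise $1/\sqrt{m}$, so raw three-point maxima are
  meaningless.  `detectPeaks()` smooths simulation estimates with a short
  moving average (9 bins by default; analytic curves are untouched) and
  keeps local maxima whose *topographic prominence* exceeds both 3 times
  the median power and 1% of the maximum.  The median-only rule of thumb
  fails for steep spectra — the far tail pulls the median orders of
  magnitude below the resonant structure — which is why the relative
  floor exists.  On the worked systems genuine peaks carry prominence
  five orders of magnitude above the noise wiggles, so the result is
  insensitive to these thresholds.

What a green simulation test establishes: that the Sturm count and the
$\sqrt{x_{\min}}$ frequencies agree with the peaks of both the analytic
resolvent spectrum and the simulated averaged periodogram to within two
frequency bins.  What it does not establish: agreement with the spectral
*amplitudes* of any particular chemical scheme (that needs the true $B$),
or behaviour of the nonlinear model far from the steady state (the
simulation is of the linearized equation).

## Generic systems, preconditions, degenerate inputs

Any square Jacobian can be supplied directly (`jacobianSystem()`,
`readJacobian()`), bypassing the model family.  Stability is a
precondition of the theory; violations warn rather than fail, since the
analysis of $R$ is still well defined.  If the graph of $J$ is
disconnected the components are independent subsystems and each diagonal
block is analysed separately (`countResonantModes()` returns per-component
results and their total); the minima of a product of independent
denominators are not the union of the factors' minima, so the blocks must
not be analysed jointly.  The zero polynomial, constant derivatives
($n = 1$) and roots at the origin are handled explicitly rather than by
convention.

## Limitations

* Factor enumeration grows combinatorially; beyond $n \approx 8$ the
  graph route is impractical (the determinant route in `rPolynomial()`
  remains available).
* Exactness of the Sturm pipeline is limited to integer data within
  double-precision integer range; floating input relies on the
  $10^{-12}$ relative zero tolerance and the root rescaling described
  above.
* Mode suppression by the numerators $Q_k(\omega^2)$ is assumed absent
  (the generic case); a species whose numerator cancels a resonance will
  still be reported as resonant.
* The simulation module validates the linearized dynamics only.
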