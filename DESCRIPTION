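Package: quasimodes
Title: Exact Counting of Resonant Modes in Stochastic Interaction Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Counts the resonant modes (quasi-cycle frequencies) of a
    stochastic interaction network exactly from the squared Jacobian of its
    stable steady state. The denominator of every species' power spectrum is
    the single polynomial R(w^2) = det(J^2 + w^2 I); local minima of R mark
    resonant frequencies, and their number is obtained by Sturm-chain real
    root counting of R', with Descartes' rule as an upper bound. Coefficients
    of R are also assembled graph-theoretically from the directed cycles and
    disjoint-cycle factors of the digraph of J^2. Includes the cyclic
    autocatalytic reaction family (Rock-Paper-Scissors for three species) as
    a worked model, parameter-space phase diagrams with connected-region
    labelling, the complex-eigenvalue-pair approximation for comparison, and
    Euler-Maruyama simulation of the linear Langevin equation with averaged
    unit-area power spectra for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
biocViews: NetworkInference, GraphAndNetwork, MathematicalBiology
RoxygenNote: 7.3.3
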