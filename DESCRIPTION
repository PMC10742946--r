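Package: infotherm
Title: Information Recoverability and Entropy Production of Noisy Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the nonequilibrium thermodynamics of discrete noisy
    channels. Builds canonical (Boltzmann) channels from receiver potential
    landscapes, computes the recoverability of source messages together with
    its exact decomposition into mutual information and error information,
    and verifies the equivalence of recoverability with the entropy
    production of sequential information transfer. Includes the
    equilibrium/nonequilibrium strength decomposition of channel columns
    with closed-form information surfaces for two-source channels,
    continuous-time receiver relaxation under local detailed balance with
    Metropolis or Glauber rates, trajectory-level estimators of
    recoverability and entropy production from simulated message sequences,
    and CSV/JSON input and output for channels, priors and potentials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
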