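Package: kinetrans
Title: Translating Effective Receptor-Ligand Kinetic Constants Between 2D and 3D Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-step mass-action framework for receptor-ligand (TCR-pMHC)
    binding kinetics: translational diffusion/encounter, rotational orientation,
    and chemical binding, in two and three dimensions. Provides the full
    five-species deterministic model and its exact stochastic counterpart, the
    four effective reductions used by experimental assays (pre-binding models A
    and B, the FRET meta-state model, and the single-step model), closed-form
    mappings between fundamental and effective rate constants with numerically
    verified quasi-steady-state reductions, synthetic generators for thermal
    fluctuation, adhesion frequency, surface plasmon resonance and FRET
    readouts, and the inference layer that fits effective constants, translates
    them back to fundamental ones, and predicts potency trend lines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
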