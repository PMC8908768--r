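Package: dftbfq
Title: Self-Consistent-Charge Tight Binding Coupled to Fluctuating-Charge
    Embedding, with Linear-Response Absorption Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale implementation of a polarizable QM/MM scheme in
    which a self-consistent-charge density-functional tight-binding (SCC-DFTB)
    ground state is mutually polarized with a classical fluctuating-charge
    (FQ) environment, and extended to linear response (Casida formalism) for
    computing absorption spectra of solvated chromophores from ensembles of
    snapshot geometries. Includes readers for multi-frame XYZ geometries and
    Slater-Koster parameter tables, a constrained charge-equilibration solver,
    Mulliken transition charges and oscillator strengths, intensity selection
    of the single-orbital transition basis, Gaussian stick-spectrum
    convolution, ensemble averaging with confidence-interval convergence
    diagnostics, and deterministic toy-fixture generators so the full pipeline
    runs without external parameter sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
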