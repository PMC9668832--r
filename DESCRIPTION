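Package: relaxmf
Title: Model-Free Analysis of 15N Spin Relaxation and NMR Ligand-Binding
    Analytics for Homodimeric Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for interpreting backbone amide 15N spin relaxation of
    homodimeric proteins and for NMR-based ligand-binding analytics.
    Extracts R1, R2 and heteronuclear NOE rates with uncertainties from
    peak-intensity decay series, performs reduced spectral density mapping
    at two magnetic fields with a per-residue J(0) consistency ratio that
    flags microsecond-millisecond chemical exchange, and fits the fully
    anisotropic Lipari-Szabo model-free model under a C2 dimer symmetry
    constraint (global diffusion tensor D1, D2, D3, gamma plus per-residue
    S2, internal correlation time and Rex) with AICc model selection and
    Monte-Carlo errors. Ligand analytics cover chemical shift
    perturbations, the 7PA fragment-screening statistic with hit triage,
    and dissociation-constant fitting from HSQC titrations with per-amide
    aggregation. Includes structure utilities (amide N-H vectors, C2-axis
    alignment, B-factor value maps) and a fully seeded synthetic-data
    generator so every stage is testable without experimental spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    bio3d,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
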