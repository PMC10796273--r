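Package: qbetr
Title: Electron-Transfer Kinetics and Quantum-Tunnelling Analysis for
    Redox-Functionalized Nanoparticles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative evidence chain behind electrically
    triggered biological electron tunnelling at redox-functionalized gold
    nanoparticles ("bio-nanoantennae"). Simulates quasi-reversible cyclic
    voltammograms by explicit finite differences and extracts heterogeneous
    electron-transfer rate constants via the Nicholson peak-separation method
    with the Lavagnini/Klingler-Kochi working function; converts normalized
    metabolic-activity measurements into donor charging rates through an
    exponential cell-survival model and fits the exponential distance decay
    expected for tunnelling through a barrier; computes the classical
    electron-hop feasibility bound; and analyzes optical difference spectra
    for quantized dips, plasmon-resonance peak positions and Soret-band
    redox-state calls. A seeded synthetic-data generator emulates all three
    instrument outputs so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
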