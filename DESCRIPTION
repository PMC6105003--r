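Package: abcalcium
Title: Whole-Cell Calcium Dynamics Under Amyloid-Beta
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a whole-cell model of intracellular calcium under
    the influence of amyloid-beta: six-state IP3-receptor gating,
    ryanodine-receptor calcium-induced calcium release, SERCA and plasma
    membrane pumps, an amyloid-beta membrane pore leak, dynamic IP3
    production, and an optional Hodgkin-Huxley-style membrane compartment
    with inward-rectifier potassium and T-type calcium currents. Provides
    steady-state continuation with Hopf and fold detection, periodic-orbit
    location by Poincare shooting with Floquet multipliers and
    period-doubling localisation, and an operational classifier of
    calcium traces into steady, periodic, mixed-mode and aberrant signal
    classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
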