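Package: cowflow
Title: Reduced-Order Cerebral Hemodynamics with ASL-Calibrated Windkessel Outflows
Version: 0.1.0
Authors@R: person("COW", "Flow Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools for quantifying patient-specific cerebral hemodynamics with a
    reduced-order (0D) pulsatile model of the aorta, neck arteries and Circle of
    Willis. Windkessel outflow boundary conditions are calibrated in three stages
    from arterial-spin-labeling (ASL) perfusion splits, phase-contrast MRI flow
    waveforms and brachial pressure. The calibrated model is interrogated for
    fractional blood supply to the vascular territories (deterministic junction
    mixing and stochastic particle routing), trans-stenotic pressure drop,
    fractional flow index and distal outlet resistance. A synthetic-cohort
    generator produces complete studies (NIfTI ASL volumes, waveform CSVs,
    network JSON) with known ground truth so the whole pipeline is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
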