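Package: ctpcea
Title: Cost-Effectiveness of Stress CT Perfusion Versus Coronary CT
    Angiography in Stented Patients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision-analytic model comparing stress myocardial CT
    perfusion (CTP), coronary CT angiography (CTA) and their combination
    for suspected obstructive coronary artery disease or in-stent
    restenosis in patients with previous stent implantation. Implements a
    diagnostic decision tree feeding a three-state annual-cycle Markov
    cohort model with discounting, cost-effectiveness metrics (net
    monetary benefit, ICER, dominance, efficiency frontier), one-way
    deterministic sensitivity analysis (tornado) and probabilistic
    sensitivity analysis (Monte Carlo, CEAC), together with a
    patient-level microsimulation oracle and a synthetic
    diagnostic-accuracy study generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
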