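Package: stenosim
Title: Coupled Heart-Valve-Arterial Simulation of Stenotic Aortic Valve
    Hemodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A one-dimensional pulse-wave model of the systemic arterial
    tree coupled to a time-varying elastance left ventricle and a dynamic
    stenotic aortic valve. The valve imposes a transvalvular pressure
    gradient made of an inertial term and a turbulent (Bernoulli) loss,
    with opening and closure driven by the instantaneous gradient.
    Terminal branches end in three-element Windkessel elements whose
    aggregate resistance and compliance are calibrated to target total
    vascular resistance and total arterial compliance. The package
    reproduces in-silico sensitivity experiments quantifying the
    independent effects of end-systolic elastance, end-diastolic
    elastance, total vascular resistance and total arterial compliance on
    the mean transaortic pressure gradient across aortic-valve-area
    levels, including ordinary-least-squares effect summaries, stroke
    volume versus gradient curves and blood-pressure maps. A synthetic
    arterial-tree generator provides physiologically plausible geometries
    so every component is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
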