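Package: afsilico
Title: In Silico Atrial Drug Trials for Multi-Target Antiarrhythmic Compounds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating multi-target antiarrhythmic compounds that
    block TASK-1 (I_K2P), Kv1.5 (I_Kur) and Nav1.5 (I_Na). Implements a
    polypharmacology ranking of docking poses across channels (contact
    counting, min-max score normalization, per-channel and global rank sums),
    dose-response analysis (Hill IC50, four-parameter logistic viability,
    Boltzmann conductance-voltage fits, percent inhibition and hemolysis),
    a Courtemanche-Ramirez-Nattel human atrial cardiomyocyte model extended
    with a TASK-1 background current, population-of-models generation via
    Latin Hypercube sampling with biomarker calibration, a one-dimensional
    monodomain cable for conduction velocity and effective refractory period
    measurement, and an in silico trial runner applying Hill pore-block drug
    profiles across concentrations and pacing rates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    lhs,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
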