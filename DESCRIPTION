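Package: sdstrip
Title: Automated Detection of Spreading Depolarizations in Full-Band
    Electrocorticography
Version: 0.1.0
Authors@R:
    person("ECoG", "Tools", email = "ecog-tools@example.org", role = c("aut", "cre"))
Description: Detects spreading depolarizations (SD) in full-band (DC-coupled)
    electrocorticography from sparsely sampled (0.1 Hz) single-channel slow
    potentials. Provides moving-median baseline correction, FIR low-pass
    filtering and decimation of raw 256-Hz recordings; extraction of 80
    time- and frequency-domain features from 400-s segments; gradient-boosted
    tree and RBF-kernel support-vector classifiers with leave-one-patient-out
    cross-validation and gain-based feature ranking; sliding-window
    computation of an SD probability time series P_SD(t) with dual
    amplitude/duration threshold event detection; an evaluation protocol that
    matches detections to expert annotations within 400-s windows and reports
    sensitivity, precision, F1, OBJ and false positives per day; and a
    synthetic multichannel ECoG generator with injected SD waveforms and
    ground-truth annotations so the whole pipeline is testable without
    patient data. Recordings are read and written as EDF or HDF5;
    annotations, events and feature tables as CSV; models as JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    rhdf5,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
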