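Package: mitodyn
Title: Quantification of Mitochondrial Dynamics in Parvalbumin Interneurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable, tested implementations of quantification
    procedures for studying Miro1-dependent mitochondrial dynamics in
    parvalbumin-positive interneurons: mitochondrial trafficking kinematics
    from particle tracks (mobility classification, pause-excluding
    velocity, path length), SWC-based neuronal morphometry (branch points,
    processes, compartment lengths, 3D Sholl analysis), mitochondrial
    distribution analysis on voxel stacks (volume masking, MitoSholl,
    branch-point-to-mitochondrion proximity), 2D fluorescence
    quantification (masked intensity, soma mitochondrial area and
    clustering, bouton detection and mitochondrial content, object-level
    synapse colocalization), electrophysiology analysis (gamma-band LFP
    spectral metrics, Gaussian 50 percent width, autocorrelogram,
    spontaneous postsynaptic current detection, train recovery, intrinsic
    membrane properties, fEPSP slope), and behavioral scoring (zone
    occupancy, trajectory kinematics, rotarod RPM, T-maze alternation).
    A seedable synthetic-data module generates every input the pipeline
    consumes together with its ground truth, so all estimators are
    testable without raw microscopy or electrophysiology data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    pracma,
    signal,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
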