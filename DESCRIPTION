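Package: betaConnect
Title: Movement-Related Beta Dynamics, Interhemispheric Coherence and
    Paired-Pulse Inhibition Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing sensorimotor beta-band (14-30 Hz)
    dynamics around voluntary movement from bilateral EEG recordings:
    sliding-window time-frequency power with adaptive three-cycle
    Hanning windows, baseline-relative normalisation, extraction of
    movement-related beta desynchronization (MRBD) and post-movement
    beta synchronization (PMBS) amplitudes and latencies, sectioned
    cross-spectral interhemispheric coherence, multivariate
    autoregressive (MVAR) directed coherence with Levinson-Wiggins-
    Robinson fitting and analytic significance thresholds, and
    motor-evoked-potential based interhemispheric inhibition (IHI)
    ratios from paired-pulse TMS protocols.  A synthetic-data module
    generates bilateral beta epochs, coupled signal pairs, AR-coupled
    processes and MEP trials with known ground truth for validation
    and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'connectivity.R'
    'ersp.R'
    'ihi.R'
    'io.R'
    'mvar.R'
    'preprocess.R'
    'synthgen.R'
    'pipeline.R'
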