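Package: cupball
Title: Predictability, Effort and Smoothness in Rhythmic Manipulation of a
    Cart-Pendulum Object
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the rhythmic "cup of coffee" manipulation
    task, modelled as a cart with a suspended pendulum (a cup containing a
    rolling ball). Provides prescribed-cup inverse dynamics and forward
    simulation of the object, stroboscopic (Poincare) sampling and bifurcation
    scans over the ball's initial angle, and a family of strategy measures:
    kernel-density mutual information between applied force and cup phase, a
    strobed-force predictability index, sensitivity of mutual information to
    execution-variable perturbations, finite-time (global) Lyapunov exponents
    of the driven ball subsystem, mean squared force, mean absolute jerk and
    spectral arc-length smoothness. Includes the full experimental-trial
    pipeline (cycle peak detection, execution-variable estimation, continuous
    strategy measures, result-space map lookups, metronome asynchrony and
    early-versus-late practice comparisons) together with a synthetic-cohort
    generator that emulates practice data so every pipeline stage can be
    exercised without access to human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    signal,
    stats,
    utils
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
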