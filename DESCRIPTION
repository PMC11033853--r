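Package: dbsloop
Title: Model-Based Closed-Loop Control of Thalamic Deep Brain Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and closed-loop control of thalamic (Vim) deep brain
    stimulation for essential tremor. Implements a biophysical pathway model
    from DBS pulse trains through Tsodyks-Markram short-term synaptic
    plasticity, a three-population Vim firing-rate network, a leaky
    integrate-and-fire motor-cortex population, spike-response spinal
    motoneurons and motor-unit action potentials to surface EMG; a fast
    polynomial biomarker mapping the Vim firing rate to estimated EMG; a
    Hann-windowed spectral system output; and a discrete PID controller that
    adjusts the stimulation frequency toward a target EMG power. Includes
    peristimulus-time-histogram validation utilities for external spike-time
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
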