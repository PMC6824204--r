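Package: speechplan
Title: Bayesian Speech Motor Planning with Multisensory Goals and
    Sensory Preference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates phoneme-conditioned planning of tongue motor
    commands as Bayesian inference under auditory (formant) and
    somatosensory (tongue-contour principal component) goal regions.
    Provides a synthetic articulatory plant, radial-basis-function
    sensory-motor internal models with additive adaptation to auditory
    perturbations, Metropolis-Hastings posterior sampling over the
    six-dimensional control space, and two mechanisms of sensory
    preference: multiplicative covariance scaling of the goal regions
    (target-based) and Gaussian softening of the sensory matching
    constraint (comparison-based), together with their closed-form
    equivalence. Includes an experiment pipeline for perturbation and
    adaptation studies of compensation, preference parameter sweeps,
    and dispersion-ellipse summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    rlang,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
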