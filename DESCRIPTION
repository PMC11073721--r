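Package: stroopddm
Title: Drift-Diffusion and Classical Analysis of Numerical Stroop rTMS
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for behavioral experiments in which repetitive
    transcranial magnetic stimulation (rTMS) is delivered during a
    numerical Stroop task.  Provides a two-boundary Wiener diffusion core
    (first-passage densities by adaptive series expansion, absorption
    probabilities, an Euler-Maruyama sampler, and a contaminant-mixture
    likelihood), per-cell maximum-likelihood drift-diffusion fitting with
    EZ-style moment initialization, staged reaction-time cleaning cascades
    with full per-stage accounting, classical reaction-time statistics
    (size congruency effect and its components, rTMS-effect percentage,
    mixed models and repeated-measures ANOVA, numerical-distance and
    backward-selection covariate analyses), and a synthetic-study
    generator with a known generative truth so every stage of the
    pipeline can be validated by parameter and effect recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    lme4,
    lmerTest,
    emmeans
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
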