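Package: dopanet
Title: Vector-Valued Dopamine Feedback Learning in a Basal-Ganglia Rate Network
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates a recurrent rate-network model of the basal ganglia in
    which a vector-valued error, encoded by nigral dopamine neurons and mixed
    by diffuse volume transmission from axonal varicosities, acts as the random
    feedback signal of a three-factor, eligibility-trace-based online learning
    rule (random feedback local online learning). Provides Gaussian-process
    target generation on a periodic kernel, sign-constrained sparse
    connectivity with excitation-inhibition balancing, a spatial dopamine
    diffusion model with controllable length scale and varicosity count,
    feedback-variant and lesion experiments, slow-dopamine filtering with
    high-pass synaptic compensation, and spatial-correlation analyses of
    striatal activity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
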