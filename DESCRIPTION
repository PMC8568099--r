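Package: crxsim
Title: Agent-Based Simulation of Community Resource Referral Information Diffusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale agent-based simulator of how community resource
    information delivered at clinical encounters ("clinical doses") diffuses
    through a synthetic population via co-location ("social doses"). Provides
    a synthetic-world generator (demographically heterogeneous agents,
    geolocated households, workplaces, schools, clinics and resource sites),
    pools of demographically keyed 24-hour activity schedules, per-agent
    capped resource-knowledge stores with source-dependent reinforcement and
    decay, in-silico generation and delivery of personalized resource
    prescriptions, an hourly time-stepped simulation engine with peer
    information exchange and threshold resource-use decisions, emergent
    diffusion-network construction, and reusable experiment pipelines for
    clinical-versus-social dosing reach, delivery-mode comparison and
    information-sharing-propensity sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
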