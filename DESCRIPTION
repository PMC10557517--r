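Package: fireclust
Title: Fireworks-Algorithm-Seeded K-Means for Mental-Health Grading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a hybrid clustering method that seeds K-means with the
    best solution found by the Fireworks Algorithm (FWA), a swarm optimizer in
    which candidate solutions explode into sparks whose number and radius
    depend on fitness. The package applies the hybrid to a mental-health
    evaluation index system for student cohorts: indicators scored on a 0-10
    scale (including a temporal-perception indicator derived from
    duration-estimation error), three-band indicator grading, and a four-grade
    anxiety outcome assigned by matching clusters to grades. Ships a labeled
    synthetic cohort generator, K-means++ and random-init comparators, an
    exhaustive-partition test oracle, Hungarian-matched clustering accuracy,
    a paired benchmark harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
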