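Package: fermxfer
Title: Local Transfer Soft-Sensor Modelling for Fed-Batch Fermentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Soft-sensor modelling of fed-batch fermentation processes
    (Pichia pastoris type) under multi-phase dynamics and batch-to-batch
    heterogeneity.  Historical source batches are partitioned into
    phase-specific sub-source domains by K-means clustering in PCA space,
    a feedforward sigmoid network is trained per domain with its
    hyperparameters chosen by an improved firefly algorithm (stochastic
    perturbation, fitness-proportional crossover with the global best,
    Mantegna Levy flight, greedy selection), the sub-domain closest to a
    new target batch is selected by centroid distance, and its model is
    adapted to the target batch by layer freezing / fine-tuning with a
    maximum-mean-discrepancy alignment term.  Includes a seeded simulator
    of multi-phase fed-batch campaigns so the whole pipeline can be run
    and tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
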