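Package: ctgalert
Title: Event-Based Intrapartum Risk Alerting from Cardiotocography Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for detecting fetuses at risk of acidosis and
    hypoxic-ischemic encephalopathy (HIE) from annotated intrapartum
    cardiotocography. Consumes event-interval annotations of fetal heart
    rate (baseline, acceleration, deceleration) and uterine pressure
    (contraction, resting interval), extracts semi-Markov transition-count
    and dwell-time features over 20-minute epochs anchored at delivery,
    trains a per-tree class-balanced random forest yielding out-of-bag
    epoch risk probabilities, and converts probability streams into
    intervention recommendations through a consecutive-alert rule whose
    run length and threshold are calibrated by AUC maximization under a
    false-positive-rate constraint tied to the Caesarean delivery rate.
    Includes a semi-Markov labor-event simulator so the full pipeline can
    be exercised and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    ggplot2
Config/testthat/edition: 3
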