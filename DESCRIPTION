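Package: cihpheno
Title: Cardiorespiratory and Gut-Microbiome Phenotyping for Chronic
    Intermittent Hypoxia Rodent Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification pipeline for phenotyping cardiorespiratory
    function in rodent models of chronic intermittent hypoxia (CIH).
    Scores whole-body plethysmography flow traces breath by breath
    (tidal volume, timing, minute ventilation with per-100 g
    normalisation), detects sighs and post-sigh/spontaneous apnoeas and
    reports the apnoea index, computes Poincare SD1/SD2 variability,
    extracts beats from arterial pressure waveforms and computes the
    full time- and frequency-domain heart-rate-variability metric
    suite, quantifies ventilatory and cardiovascular responses to gas
    and drug challenges with the study's windowing rules, computes
    metabolic rates from flow-through gas fractions, and summarises
    compositional microbiome count tables (prevalence filtering,
    centred log-ratio transform, alpha diversity, Aitchison PCA,
    pairwise PERMANOVA, CLR-space differential abundance with
    Benjamini-Hochberg FDR, and KEGG-orthologue module aggregation).
    A synthetic-data generator with planted ground truth makes every
    stage verifiable without animal recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
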