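Package: steatoflux
Title: Personalized Constraint-Based Modeling of Liver Metabolism in Hepatic Steatosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for personalized flux-balance analysis of fasting-state liver
    metabolism in cohorts with varying degrees of hepatic steatosis. Derives
    per-subject exchange bounds for a hepatocyte metabolic network from
    anthropometric and clinical variables (adipose fatty-acid and amino-acid
    release, muscle amino-acid release, hepatic autophagy, lactate supply,
    gluconeogenesis and ketone-body output, measured VLDL triglyceride and
    apolipoprotein B secretion), solves each subject's network by linear
    programming with flux-sum minimization or hit-and-run flux sampling, and
    correlates intracellular fluxes with liver-fat content and net fat influx.
    Includes a curated reduced hepatocyte network covering beta-oxidation,
    NNT/glutathione redox cycling, one-carbon metabolism, gluconeogenesis,
    ketogenesis and VLDL assembly; a synthetic-cohort and plasma-metabolome
    generator for testing; and the group-comparison and correlation statistics
    used for plasma metabolomics (Welch tests, detection-threshold pairwise
    correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
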