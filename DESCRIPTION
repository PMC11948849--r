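Package: ryepollen
Title: Population Genomics and Pollen-Trait Analysis for Domestication Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the genetic architecture and selection history of
    pollen and anther morphology in wind-pollinated crops such as rye. Includes a
    two-population Balding-Nichols genotype simulator with planted selective sweeps,
    imaging-flow-cytometry particle gating and trait summarization, VCF genotype and
    site filtering with heterozygosity-based ploidy classification, PCA on a genetic
    covariance matrix, GREML SNP heritability and an iterative fixed/random-effect
    association scan with resampling validation, windowed selection statistics
    (Weir-Cockerham FST, nucleotide diversity, diversity reduction index, XP-CLR),
    PST-FST comparison with bootstrap confidence intervals, and a Stokes-law
    ballistic pollen dispersal model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
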