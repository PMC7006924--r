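Package: coralprot
Title: iTRAQ Quantitative Proteomics and Ecological Statistics for Coral
    Stress Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse isobaric-label (iTRAQ 8-plex) quantitative
    proteomics experiments on non-model organisms such as reef-building
    corals, together with the ecological statistics used alongside them.
    Builds nonredundant protein search databases from transcriptome
    assemblies by six-frame translation, filters peptide-spectrum matches
    on identification confidence, peptide uniqueness, length and summed
    reporter signal-to-noise, quantifies per-protein reporter-channel
    ratios against the mean of duplicate ambient controls, and calls
    differential protein abundance per treatment with Fisher's combined
    probability and fold-change gates. Also implements choice-flume
    preference proportions with Kolmogorov-Smirnov comparison, maximum
    quantum yield of photosystem II (Fv/Fm), balanced two-way ANOVA with
    Tukey HSD, the Scheirer-Ray-Hare nonparametric two-way ANOVA,
    Mann-Whitney tests with Bonferroni correction, and the arcsine
    square-root transform. A seeded synthetic-data generator emulates a
    2-run x 8-plex spike-in design so the full pipeline is testable
    without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
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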