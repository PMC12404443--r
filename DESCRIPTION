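Package: ardscan
Title: Missense-Variant Burial Profiles and Channel-Function Assays for
    Ankyrin Repeat Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joins population missense-variant spectra with per-residue
    solvent accessibility to find buried residues with unexpectedly many
    variant types, as applied to the TRPV1 ankyrin repeat domain. Reads
    gnomAD-style variant exports and PDB/mmCIF structures, computes
    Shrake-Rupley solvent-accessible surface area, ranks residues by
    fractional SASA, smooths variant-type counts along the burial axis and
    scores burial/variability discordance by permutation. Also quantifies
    the matching functional assays: Hill dose-response fitting (EC50),
    single-channel open probability by half-amplitude idealization,
    macroscopic approximate open probability, temperature-current
    relations, and calcium-imaging responder fractions. A synthetic-data
    module generates every input format the pipeline consumes so all
    stages run and are testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    bio3d,
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
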