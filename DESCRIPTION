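Package: d2otrace
Title: Heavy-Water Tracer Analysis of Lipid and Bile Acid Synthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of deuterated-water (2H2O) stable-isotope tracer
    experiments measuring fractional synthesis of hepatic palmitate (de novo
    lipogenesis), cholesterol, and taurine-conjugated bile acids from
    mass-spectrometry isotopologue peak areas. Provides natural-abundance
    isotope mathematics (mass isotopomer distributions, correction matrices,
    non-negative deconvolution), a binomial labeling model with
    exchangeable-hydrogen estimation, body-water enrichment and
    internal-standard calibrations, a synthetic cohort generator with known
    ground truth, and an end-to-end per-sample analysis pipeline emitting tidy
    results.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    pracma,
    stats,
    tibble,
    utils
Suggests:
    dplyr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
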