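Package: transpoly
Title: Footprints of Ancient Balanced Trans-Species Polymorphisms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytic theory and coalescent simulators for the genetic
    footprints left by an ancient biallelic balanced polymorphism shared
    identical by descent between two closely related species. Provides the
    length distribution of the ancestral segment around the selected site,
    expected coalescent times and shared neutral SNP counts from a
    discrete-generation Markov chain, linkage-disequilibrium summaries of
    shared SNPs, a structured-coalescent simulator conditioned on the
    trans-species polymorphism, a neutral recurrent-mutation null model with
    CpG hypermutability, and a scanner that applies the resulting detection
    criteria to two-species variant data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    ape,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
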