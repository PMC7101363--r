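Package: snppanel
Title: SNP Panel Discovery, Targeted-Amplicon Genotyping and Variety
    Fingerprinting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for building DNA fingerprints of crop varieties from
    targeted amplicon sequencing. Discovers "perfect" SNP panels from
    population variant data (biallelic sites with unique, variant- and
    SSR-free flanking sequence and informative allele frequencies), calls
    genotypes from per-allele read depths with depth and allele-ratio rules,
    computes per-locus and per-subpopulation diversity statistics (MAF,
    observed and expected heterozygosity, polymorphic information content,
    Simpson's diversity, inbreeding coefficient), partitions variance by
    AMOVA and estimates pairwise Weir-Cockerham Fst, selects minimal
    discriminating marker sets with saturation curves, identifies core
    (backbone) varieties from differential-genotype kinship, and simulates
    structured populations with amplicon read depths for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
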