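Package: strpop
Title: Population Structure, Marker Informativeness and Mito-Nuclear
    Concordance from Microsatellite Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing diploid multi-allelic short tandem repeat
    (STR) genotypes in two-species hybrid-zone settings: a Gibbs sampler for
    the Bayesian admixture model with Evanno delta-K model choice, factorial
    correspondence analysis of allele dosages, Cavalli-Sforza chord distances
    with neighbor-joining locale trees, Hardy-Weinberg/null-allele/linkage
    locus QC, Shannon-information ranking of loci for geographic-assignment
    panels, quantification of mito-nuclear discordance with an exact
    habitat-by-clade association test, and a synthetic-data generator that
    emulates two diverged gene pools with rare backcross hybrids and
    sex-biased mitochondrial introgression. Readers and writers for the
    STRUCTURE and GenePop text formats are included, plus a config-driven
    pipeline runner with a reproducible manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
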