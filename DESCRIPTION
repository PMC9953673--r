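Package: polyion
Title: Conformational Analysis of Charged Homo-Polypeptide Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing conformational ensembles of polyelectrolytic
    homo-polypeptides (polyD, polyE, polyK, polyR and neutral polyGS controls):
    radius-of-gyration distributions, Flory scaling exponents from internal
    distance profiles, Rg relaxation times from autocorrelation fits, explicit-ion
    adsorption statistics, and principal component analysis of aligned ensembles.
    Includes a coarse-grained bead-spring Metropolis Monte Carlo simulator with
    explicit counterions and added 1:1 or 2:1 salt (harmonic bonds,
    Weeks-Chandler-Andersen excluded volume, truncated minimum-image Coulomb),
    reference conformation generators (rod, space-filling compact chain, freely
    jointed chain, self-avoiding walk), a homorepeat census for proteome FASTA
    files, and multi-model PDB and columnar trajectory input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    minpack.lm,
    yaml,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
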