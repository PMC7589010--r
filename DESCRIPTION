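Package: gagchain
Title: Conformational Ensembles of Glycosaminoglycan Polymers from
    Conformer Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds three-dimensional, heavy-atom conformational ensembles of
    nonsulfated glycosaminoglycan (GAG) polymers of arbitrary length
    (hyaluronan and nonsulfated dermatan, keratan, and heparan) by
    independently sampling monosaccharide-ring and glycosidic-linkage
    conformations from a conformer database. Databases can be extracted from
    multi-model PDB ensembles or generated synthetically from free-energy
    basin and ring-pucker specifications. Constructed chains are relaxed by
    restrained energy minimization and screened with a bond potential energy
    cutoff that rejects nonphysical geometries (overlapping bonds, bonds
    piercing rings). Includes Cremer-Pople ring puckering analysis,
    glycosidic phi/psi free-energy maps on 2.5 degree bins, and end-to-end
    distance and radius-of-gyration statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
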