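Package: clonedyn
Title: Stochastic Multiclonal Dynamics of the Naive T Cell Repertoire
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exact event-driven (Gillespie) simulation of a multiclonal naive
    T cell repertoire in which clonotypes compete for division stimuli from
    subsets of self peptide-MHC presented on a random bipartite recognition
    network, together with the closed-form theory of repertoire homeostasis:
    stationary total cell numbers, the thymic-to-peripheral production ratio,
    mean clonal lifetimes from a diffusion approximation of clone size, and
    clonotype-number estimates for mice and humans.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
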