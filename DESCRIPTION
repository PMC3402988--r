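Package: cgrmatch
Title: Chaos Game Representation Indexes for Exact and Approximate DNA
    String Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Encodes DNA sequences as Chaos Game Representation (CGR)
    coordinate indexes, both in the classical unit-square formulation
    (contraction ratio 1/2) and in a Cantor-set embedding (contraction
    ratio 2/3) whose base-3 digit structure makes coordinate proximity
    equivalent to suffix sharing.  On top of constant-time longest
    common extension queries the package implements exact and
    k-mismatch pattern matching, maximal complemented-palindrome and
    tandem-repeat detection, longest common substring by quadrant-order
    sorting, a quadtree (CGR-tree) sequence index, and a CGR-derived
    rolling hash for Rabin-Karp search.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
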