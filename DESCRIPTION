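Package: satayfit
Title: Fitness Estimation from Saturated Transposon Insertion Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the fitness effect of gene disruptions from
    SATAY-style transposon insertion sequencing read counts. Corrects the
    pericentromeric insertion bias of the MiniDS transposon with a cubic fit
    of the cumulative insertion curve, imputes unobserved (zero-read)
    insertion sites from the bias-corrected expected insertion count, and
    estimates per-gene fitness as the mean read count per insertion site with
    negative-binomial uncertainty shared across genes. Includes positional
    read-count diagnostics, replicate concordance statistics, hypergeometric
    sequencing-saturation analysis, and a forward simulator of transposon
    libraries with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), optparse, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
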