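Package: pathmdf
Title: Bioenergetic Trade-Off Analysis of Microbial CO2-Fixation Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify the trade-off between chemiosmotic ATP yield and
    thermodynamic driving force in prokaryotic carbon-fixation pathways. A
    pathway variant (a concrete electron-carrier assignment closed by carrier
    regeneration against hydrogen) is optimized in two stages: first the net
    number of chemiosmotic proton translocations is maximized, then, trading a
    chosen number of translocations, the max-min driving force (MDF) over all
    elementary reactions is maximized over metabolite log-concentrations. The
    integer program is solved by an exact branch-and-bound over a dense
    two-phase simplex. Includes encoded fixtures for six natural and six
    postulated CO2-fixation pathways, electron-carrier reduction-potential
    range analysis via solution-pool enumeration, environmental condition
    scans, and a synthetic-pathway generator with closed-form oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
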