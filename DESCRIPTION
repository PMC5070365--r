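Package: ruralaccess
Title: Car and Public-Transport Accessibility of Physician Practices in
    Rural Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring the accessibility of general practitioners
    and specialist physicians in sparsely populated rural regions, by car and
    by timetable-based public transport. Includes a seeded synthetic-region
    generator (population districts, a routable street network, physician
    practices with a buffer ring, GTFS timetables), street-network routing
    with origin-destination cost matrices and service-area time bands,
    multimodal round-trip journey search on a time-expanded transit graph
    under walking-distance caps and appointment time windows,
    population-weighted zone tabulation, Kruskal-Wallis group comparison with
    a rank-based Tukey-type post hoc, and Thiessen-polygon map layers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
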