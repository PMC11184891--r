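Package: rwdsandbox
Title: Modular Sandbox for Privacy-Preserving Distributed Analytics on Hospital Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A multi-agent platform for distributed analytics inside a hospital
    trust zone: external researchers submit analysis jobs through a polled XML
    message protocol, jobs travel as self-describing zip tokens executed by
    black-box processor modules, and every request and result is notarised in a
    hash-chained append-only ledger and covered by a dual digital-signature
    workflow. Includes identity and access management with ticketed sessions
    and group hierarchies, a periodic-task scheduler, a load-balancing proxy,
    and synthetic datamart fixtures (including a minimal OMOP-style subset) so
    the whole pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    R6,
    jsonlite,
    openssl,
    processx,
    xml2,
    yaml,
    zip,
    stats,
    tools,
    utils
Suggests:
    digest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
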