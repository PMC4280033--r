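Package: torrentools
Title: Private BitTorrent Publication, Tracking and Swarm Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for controlled distribution of large scientific datasets
    over private BitTorrent swarms. Provides a canonical bencode
    encoder/decoder, creation and verification of .torrent metainfo files
    (forced private flag, per-user tokenized announce URLs), a role-based
    access-control portal (users, feeds, per-feed subscriber/publisher
    roles, admin bit, token issuance), an authenticated HTTP tracker
    (announce/scrape, compact peer lists, peer dashboard), RSS
    broadcatching feeds of torrents, and a deterministic piece-level swarm
    simulator for studying churn resilience and aggregate availability,
    together with a volunteer-storage calculator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    openssl,
    jsonlite,
    xml2,
    yaml,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
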