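---
title: "Private torrent distribution: model, access control and swarm simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Private torrent distribution: model, access control and swarm simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torrentools)
```

## The problem

Moving multi-hundred-GiB genomics payloads between collaborating sites
strains any centralized download service: the publisher's uplink is the
bottleneck, and a single silo is a single point of failure. BitTorrent
solves the bandwidth and resilience problem — every node that holds pieces
serves them — but the open protocol has no notion of *who* may join a
swarm. Controlled-access data, which is most of the data in the life
sciences, needs swarms that are private, authenticated and auditable while
leaving the peer-to-peer wire protocol untouched so stock clients keep
working.

`torrentools` implements that model end to end: torrents whose `private`
flag is forced on at publication, per-user authorization tokens embedded in
the announce URL and in RSS subscription URLs, a tracker that refuses
announces for unknown tokens, unknown torrents or insufficient roles, and a
deterministic piece-level simulator for studying how such a swarm behaves
under node churn.

## Identity: bencoding and the info-hash

Everything hangs off the info-hash, the SHA-1 digest of the bencoded
`info` dictionary of a torrent. Two properties of the serialization layer
make this identity usable:

* **Canonicality.** Bencoded dictionaries sort their keys by raw byte
  order and integers admit no leading zeros, so a value has exactly one
  encoding and `bencode(bdecode(b))` reproduces `b` byte for byte. The
  decoder is strict by default; a lenient mode accepts real-world torrents
  with unsorted keys and re-emits them canonically.
* **Verbatim hashing.** For a third-party torrent file the info-hash must
  be computed over the *exact bytes* of its `info` entry, not over a
  re-encoding — `bencode_slice()` extracts that span. For objects built in
  R the canonical encoding is, by construction, the same bytes.

Because the `private` flag lives inside `info`, privatizing a torrent
changes its info-hash. The portal therefore privatizes at upload time and
distributes only the privatized metainfo: the canonical swarm identity is
the post-privatization hash, the same for every subscriber.
`torrent_tokenize()` rewrites only the announce URL
(`<base>/<token>/announce`), which lives *outside* `info`, so per-user
copies still join one swarm. The token travels as a path segment rather
than a query parameter because clients are far less likely to mangle path
components when they rewrite tracker URLs.

Bencoded integers are represented as R doubles, exact to 2^53 — five
orders of magnitude beyond the largest payloads this system targets; the
decoder raises an error rather than silently rounding beyond that.
BitTorrent v1 (SHA-1) only: the private-flag mechanism this design builds
on is a v1-era extension, and v2/hybrid torrents are out of scope.

## Torrent creation and verification

`torrent_create()` splits the payload stream into `piece_length`-byte
pieces and stores one 20-byte SHA-1 digest per piece, so the digest count
is always `ceiling(total_bytes / piece_length)`. The default piece size is
4 MiB, a practical choice for payloads in the GiB range (small enough for
fine-grained verification and resumption, large enough to keep the
`pieces` field compact). Directories become multi-file torrents with files
ordered lexicographically by path components, bytewise — filesystem
enumeration order is not deterministic across platforms, and a
reproducible info-hash demands a reproducible file order. Piece indexing
is 0-based everywhere.

`torrent_verify()` recomputes every piece digest and reports a per-piece
pass/fail vector and the completion fraction. It never errors on damaged
data: missing or truncated files simply fail the affected pieces, which is
the behaviour an operator monitoring a partially-replicated node wants.

## Access control

The portal holds users, feeds and role assignments. The decision matrix,
enforced in the single `portal_authorize()` choke point and exercised
exhaustively in the tests:

| role | view feed | download / announce / RSS | publish / manage feed | manage users |
|------------|:---:|:---:|:---:|:---:|
| none       | – | – | – | – |
| subscriber | yes | yes | – | – |
| publisher  | yes | yes | yes | – |
| admin bit  | yes, every feed | yes, every feed | yes, every feed | yes |

Deny is the default: an unknown or rotated token, an unapproved account,
or an action outside the role's set all produce a deny *value* (with a
logged reason and stage), never a partial result. New accounts require
admin approval before any check can pass; the bootstrap admin is
pre-approved because someone must approve everyone else. Roles are per
user per feed; newly granted access defaults to subscriber, and absence of
a grant is role `none`. One deliberately conservative choice: publishers
may grant roles on their feeds but only admins may demote another
publisher, closing a mutual-demotion loophole the role model would
otherwise allow.

Tokens are 32 bytes from a cryptographic RNG, hex-rendered (256 bits of
entropy, URL-safe), stored only as SHA-256 hashes; passwords are stored as
salted bcrypt-PBKDF digests. Rotation installs a new token and invalidates
the old one atomically, and the tracker, RSS and download surfaces all
consult the same token table, so revocation is immediate everywhere.
Token *transport* security is the deployer's problem — the portal can
refuse token-bearing requests on plain HTTP (`require_https`), but
encryption itself belongs to the TLS layer in front of the service.

## The tracker

`tracker_announce()` performs the three-stage check (token → account
approval → role on the owning feed) and additionally refuses info-hashes
not registered in any feed: the tracker serves exactly the portal's
torrents, which is what partitions the private network. Peer records hold
the standard byte counters; a peer reporting `left == 0` counts as a
seeder, and completion percent is `100 × (1 − left/total)`, clamped to
[0, 100]. Responses use the compact 6-byte-per-peer form by default
(IPv4; other addresses fall back to dictionary entries), exclude the
requester, and cap the list at `max_peers` (default 50). Announce
interval defaults to 1800 s and the prune timeout to 2.5 intervals, so a
peer surviving two consecutive lost announces is still listed; a pruned
peer that re-announces is simply re-added, which is all the state
intermittently-connected nodes need. Failures are bencoded
`failure reason` dictionaries over HTTP 200 per tracker convention,
except authentication failures, which also carry 401/403.

## Feeds

`feed_rss()` renders a feed as RSS 2.0 broadcatching documents: one item
per torrent, newest first, guid = info-hash hex, RFC-822 `pubDate`, and an
`application/x-bittorrent` enclosure whose URL embeds the requesting
user's token — so two users' documents are identical except for every
embedded token, and a document generated for one user never contains
another's token. Feeds are expected to stay modest in item count, so
there is no pagination.

## The swarm simulator

The simulator stands in for a live multi-client deployment at the level
that matters for availability arguments: per-piece ownership. Time is
discrete; each node has download/upload capacities in pieces per tick
(bandwidth shaping abstracted to its effect, not its mechanism). Per
tick, after applying the churn schedule, each online node requests its
**rarest** missing piece among those visible on online peers — the
standard BitTorrent heuristic — with fully deterministic tie-breaks
(lowest piece index, then lowest provider id in sorted-id order) and
snapshot semantics: pieces acquired this tick become visible next tick.
The determinism is a design requirement, not an optimization: identical
configurations must produce identical traces so that experiments are
exactly reproducible, and with deterministic tie-breaks the exchange
rules consume no randomness at all (the config's seed feeds payload
generation, nothing else).

Two properties anchor the model, both tested over randomized churn
schedules:

* if the union of online nodes' bitfields covers all pieces at every tick
  (and each node is eventually online), every subscriber completes;
* conversely a piece absent from all nodes can never be conjured —
  configurations starting in that state are flagged `unrecoverable`.

What the simulator does *not* model: network latency and loss, choking /
tit-for-tat incentives, transfer-rate dynamics within a tick, and
geography. Passing simulations therefore demonstrate the availability and
churn-resilience logic of the system, not wire-level client behaviour —
interoperability with real clients rests on the standards compliance of
the metainfo and tracker layers, which the byte-level tests and the
independent info-hash oracle cover.

The bundled desk-scale experiment mirrors a realistic deployment shape at
bench size: 1 publishing seeder plus 7 subscribers moving a 64 MiB seeded
random payload in 4 MiB pieces (16 pieces), every subscriber interrupted
once and recovering, with node states mirrored into the live tracker so
the dashboard reports per-node percentages throughout. Payload sizes in
tests are kept in the KiB–MiB range; nothing in the code paths depends on
size beyond the hashing itself, which is streamed in piece-size chunks.

## The storage calculator

`storage_per_device(total, devices, participation)` divides an archive
across the participating fraction of a device fleet:
`total / (devices × participation)`, reported in GiB. Unit conventions
dominate at these scales, so they are explicit: `pb()` defaults to
decimal petabytes (10^15 bytes, the convention of storage vendors) while
the result uses binary GiB (2^30, the convention of operating systems);
`pb(x, binary = TRUE)` switches to all-binary units. A 40 PB archive
across 50% of a 2,883,000-device fleet works out to 25.8 GiB per device
under the default convention and 29.1 GiB all-binary — the same order,
differing only in unit bookkeeping.

## Service surface

No R HTTP-server framework is assumed: the entire service is a pure
request router, `portal_handle_request()`, mapping (method, path, query,
body, scheme) to (status, content type, body) for every tracker, feed and
admin endpoint, with `portal_serve()` a thin blocking socket loop around
it for actual deployments. This keeps the whole surface unit-testable
in-process. Durable portal state round-trips through a JSON document
(`portal_save()`/`portal_load()`) that contains credential and token
*hashes* only; the peer registry is deliberately ephemeral, since
announces are keep-alives and swarms rebuild within one interval. The
`torrentools` script under `inst/exec/` wraps creation, verification,
simulation, serving and admin actions for shell use.

## Known limitations

* BitTorrent v1 only; no magnet links, DHT or PEX (deliberately — they
  are incompatible with tracker-enforced privacy), no multi-tracker
  `announce-list`, no UDP tracker protocol.
* The simulator's capacity model is pieces/tick, not bytes/second; it
  cannot answer throughput questions, only availability ones.
* One portal instance is one network namespace; federation across portals
  is out of scope.
* Bencoded integers beyond 2^53 are rejected rather than arbitrary
  precision.
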