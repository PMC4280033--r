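# torrentools

Private BitTorrent publication, tracking and swarm simulation for large
scientific datasets.

Centralized downloads of multi-hundred-GiB genomics payloads bottleneck on
the publisher's uplink and fail with the silo. BitTorrent removes both
problems — every node holding pieces serves them — but the open protocol
has no access control. `torrentools` implements the private-swarm model on
top of standard BitTorrent: torrents whose BEP-0027 `private` flag is
*forced* on at publication, per-user authorization tokens embedded in the
announce URL (`<tracker>/<token>/announce`) and in RSS broadcatching URLs,
a tracker that authenticates every announce and refuses foreign torrents,
and role-based access control (per-feed `none`/`subscriber`/`publisher`
roles plus a global admin bit). The peer wire protocol is untouched, so
stock clients work. It is aimed at data managers running controlled-access
distribution networks and at anyone studying replication/churn behaviour
of such swarms.

The core quantities:

- a torrent's identity is its **info-hash**, `SHA1(bencode(info))`; the
  piece table holds `ceiling(total_bytes / piece_length)` 20-byte SHA-1
  digests (default piece size 4 MiB);
- a payload is recoverable iff the **union of online nodes' bitfields**
  covers all pieces: `complete ⟺ ⋁ᵢ bᵢ = 1`;
- per-peer dashboard completion is `100 × (1 − left/total)`;
- volunteer storage per device for a replicated archive is
  `total / (devices × participation)`.

The package also ships a deterministic piece-level swarm simulator
(rarest-first requests, capacity caps, churn schedules, reproducible
traces) and a minimal HTTP service layer (pure request router + socket
loop + CLI).

## Worked example

```r
library(torrentools)

# publisher side: a seeded 1 MiB payload and its torrent
fx <- fixture_payload("payload.bin", size = 2^20, seed = 7,
                      announce = "http://uploader.example/announce",
                      piece_length = 256 * 1024)
fx$torrent
#> <torrent payload-1048576-seed7>
#>   announce:     http://uploader.example/announce
#>   piece length: 262144 bytes
#>   pieces:       4
#>   total bytes:  1048576
#>   private:      FALSE
#>   info-hash:    0d7be8a3c64da1a744f6a37d1ee1c4e8ba3a5c29

# portal side: users, a feed, publication (forces private=1)
p <- portal_create(tracker_base = "https://portal.example/bt")
alice <- portal_register_user(p, "alice@lab.org", "pw-a")
bob   <- portal_register_user(p, "bob@lab.org", "pw-b")
portal_approve_user(p, "admin@localhost", "alice@lab.org")
portal_approve_user(p, "admin@localhost", "bob@lab.org")
fid <- portal_create_feed(p, "admin@localhost", "rna-sets", "reference RNA data")
portal_grant_role(p, "admin@localhost", "alice@lab.org", fid, "publisher")
portal_grant_role(p, "admin@localhost", "bob@lab.org", fid, "subscriber")

hex <- feed_publish(p, fid, fx$torrent, alice$token)
hex
#> [1] "2d09f8815dcc29e918150e257b75973fc3774964"   # post-privatization identity

# bob's personal copy: same swarm, his token in the announce URL
mi <- torrent_from_bytes(feed_download_torrent(p, fid, hex, bob$token))
mi$info$private            #> [1] 1
identical(format(info_hash(mi)), hex)   #> [1] TRUE

# bob announces as a seeder; the dashboard shows per-node completion
tracker_announce(p, bob$token, list(info_hash = hex,
                                    peer_id = strrep("b", 20),
                                    port = 6881, left = 0))$parsed$complete
#> [1] 1
swarm_status(p, fid, bob$token)[, c("torrent", "completion_pct", "seeder")]
#> # A tibble: 1 × 3
#>   torrent                completion_pct seeder
#>   <chr>                           <dbl> <lgl>
#> 1 payload-1048576-seed7             100 TRUE

# availability: 40 PB across half of a 2.9M-device fleet
storage_per_device(pb(40), 2883000, 0.5)
#> [1] 25.84315    # GiB per device
```

The info-hash changes at publication because the forced `private` flag
lives inside the `info` dictionary; every subscriber shares that one
post-privatization identity, while each carries a personal announce URL.

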