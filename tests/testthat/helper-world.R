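# Shared fixtures, built in code at test time.

# Random well-formed bencode value for property tests. Byte-strings are
# raw vectors (the native decode type) so round-trip comparisons are exact.
gen_bvalue <- function(depth = 0L) {
  kind <- if (depth >= 3L) sample(1:2, 1L) else sample(1:4, 1L, prob = c(.35, .25, .2, .2))
  switch(kind,
    as.raw(sample(0:255, sample(0:12, 1L), replace = TRUE)),       # byte-string
    as.numeric(sample(c(0, 1, -1, sample(-1e6:1e6, 1), 2^40 + sample(0:10, 1)), 1L)), # integer
    lapply(seq_len(sample(0:3, 1L)), function(i) gen_bvalue(depth + 1L)), # list
    {                                                               # dict (canonical key order)
      n <- sample(0:3, 1L)
      keys <- unique(as.character(replicate(n, paste(
        sample(c(letters, LETTERS, 0:9), sample(1:8, 1L), replace = TRUE),
        collapse = ""))))
      keys <- sort(keys, method = "radix")
      v <- lapply(seq_along(keys), function(i) gen_bvalue(depth + 1L))
      names(v) <- keys
      if (length(v) == 0L) structure(list(), names = character()) else v
    }
  )
}

# A small portal world: 3 users x 2 feeds covering every role combination,
# with one torrent published per feed.
build_world <- function(payload_bytes = 64 * 1024, piece_length = 16 * 1024) {
  p <- portal_create(tracker_base = "https://portal.example/bt")
  users <- list()
  for (nm in c("pub", "sub", "none")) {
    users[[nm]] <- portal_register_user(p, paste0(nm, "@example.org"), paste0(nm, "-pw"))
    portal_approve_user(p, "admin@localhost", paste0(nm, "@example.org"))
  }
  feeds <- c(
    a = portal_create_feed(p, "admin@localhost", "feed-a", "first feed"),
    b = portal_create_feed(p, "admin@localhost", "feed-b", "second feed")
  )
  portal_grant_role(p, "admin@localhost", "pub@example.org", feeds["a"], "publisher")
  portal_grant_role(p, "admin@localhost", "sub@example.org", feeds["a"], "subscriber")
  # feed b: pub is subscriber, sub has nothing
  portal_grant_role(p, "admin@localhost", "pub@example.org", feeds["b"], "subscriber")

  hashes <- character(0)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  for (i in seq_along(feeds)) {
    f <- file.path(dir, paste0("payload", i, ".bin"))
    fx <- fixture_payload(f, payload_bytes, seed = 100L + i,
                          announce = "http://uploader.example/announce",
                          piece_length = piece_length)
    hashes[names(feeds)[i]] <- feed_publish(
      p, feeds[i], fx$torrent,
      token = if (i == 1L) users$pub$token else portal_admin_token(p),
      published_at = 1700000000 + i * 3600
    )
  }
  list(portal = p, users = users, feeds = feeds, hashes = hashes, dir = dir)
}

# the bootstrap admin has no exposed clear token; rotating issues a fresh one
portal_admin_token <- function(p) portal_rotate_token(p, "admin@localhost")

announce_params <- function(hash_hex, peer, port = 6881, left = 0, event = "",
                            uploaded = 0, downloaded = 0, compact = "1", ip = NULL) {
  out <- list(info_hash = hash_hex,
              peer_id = sprintf("%-20s", substr(paste0("peer-", peer), 1, 20)),
              port = port, uploaded = uploaded, downloaded = downloaded,
              left = left, event = event, compact = compact)
  if (!is.null(ip)) out$ip <- ip
  out
}

python_infohash <- function(torrent_path) {
  out <- system2("python", c(test_path("oracle_infohash.py"), torrent_path),
                 stdout = TRUE, stderr = TRUE)
  trimws(out[length(out)])
}

have_python <- function() nzchar(Sys.which("python"))
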