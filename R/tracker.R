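#' Handle a tracker announce
#'
#' The authenticated announce endpoint. Validation happens in three layers:
#' the token must resolve to an approved account, the account must hold a
#' role allowing `announce` on the feed owning the torrent, and the
#' info-hash must belong to a torrent registered in some feed — announces
#' for foreign torrents are refused outright, which is what partitions the
#' private network from the open BitTorrent world.
#'
#' On success the peer is upserted into the swarm keyed by info-hash:
#' `started`/keep-alive announces refresh its counters and timestamp,
#' `completed` marks it a seeder, `stopped` removes it. The response lists
#' up to `max_peers` *other* members of the swarm, in compact 6-byte form
#' (4 address bytes + 2 port bytes, big-endian) by default or dictionary
#' form when `compact = 0`; non-IPv4 peers are always returned in
#' dictionary form.
#'
#' @param portal A `portal`.
#' @param token Clear authorization token (from the announce URL path).
#' @param params Announce parameters: `info_hash` (20 raw bytes or 40-char
#'   hex), `peer_id` (20 raw bytes or character), `port`, and optionally
#'   `uploaded`, `downloaded`, `left` (bytes), `event`
#'   (`"started"`, `"stopped"`, `"completed"` or empty), `compact` (0/1),
#'   `ip` (observed client address).
#' @param scheme `"http"` or `"https"` — the channel the request arrived
#'   on; plain HTTP is refused when the portal's `require_https` flag is
#'   set.
#' @param now Announce timestamp (numeric epoch seconds or POSIXct).
#' @return A list: `ok`, `http_status`, `body` (bencoded raw response,
#'   bit-exact as sent on the wire), and `parsed` (the decoded
#'   dictionary). Failures carry a `failure reason` key in the body;
#'   authentication failures also use an HTTP auth status.
#' @export
tracker_announce <- function(portal, token, params, scheme = "https", now = Sys.time()) {
  now <- as.numeric(now)
  fail <- function(reason, status = 200L) {
    body <- bencode(list(`failure reason` = reason))
    list(ok = FALSE, http_status = status, body = body,
         parsed = list(`failure reason` = reason))
  }
  if (isTRUE(portal$config$require_https) && !identical(scheme, "https")) {
    return(fail("secure channel required", 403L))
  }
  p <- tryCatch(normalize_announce_params(params), error = function(e) conditionMessage(e))
  if (is.character(p)) return(fail(paste0("bad request: ", p), 400L))

  hash_hex <- p$info_hash_hex
  feed_id <- portal$hash_feed[[hash_hex]]
  if (is.null(feed_id)) {
    # still require a real token before admitting anything about registration
    u <- portal_user_by_token(portal, token)
    if (is.null(u) || !isTRUE(u$approved)) return(fail("unauthorized", 401L))
    return(fail("unregistered torrent"))
  }
  dec <- portal_authorize(portal, token, feed_id, "announce", stage = "announce")
  if (!dec$allowed) {
    if (grepl("token|approved", dec$reason)) return(fail("unauthorized", 401L))
    return(fail("forbidden", 403L))
  }

  if (is.null(portal$swarms[[hash_hex]])) portal$swarms[[hash_hex]] <- list()
  key <- p$peer_id_hex
  if (identical(p$event, "stopped")) {
    portal$swarms[[hash_hex]][[key]] <- NULL
  } else {
    prev <- portal$swarms[[hash_hex]][[key]]
    completed <- identical(p$event, "completed") || p$left == 0 ||
      (!is.null(prev) && isTRUE(prev$completed))
    portal$swarms[[hash_hex]][[key]] <- list(
      peer_id = p$peer_id, ip = p$ip, port = p$port,
      uploaded = p$uploaded, downloaded = p$downloaded, left = p$left,
      completed = completed, last_announce = now, email = portal$tokens[[hash_token(token)]]
    )
  }

  swarm <- portal$swarms[[hash_hex]]
  others <- swarm[setdiff(names(swarm), key)]
  if (length(others) > portal$config$max_peers) {
    others <- others[seq_len(portal$config$max_peers)]
  }
  n_complete <- sum(vapply(swarm, function(pr) pr$left == 0, TRUE))
  n_incomplete <- length(swarm) - n_complete

  resp <- list(
    interval = portal$config$announce_interval,
    complete = n_complete,
    incomplete = n_incomplete
  )
  if (p$compact) {
    ipv4 <- Filter(function(pr) is_ipv4(pr$ip), others)
    rest <- Filter(function(pr) !is_ipv4(pr$ip), others)
    resp$peers <- peers_compact(
      vapply(ipv4, function(pr) pr$ip, ""),
      vapply(ipv4, function(pr) pr$port, 1)
    )
    if (length(rest)) resp$peers6dict <- unname(lapply(rest, peer_dict_entry))
  } else {
    resp$peers <- unname(lapply(others, peer_dict_entry))
  }
  list(ok = TRUE, http_status = 200L, body = bencode(resp), parsed = resp)
}

peer_dict_entry <- function(pr) {
  list(`peer id` = pr$peer_id, ip = pr$ip, port = pr$port)
}

is_ipv4 <- function(ip) grepl("^([0-9]{1,3}\\.){3}[0-9]{1,3}$", ip)

normalize_announce_params <- function(params) {
  need_20 <- function(x, what) {
    if (is.character(x) && length(x) == 1L && grepl("^[0-9a-fA-F]{40}$", x)) {
      x <- hex_to_raw(tolower(x))
    } else if (is.character(x) && length(x) == 1L && nchar(x, type = "bytes") == 20L) {
      x <- charToRaw(x)
    }
    if (!is.raw(x) || length(x) != 20L) stop(what, " must be exactly 20 bytes")
    x
  }
  info_hash <- need_20(params$info_hash, "info_hash")
  peer_id <- need_20(params$peer_id, "peer_id")
  port <- as.numeric(params$port %||% stop("port required"))
  if (is.na(port) || port < 1 || port > 65535) stop("port out of range")
  num <- function(x, default = 0) {
    v <- as.numeric(x %||% default)
    if (is.na(v) || v < 0) stop("byte counters must be non-negative")
    v
  }
  event <- as.character(params$event %||% "")
  if (!event %in% c("", "started", "stopped", "completed")) stop("unknown event")
  list(
    info_hash = info_hash, info_hash_hex = raw_to_hex(info_hash),
    peer_id = peer_id, peer_id_hex = raw_to_hex(peer_id),
    port = port,
    uploaded = num(params$uploaded), downloaded = num(params$downloaded),
    left = num(params$left),
    event = event,
    compact = !identical(as.character(params$compact %||% "1"), "0"),
    ip = as.character(params$ip %||% "127.0.0.1")
  )
}

#' Compact peer-list encoding
#'
#' Encodes IPv4 peers as the standard concatenation of 6-byte entries: 4
#' address bytes followed by the port in big-endian. `peers_uncompact()`
#' inverts it.
#'
#' @param ips Character vector of dotted-quad IPv4 addresses.
#' @param ports Numeric vector of ports (1–65535).
#' @return `peers_compact()`: raw vector, 6 bytes per peer.
#'   `peers_uncompact()`: tibble with `ip` and `port`.
#' @export
peers_compact <- function(ips, ports) {
  stopifnot(length(ips) == length(ports))
  if (length(ips) == 0L) return(raw(0))
  parts <- lapply(seq_along(ips), function(i) {
    if (!is_ipv4(ips[i])) stop("peers_compact: not an IPv4 address: ", ips[i])
    oct <- as.integer(strsplit(ips[i], ".", fixed = TRUE)[[1L]])
    if (length(oct) != 4L || anyNA(oct) || any(oct < 0 | oct > 255)) {
      stop("peers_compact: not an IPv4 address: ", ips[i])
    }
    port <- as.integer(ports[i])
    if (is.na(port) || port < 1L || port > 65535L) stop("peers_compact: bad port")
    as.raw(c(oct, port %/% 256L, port %% 256L))
  })
  do.call(c, parts)
}

#' @rdname peers_compact
#' @param compact Raw vector of 6-byte peer entries.
#' @export
peers_uncompact <- function(compact) {
  stopifnot(is.raw(compact), length(compact) %% 6L == 0L)
  n <- length(compact) %/% 6L
  if (n == 0L) return(tibble::tibble(ip = character(), port = integer()))
  m <- matrix(as.integer(compact), nrow = 6L)
  tibble::tibble(
    ip = apply(m[1:4, , drop = FALSE], 2L, paste, collapse = "."),
    port = as.integer(m[5L, ] * 256L + m[6L, ])
  )
}

#' Handle a tracker scrape
#'
#' Returns per-torrent swarm statistics — seeder count (`complete`),
#' leecher count (`incomplete`) and historical completion count
#' (`downloaded`) — for each requested info-hash the token is authorized
#' on. Hashes the token may not see carry an error marker instead of
#' counts, so swarm sizes never leak across feed boundaries.
#'
#' @param portal A `portal`.
#' @param token Clear authorization token.
#' @param info_hashes List/vector of info-hashes (raw or hex).
#' @param scheme Request channel, as in [tracker_announce()].
#' @return A list: `ok`, `http_status`, `body` (bencoded), `parsed` with a
#'   `files` dictionary keyed by hex hash.
#' @export
tracker_scrape <- function(portal, token, info_hashes, scheme = "https") {
  if (isTRUE(portal$config$require_https) && !identical(scheme, "https")) {
    body <- bencode(list(`failure reason` = "secure channel required"))
    return(list(ok = FALSE, http_status = 403L, body = body,
                parsed = list(`failure reason` = "secure channel required")))
  }
  if (!is.list(info_hashes)) info_hashes <- as.list(info_hashes)
  files <- list()
  for (h in info_hashes) {
    hex <- if (is.raw(h)) raw_to_hex(h) else tolower(as.character(h))
    feed_id <- portal$hash_feed[[hex]]
    authorized <- !is.null(feed_id) &&
      portal_authorize(portal, token, feed_id, "announce", stage = "announce")$allowed
    if (!authorized) {
      files[[hex]] <- list(error = "unauthorized")
      next
    }
    swarm <- portal$swarms[[hex]] %||% list()
    n_complete <- if (length(swarm)) sum(vapply(swarm, function(pr) pr$left == 0, TRUE)) else 0L
    n_downloaded <- if (length(swarm)) sum(vapply(swarm, function(pr) isTRUE(pr$completed), TRUE)) else 0L
    files[[hex]] <- list(
      complete = n_complete,
      downloaded = n_downloaded,
      incomplete = length(swarm) - n_complete
    )
  }
  parsed <- list(files = files)
  list(ok = TRUE, http_status = 200L, body = bencode(parsed), parsed = parsed)
}

#' Remove peers that stopped announcing
#'
#' Peers whose last announce is older than `timeout` are dropped from
#' every swarm. A pruned peer that comes back (for example a node on an
#' intermittent connection) is simply re-added by its next announce; no
#' state beyond the announce itself is needed to resume.
#'
#' @param portal A `portal`.
#' @param now Current time (numeric epoch seconds or POSIXct).
#' @param timeout Seconds of silence tolerated; defaults to the portal's
#'   `peer_timeout`. `Inf` disables pruning.
#' @return Number of peers removed (invisibly returns 0 for none).
#' @export
tracker_prune <- function(portal, now = Sys.time(), timeout = portal$config$peer_timeout) {
  now <- as.numeric(now)
  removed <- 0L
  for (hex in names(portal$swarms)) {
    swarm <- portal$swarms[[hex]]
    stale <- vapply(swarm, function(pr) (now - pr$last_announce) > timeout, TRUE)
    if (any(stale)) {
      removed <- removed + sum(stale)
      portal$swarms[[hex]] <- swarm[!stale]
    }
  }
  removed
}

#' Per-feed swarm dashboard
#'
#' One row per (torrent, peer): who is in each swarm, how complete they
#' are, when they last announced, and whether they are seeding. The
#' completion percentage is derived from the peer's reported `left`
#' counter against the torrent's payload size, clamped to [0, 100].
#' Geolocation is resolved by a pluggable function; the default stub
#' reports `"unknown"`.
#'
#' @param portal A `portal`.
#' @param feed_id Feed to report on.
#' @param token Clear token; must be allowed `view_feed` on the feed.
#' @param geolocate Function `(ip) -> character` used to annotate peers.
#' @return Tibble: `torrent`, `info_hash`, `peer_id`, `ip`, `location`,
#'   `port`, `completion_pct`, `seeder`, `last_announce`.
#' @export
swarm_status <- function(portal, feed_id, token, geolocate = function(ip) "unknown") {
  dec <- portal_authorize(portal, token, feed_id, "view_feed")
  if (!dec$allowed) stop("swarm_status: ", dec$reason)
  feed <- portal$feeds[[as.character(feed_id)]]
  rows <- list()
  for (hex in names(feed$torrents)) {
    rec <- feed$torrents[[hex]]
    total <- rec$total_bytes
    swarm <- portal$swarms[[hex]] %||% list()
    for (pr in swarm) {
      pct <- 100 * (1 - pr$left / total)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        torrent = rec$title,
        info_hash = hex,
        peer_id = raw_to_hex(pr$peer_id),
        ip = pr$ip,
        location = geolocate(pr$ip),
        port = as.integer(pr$port),
        completion_pct = max(0, min(100, pct)),
        seeder = pr$left == 0,
        last_announce = pr$last_announce
      )
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(
      torrent = character(), info_hash = character(), peer_id = character(),
      ip = character(), location = character(), port = integer(),
      completion_pct = numeric(), seeder = logical(), last_announce = numeric()
    ))
  }
  do.call(rbind, rows)
}
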