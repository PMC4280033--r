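#' Save and load portal state
#'
#' Serializes the durable portal state — configuration, accounts (with
#' salted credential hashes and token hashes, never clear secrets), feeds
#' with their torrent bytes, role assignments — to a JSON document. The
#' peer registry is deliberately *not* persisted: announces are
#' keep-alives, so live swarms rebuild themselves within one announce
#' interval of a restart.
#'
#' @param portal A `portal`.
#' @param path JSON file path.
#' @return `portal_load()` returns a `portal`; `portal_save()` the path,
#'   invisibly.
#' @export
portal_save <- function(portal, path) {
  stopifnot(inherits(portal, "portal"))
  state <- list(
    config = portal$config,
    next_feed_id = portal$next_feed_id,
    users = lapply(unname(portal$users), function(u) list(
      email = u$email, salt = raw_to_hex(u$salt), credential = u$credential,
      approved = u$approved, admin = u$admin, token_hash = u$token_hash
    )),
    tokens = portal$tokens,
    roles = portal$roles,
    feeds = lapply(unname(portal$feeds), function(f) list(
      id = f$id, name = f$name, description = f$description,
      torrents = lapply(names(f$torrents), function(hex) {
        rec <- f$torrents[[hex]]
        list(info_hash = hex, title = rec$title, published_at = rec$published_at,
             bytes = jsonlite::base64_enc(torrent_bytes(rec$metainfo)))
      })
    ))
  )
  jsonlite::write_json(state, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname portal_save
#' @export
portal_load <- function(path) {
  s <- jsonlite::read_json(path)
  p <- new.env(parent = emptyenv())
  p$config <- s$config
  p$next_feed_id <- as.integer(s$next_feed_id)
  p$users <- list()
  for (u in s$users) {
    p$users[[u$email]] <- list(
      email = u$email, salt = hex_to_raw(u$salt), credential = u$credential,
      approved = isTRUE(u$approved), admin = isTRUE(u$admin), token_hash = u$token_hash
    )
  }
  p$tokens <- s$tokens
  p$roles <- s$roles
  p$feeds <- list()
  p$hash_feed <- list()
  p$swarms <- list()
  p$log <- list()
  for (f in s$feeds) {
    torrents <- list()
    for (tr in f$torrents) {
      mi <- torrent_from_bytes(jsonlite::base64_dec(tr$bytes))
      torrents[[tr$info_hash]] <- list(
        metainfo = mi, title = tr$title,
        published_at = as.numeric(tr$published_at),
        total_bytes = torrent_total_bytes(mi)
      )
      p$hash_feed[[tr$info_hash]] <- f$id
    }
    p$feeds[[as.character(f$id)]] <- list(
      id = f$id, name = f$name, description = f$description, torrents = torrents
    )
  }
  class(p) <- "portal"
  p
}
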