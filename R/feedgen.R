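#' Publish a torrent to a feed
#'
#' Registers an uploaded torrent with a feed. The stored record holds the
#' *privatized* canonical metainfo: the private flag is forced on at
#' upload, so the info-hash every subscriber sees — and the one the
#' tracker keys the swarm by — is the post-privatization one, and all
#' users share a single swarm. Duplicate info-hashes within a feed are
#' rejected.
#'
#' @param portal A `portal`.
#' @param feed_id Target feed.
#' @param torrent A `metainfo` object or raw bencoded torrent bytes.
#' @param token Clear token of the publisher; must be allowed
#'   `publish_torrent` on the feed.
#' @param title Display title (defaults to the torrent name).
#' @param published_at Publication time (numeric epoch seconds or
#'   POSIXct).
#' @return The hex info-hash of the registered (privatized) torrent.
#' @export
feed_publish <- function(portal, feed_id, torrent, token,
                         title = NULL, published_at = Sys.time()) {
  dec <- portal_authorize(portal, token, feed_id, "publish_torrent")
  if (!dec$allowed) stop("feed_publish: ", dec$reason)
  if (is.raw(torrent)) torrent <- torrent_from_bytes(torrent)
  stopifnot(inherits(torrent, "metainfo"))
  torrent <- torrent_privatize(torrent)
  hex <- format(info_hash(torrent))
  fkey <- as.character(feed_id)
  if (!is.null(portal$feeds[[fkey]]$torrents[[hex]])) {
    stop("feed_publish: torrent already published to feed ", feed_id, " (", hex, ")")
  }
  if (!is.null(portal$hash_feed[[hex]])) {
    stop("feed_publish: torrent already registered in another feed (", hex, ")")
  }
  portal$feeds[[fkey]]$torrents[[hex]] <- list(
    metainfo = torrent,
    title = title %||% torrent$info$name,
    published_at = as.numeric(published_at),
    total_bytes = torrent_total_bytes(torrent)
  )
  portal$hash_feed[[hex]] <- feed_id
  hex
}

#' Download a tokenized .torrent
#'
#' Produces the .torrent bytes a specific user should load into their
#' client: the stored privatized metainfo with the announce URL customized
#' to embed *that user's* token (`<tracker_base>/<token>/announce`).
#' Because only the announce URL differs between users, every user's copy
#' has the same info-hash and joins the same swarm — but each copy is
#' personal, and announces made with it are attributable to its owner.
#'
#' @param portal A `portal`.
#' @param feed_id Feed the torrent belongs to.
#' @param hash Info-hash (hex string or `info_hash`).
#' @param token Clear token; must be allowed `download_torrent`.
#' @return Raw vector: the bencoded, privatized, tokenized .torrent.
#' @export
feed_download_torrent <- function(portal, feed_id, hash, token) {
  dec <- portal_authorize(portal, token, feed_id, "download_torrent")
  if (!dec$allowed) stop("feed_download_torrent: ", dec$reason)
  hex <- if (inherits(hash, "info_hash")) format(hash) else tolower(as.character(hash))
  rec <- portal$feeds[[as.character(feed_id)]]$torrents[[hex]]
  if (is.null(rec)) stop("feed_download_torrent: no such torrent in feed ", feed_id, ": ", hex)
  mi <- torrent_tokenize(rec$metainfo, portal$config$tracker_base, token)
  torrent_bytes(mi)
}

#' Generate a per-user RSS feed document
#'
#' Builds the RSS 2.0 broadcatching document for a feed, personalized to
#' the requesting user: the channel link and every item's enclosure URL
#' embed that user's token, so a client that subscribes to the URL
#' automatically fetches each .torrent with the right credentials. Items
#' are sorted newest-first; the guid of each item is the torrent's hex
#' info-hash; enclosures carry the `application/x-bittorrent` media type
#' and the byte length of the tokenized .torrent file.
#'
#' @param portal A `portal`.
#' @param feed_id Feed to render.
#' @param token Clear token; must be allowed `fetch_rss` on the feed (an
#'   unauthorized token yields an error, never a partial document).
#' @param base_url Portal base URL used to construct embedded links.
#' @return Raw vector: the serialized RSS 2.0 XML document (UTF-8).
#' @export
feed_rss <- function(portal, feed_id, token, base_url = portal$config$tracker_base) {
  dec <- portal_authorize(portal, token, feed_id, "fetch_rss", stage = "rss")
  if (!dec$allowed) stop("feed_rss: ", dec$reason)
  feed <- portal$feeds[[as.character(feed_id)]]
  base <- sub("/+$", "", base_url)

  doc <- xml2::xml_new_root("rss", version = "2.0")
  channel <- xml2::xml_add_child(doc, "channel")
  xml2::xml_add_child(channel, "title", feed$name)
  xml2::xml_add_child(channel, "description", feed$description)
  xml2::xml_add_child(channel, "link",
                      paste0(base, "/", token, "/feeds/", feed_id, ".rss"))

  recs <- feed$torrents
  if (length(recs)) {
    ord <- order(vapply(recs, function(r) r$published_at, 1), decreasing = TRUE)
    for (i in ord) {
      hex <- names(recs)[i]
      rec <- recs[[i]]
      item <- xml2::xml_add_child(channel, "item")
      xml2::xml_add_child(item, "title", rec$title)
      guid <- xml2::xml_add_child(item, "guid", hex)
      xml2::xml_set_attr(guid, "isPermaLink", "false")
      xml2::xml_add_child(item, "pubDate", rfc822_date(rec$published_at))
      enc <- xml2::xml_add_child(item, "enclosure")
      xml2::xml_set_attr(enc, "url",
                         paste0(base, "/", token, "/feeds/", feed_id,
                                "/torrents/", hex, ".torrent"))
      tok_bytes <- torrent_bytes(torrent_tokenize(rec$metainfo,
                                                  portal$config$tracker_base, token))
      xml2::xml_set_attr(enc, "length", format(length(tok_bytes), scientific = FALSE))
      xml2::xml_set_attr(enc, "type", "application/x-bittorrent")
    }
  }
  charToRaw(as.character(doc))
}

rfc822_date <- function(epoch) {
  t <- as.POSIXct(as.numeric(epoch), origin = "1970-01-01", tz = "GMT")
  old <- Sys.getlocale("LC_TIME")
  on.exit(suppressWarnings(Sys.setlocale("LC_TIME", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_TIME", "C"))
  format(t, "%a, %d %b %Y %H:%M:%S GMT")
}

#' List the torrents registered in a feed
#' @param portal A `portal`.
#' @param feed_id Feed.
#' @param token Clear token; must be allowed `view_feed`.
#' @return Tibble: `info_hash`, `title`, `published_at`, `total_bytes`,
#'   `pieces`, `piece_length`.
#' @export
feed_torrents_tbl <- function(portal, feed_id, token) {
  dec <- portal_authorize(portal, token, feed_id, "view_feed")
  if (!dec$allowed) stop("feed_torrents_tbl: ", dec$reason)
  recs <- portal$feeds[[as.character(feed_id)]]$torrents
  tibble::tibble(
    info_hash = names(recs) %||% character(),
    title = vapply(recs, function(r) r$title, ""),
    published_at = vapply(recs, function(r) r$published_at, 1),
    total_bytes = vapply(recs, function(r) r$total_bytes, 1),
    pieces = vapply(recs, function(r) torrent_piece_count(r$metainfo), 1L),
    piece_length = vapply(recs, function(r) as.numeric(r$metainfo$info$`piece length`), 1)
  )
}
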