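#' Create a portal instance
#'
#' A portal is the access-control core of a private distribution network:
#' it owns the user accounts, the feeds (named, access-controlled
#' collections of torrents), per-feed role assignments, authorization
#' tokens, and the tracker's peer registry. One portal instance manages
#' exactly one network namespace.
#'
#' New accounts start unapproved and fail every authorization check until
#' an administrator approves them. The first account, created from
#' `admin_email`/`admin_password`, is bootstrapped pre-approved with the
#' admin bit set — someone has to be able to approve everyone else.
#'
#' @param admin_email,admin_password Bootstrap administrator credentials.
#' @param announce_interval Seconds clients should wait between announces
#'   (default 1800).
#' @param peer_timeout Seconds of announce silence after which a peer is
#'   considered gone (default 2.5 x `announce_interval`).
#' @param max_peers Maximum peers returned per announce (default 50).
#' @param piece_length Default piece size in bytes for torrents created
#'   through this portal (default 4 MiB).
#' @param require_https When `TRUE`, token-authenticated requests arriving
#'   over plain HTTP are refused; token transport is assumed to need an
#'   encrypted channel.
#' @param tracker_base Base URL under which announce endpoints are exposed
#'   (used when tokenizing torrents for download).
#' @return A `portal` object (a mutable environment); pass it to the
#'   `portal_*`, `tracker_*` and `feed_*` functions.
#' @export
portal_create <- function(admin_email = "admin@localhost",
                          admin_password = "change-me",
                          announce_interval = 1800,
                          peer_timeout = 2.5 * announce_interval,
                          max_peers = 50L,
                          piece_length = 4 * 1048576,
                          require_https = FALSE,
                          tracker_base = "http://localhost:6969") {
  p <- new.env(parent = emptyenv())
  p$config <- list(
    announce_interval = announce_interval,
    peer_timeout = peer_timeout,
    max_peers = as.integer(max_peers),
    piece_length = piece_length,
    require_https = require_https,
    tracker_base = tracker_base
  )
  p$users <- list()      # email -> user record
  p$tokens <- list()     # sha256(token) hex -> email
  p$feeds <- list()      # feed id -> feed record
  p$roles <- list()      # "email\rfeed_id" -> "subscriber"|"publisher"
  p$swarms <- list()     # info-hash hex -> list(peer key -> peer record)
  p$hash_feed <- list()  # info-hash hex -> owning feed id
  p$next_feed_id <- 1L
  p$log <- list()
  class(p) <- "portal"

  admin <- portal_register_user(p, admin_email, admin_password)
  p$users[[admin_email]]$approved <- TRUE
  p$users[[admin_email]]$admin <- TRUE
  p
}

#' @export
print.portal <- function(x, ...) {
  cat("<portal: ", length(x$users), " users, ", length(x$feeds), " feeds, ",
      length(x$swarms), " swarms>\n", sep = "")
  invisible(x)
}

portal_log <- function(portal, stage, decision, detail) {
  portal$log[[length(portal$log) + 1L]] <- list(
    time = as.numeric(Sys.time()), stage = stage,
    decision = decision, detail = detail
  )
  invisible(NULL)
}

#' Portal authorization log
#' @param portal A `portal`.
#' @return A tibble with one row per logged authorization decision
#'   (`time`, `stage`, `decision`, `detail`).
#' @export
portal_log_tbl <- function(portal) {
  if (length(portal$log) == 0L) {
    return(tibble::tibble(time = numeric(), stage = character(),
                          decision = character(), detail = character()))
  }
  tibble::tibble(
    time = vapply(portal$log, function(e) e$time, 1),
    stage = vapply(portal$log, function(e) e$stage, ""),
    decision = vapply(portal$log, function(e) e$decision, ""),
    detail = vapply(portal$log, function(e) e$detail, "")
  )
}

hash_token <- function(token) digest::digest(charToRaw(token), algo = "sha256", serialize = FALSE)

hash_password <- function(password, salt) {
  raw_to_hex(openssl::bcrypt_pbkdf(password, salt, rounds = 16L, size = 32L))
}

#' Register a new user account
#'
#' New accounts are created in the unapproved state: they hold a token but
#' every authorization check denies until an administrator approves the
#' account. Email addresses are unique per portal.
#'
#' @param portal A `portal`.
#' @param email,password Credentials; the password is stored as a salted
#'   adaptive hash, never in clear.
#' @return Invisibly, a list describing the account (email, approved,
#'   admin, token). The token is the only time the clear token is exposed.
#' @export
portal_register_user <- function(portal, email, password) {
  stopifnot(inherits(portal, "portal"), nzchar(email), nzchar(password))
  if (!is.null(portal$users[[email]])) stop("portal_register_user: email already registered: ", email)
  salt <- openssl::rand_bytes(16)
  token <- issue_token_string()
  portal$users[[email]] <- list(
    email = email,
    salt = salt,
    credential = hash_password(password, salt),
    approved = FALSE,
    admin = FALSE,
    token_hash = hash_token(token)
  )
  portal$tokens[[hash_token(token)]] <- email
  invisible(list(email = email, approved = FALSE, admin = FALSE, token = token))
}

# 32 bytes from a cryptographic RNG, hex-rendered: URL-safe, 256 bits entropy
issue_token_string <- function() raw_to_hex(openssl::rand_bytes(32))

#' Verify a user's password
#' @param portal A `portal`.
#' @param email,password Credentials to check.
#' @return `TRUE` only for a known account with a matching password.
#' @export
portal_check_password <- function(portal, email, password) {
  u <- portal$users[[email]]
  if (is.null(u)) return(FALSE)
  identical(hash_password(password, u$salt), u$credential)
}

portal_user_by_token <- function(portal, token) {
  if (!is.character(token) || length(token) != 1L || !nzchar(token)) return(NULL)
  email <- portal$tokens[[hash_token(token)]]
  if (is.null(email)) NULL else portal$users[[email]]
}

#' Approve a pending account
#'
#' Only administrators may approve accounts; until approved, a user cannot
#' log in and all token checks deny.
#'
#' @param portal A `portal`.
#' @param admin_email Acting administrator.
#' @param email Account to approve.
#' @export
portal_approve_user <- function(portal, admin_email, email) {
  actor <- portal$users[[admin_email]]
  if (is.null(actor) || !isTRUE(actor$admin) || !isTRUE(actor$approved)) {
    stop("portal_approve_user: ", admin_email, " is not an administrator")
  }
  if (is.null(portal$users[[email]])) stop("portal_approve_user: no such user: ", email)
  portal$users[[email]]$approved <- TRUE
  invisible(portal)
}

#' Set or clear the global administrator bit
#' @inheritParams portal_approve_user
#' @param admin Logical.
#' @export
portal_set_admin <- function(portal, admin_email, email, admin = TRUE) {
  actor <- portal$users[[admin_email]]
  if (is.null(actor) || !isTRUE(actor$admin)) stop("portal_set_admin: not an administrator")
  if (is.null(portal$users[[email]])) stop("portal_set_admin: no such user: ", email)
  portal$users[[email]]$admin <- isTRUE(admin)
  invisible(portal)
}

#' Create a feed
#'
#' A feed is a named, access-controlled collection of torrents that
#' subscribers receive via a tokenized RSS URL. Feed creation is an
#' administrative action; publishers are then granted per-feed.
#'
#' @param portal A `portal`.
#' @param admin_email Acting administrator.
#' @param name,description Feed metadata.
#' @return The feed id (integer).
#' @export
portal_create_feed <- function(portal, admin_email, name, description = "") {
  actor <- portal$users[[admin_email]]
  if (is.null(actor) || !isTRUE(actor$admin) || !isTRUE(actor$approved)) {
    stop("portal_create_feed: not an administrator")
  }
  id <- portal$next_feed_id
  portal$next_feed_id <- id + 1L
  portal$feeds[[as.character(id)]] <- list(
    id = id, name = name, description = description,
    torrents = list() # info-hash hex -> list(bytes, metainfo, published_at, title)
  )
  id
}

role_key <- function(email, feed_id) paste0(email, "\r", feed_id)

#' Grant or change a user's role on a feed
#'
#' Roles are per user per feed: `none` (no visibility at all),
#' `subscriber` (log in, use download links, join torrents), `publisher`
#' (all subscriber abilities plus publishing and feed management). The
#' granter must hold the admin bit or be a publisher on that feed; only
#' admins may demote a publisher.
#'
#' @param portal A `portal`.
#' @param granter_email Acting user.
#' @param email Target user.
#' @param feed_id Feed.
#' @param role One of `"none"`, `"subscriber"`, `"publisher"`.
#' @export
portal_grant_role <- function(portal, granter_email, email, feed_id,
                              role = c("subscriber", "publisher", "none")) {
  role <- match.arg(role)
  granter <- portal$users[[granter_email]]
  if (is.null(granter) || !isTRUE(granter$approved)) {
    stop("portal_grant_role: granter not an approved account")
  }
  feed <- portal$feeds[[as.character(feed_id)]]
  if (is.null(feed)) stop("portal_grant_role: no such feed: ", feed_id)
  if (is.null(portal$users[[email]])) stop("portal_grant_role: no such user: ", email)
  granter_is_admin <- isTRUE(granter$admin)
  granter_is_pub <- identical(portal_role(portal, granter_email, feed_id), "publisher")
  if (!granter_is_admin && !granter_is_pub) {
    stop("portal_grant_role: granter lacks publisher rights on feed ", feed_id)
  }
  current <- portal_role(portal, email, feed_id)
  if (current == "publisher" && role != "publisher" && !granter_is_admin) {
    stop("portal_grant_role: only administrators may demote a publisher")
  }
  k <- role_key(email, feed_id)
  if (role == "none") portal$roles[[k]] <- NULL else portal$roles[[k]] <- role
  invisible(list(user = email, feed = feed_id, role = role))
}

#' Effective role of a user on a feed
#' @inheritParams portal_grant_role
#' @return `"none"`, `"subscriber"` or `"publisher"` (explicit assignment
#'   only; the admin bit is resolved by [portal_authorize()], not here).
#' @export
portal_role <- function(portal, email, feed_id) {
  portal$roles[[role_key(email, feed_id)]] %||% "none"
}

#' Rotate a user's authorization token
#'
#' Issues a fresh token and immediately invalidates the old one everywhere:
#' RSS fetches, torrent downloads and tracker announces bearing the old
#' token are denied from this call on.
#'
#' @param portal A `portal`.
#' @param email Account whose token to rotate.
#' @return The new clear token (character).
#' @export
portal_rotate_token <- function(portal, email) {
  u <- portal$users[[email]]
  if (is.null(u)) stop("portal_rotate_token: no such user: ", email)
  portal$tokens[[u$token_hash]] <- NULL
  token <- issue_token_string()
  portal$users[[email]]$token_hash <- hash_token(token)
  portal$tokens[[hash_token(token)]] <- email
  token
}

portal_actions <- c("view_feed", "download_torrent", "announce", "fetch_rss",
                    "publish_torrent", "manage_feed", "manage_users")

subscriber_actions <- c("view_feed", "download_torrent", "announce", "fetch_rss")
publisher_actions <- c(subscriber_actions, "publish_torrent", "manage_feed")

#' Authorize an action by token
#'
#' The single decision point for every portal, feed and tracker request.
#' The decision matrix: an unknown or rotated token, or an unapproved
#' account, denies everything; role `none` denies everything on the feed;
#' `subscriber` allows `view_feed`, `download_torrent`, `announce` and
#' `fetch_rss`; `publisher` adds `publish_torrent` and `manage_feed`; the
#' global admin bit grants publisher rights on every feed plus
#' `manage_users`. Anything not explicitly allowed is denied.
#'
#' @param portal A `portal`.
#' @param token Clear authorization token from the request.
#' @param feed_id Feed the action concerns (`NA` for feed-independent
#'   actions such as `manage_users`).
#' @param action One of `"view_feed"`, `"download_torrent"`, `"announce"`,
#'   `"fetch_rss"`, `"publish_torrent"`, `"manage_feed"`, `"manage_users"`.
#' @param stage Which authenticated surface the request hit (for the
#'   decision log): `"portal"`, `"rss"` or `"announce"`.
#' @return A list: `allowed` (logical) and `reason` (character). Denial is
#'   a value, not an error.
#' @export
portal_authorize <- function(portal, token, feed_id, action, stage = "portal") {
  if (!action %in% portal_actions) stop("portal_authorize: unknown action: ", action)
  deny <- function(reason) {
    portal_log(portal, stage, "deny", paste0(action, ": ", reason))
    list(allowed = FALSE, reason = reason)
  }
  u <- portal_user_by_token(portal, token)
  if (is.null(u)) return(deny("unknown or revoked token"))
  if (!isTRUE(u$approved)) return(deny("account not approved"))
  if (isTRUE(u$admin)) {
    portal_log(portal, stage, "allow", paste0(action, ": admin ", u$email))
    return(list(allowed = TRUE, reason = "admin"))
  }
  if (action == "manage_users") return(deny("requires administrator"))
  if (is.na(feed_id) || is.null(portal$feeds[[as.character(feed_id)]])) {
    return(deny("unknown feed"))
  }
  role <- portal_role(portal, u$email, feed_id)
  allowed_set <- switch(role,
    none = character(0),
    subscriber = subscriber_actions,
    publisher = publisher_actions
  )
  if (action %in% allowed_set) {
    portal_log(portal, stage, "allow", paste0(action, ": ", role, " ", u$email))
    list(allowed = TRUE, reason = role)
  } else {
    deny(paste0("role ", role, " may not ", action))
  }
}

#' Users table
#' @param portal A `portal`.
#' @return Tibble of accounts: email, approved, admin.
#' @export
portal_users_tbl <- function(portal) {
  us <- portal$users
  tibble::tibble(
    email = vapply(us, function(u) u$email, ""),
    approved = vapply(us, function(u) isTRUE(u$approved), TRUE),
    admin = vapply(us, function(u) isTRUE(u$admin), TRUE)
  )
}
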