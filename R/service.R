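#' Dispatch an HTTP-style request against a portal
#'
#' The service surface of the portal as a pure function: it takes a
#' method, URL path, query parameters and body and returns the status,
#' content type and body the HTTP layer should send. All tracker, feed
#' and admin endpoints go through here; [portal_serve()] is a thin socket
#' loop around it and tests drive it directly.
#'
#' Routes (token always travels as a path segment):
#' \itemize{
#'   \item `GET /health` — liveness probe, JSON.
#'   \item `GET /:token/announce` — tracker announce (standard query
#'     parameters: `info_hash`, `peer_id`, `port`, `uploaded`,
#'     `downloaded`, `left`, `event`, `compact`); bencoded body.
#'   \item `GET /:token/scrape?info_hash=...` — bencoded scrape.
#'   \item `GET /:token/feeds/:id.rss` — the user's RSS document.
#'   \item `GET /:token/feeds/:id/torrents/:hex.torrent` — tokenized
#'     .torrent download.
#'   \item `GET /:token/feeds/:id/status` — dashboard rows, JSON.
#'   \item `POST /:token/feeds/:id/torrents` — publish (body = raw
#'     torrent bytes).
#'   \item `POST /:token/admin/approve?email=` /
#'     `POST /:token/admin/grant?email=&feed=&role=` — admin actions,
#'     JSON.
#' }
#'
#' @param portal A `portal`.
#' @param method `"GET"` or `"POST"`.
#' @param path URL path.
#' @param query Named list of query parameters.
#' @param body Raw vector (POST bodies).
#' @param scheme `"http"` or `"https"`; interacts with the portal's
#'   `require_https` flag for all token-authenticated routes.
#' @param client_ip Observed client address (fills the announce `ip`
#'   default).
#' @return A list: `status` (integer), `content_type`, `body` (raw).
#' @export
portal_handle_request <- function(portal, method, path, query = list(),
                                  body = raw(0), scheme = "https",
                                  client_ip = "127.0.0.1") {
  res <- function(status, content_type, payload) {
    if (is.character(payload)) payload <- charToRaw(paste(payload, collapse = "\n"))
    list(status = as.integer(status), content_type = content_type, body = payload)
  }
  jres <- function(status, obj) {
    res(status, "application/json",
        jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null"))
  }

  if (method == "GET" && path == "/health") {
    return(jres(200L, list(status = "ok", feeds = length(portal$feeds),
                           swarms = length(portal$swarms))))
  }

  seg <- strsplit(sub("^/", "", path), "/", fixed = TRUE)[[1L]]
  if (length(seg) < 2L) return(jres(404L, list(error = "not found")))
  token <- utils::URLdecode(seg[1L])

  if (isTRUE(portal$config$require_https) && !identical(scheme, "https")) {
    return(jres(403L, list(error = "secure channel required")))
  }

  if (method == "GET" && seg[2L] == "announce" && length(seg) == 2L) {
    if (!is.null(query$ip)) client_ip <- query$ip
    query$ip <- client_ip
    ans <- tracker_announce(portal, token, query, scheme = scheme)
    return(res(ans$http_status, "text/plain", ans$body))
  }

  if (method == "GET" && seg[2L] == "scrape" && length(seg) == 2L) {
    hashes <- query[names(query) == "info_hash"]
    ans <- tracker_scrape(portal, token, hashes, scheme = scheme)
    return(res(ans$http_status, "text/plain", ans$body))
  }

  if (seg[2L] == "feeds" && length(seg) >= 3L) {
    if (method == "GET" && length(seg) == 3L && grepl("\\.rss$", seg[3L])) {
      feed_id <- sub("\\.rss$", "", seg[3L])
      out <- tryCatch(feed_rss(portal, feed_id, token),
                      error = function(e) e)
      if (inherits(out, "error")) return(jres(403L, list(error = conditionMessage(out))))
      return(res(200L, "application/rss+xml", out))
    }
    if (method == "GET" && length(seg) == 5L && seg[4L] == "torrents" &&
        grepl("\\.torrent$", seg[5L])) {
      hex <- sub("\\.torrent$", "", seg[5L])
      out <- tryCatch(feed_download_torrent(portal, seg[3L], hex, token),
                      error = function(e) e)
      if (inherits(out, "error")) {
        status <- if (grepl("no such torrent", conditionMessage(out))) 404L else 403L
        return(jres(status, list(error = conditionMessage(out))))
      }
      return(res(200L, "application/x-bittorrent", out))
    }
    if (method == "GET" && length(seg) == 4L && seg[4L] == "status") {
      out <- tryCatch(swarm_status(portal, seg[3L], token), error = function(e) e)
      if (inherits(out, "error")) return(jres(403L, list(error = conditionMessage(out))))
      return(jres(200L, list(peers = out)))
    }
    if (method == "POST" && length(seg) == 4L && seg[4L] == "torrents") {
      out <- tryCatch(feed_publish(portal, seg[3L], body, token), error = function(e) e)
      if (inherits(out, "error")) {
        status <- if (grepl("already published|already registered", conditionMessage(out))) 409L else 403L
        return(jres(status, list(error = conditionMessage(out))))
      }
      return(jres(201L, list(info_hash = out)))
    }
  }

  if (method == "POST" && seg[2L] == "admin" && length(seg) == 3L) {
    u <- portal_user_by_token(portal, token)
    dec <- portal_authorize(portal, token, NA, "manage_users")
    action <- seg[3L]
    if (action == "approve") {
      if (!dec$allowed) return(jres(403L, list(error = dec$reason)))
      out <- tryCatch(portal_approve_user(portal, u$email, query$email), error = function(e) e)
      if (inherits(out, "error")) return(jres(400L, list(error = conditionMessage(out))))
      return(jres(200L, list(approved = query$email)))
    }
    if (action == "grant") {
      # publishers may grant on their feeds; portal_grant_role enforces
      if (is.null(u) || !isTRUE(u$approved)) return(jres(403L, list(error = "unauthorized")))
      out <- tryCatch(
        portal_grant_role(portal, u$email, query$email, query$feed, query$role),
        error = function(e) e)
      if (inherits(out, "error")) return(jres(403L, list(error = conditionMessage(out))))
      return(jres(200L, out))
    }
    if (action == "rotate") {
      if (is.null(u) || !isTRUE(u$approved)) return(jres(403L, list(error = "unauthorized")))
      target <- query$email %||% u$email
      if (!identical(target, u$email) && !dec$allowed) {
        return(jres(403L, list(error = "only administrators rotate other users' tokens")))
      }
      return(jres(200L, list(token = portal_rotate_token(portal, target))))
    }
  }

  jres(404L, list(error = "not found"))
}

#' Serve a portal over HTTP
#'
#' A minimal blocking HTTP/1.0 loop on a base-R server socket, handling
#' one request per connection and dispatching each to
#' [portal_handle_request()]. Intended for demonstrations and local
#' deployments; put a TLS-terminating proxy in front of it in any real
#' setting (and set `require_https` so the portal refuses tokens on plain
#' HTTP).
#'
#' @param portal A `portal`.
#' @param port TCP port to listen on.
#' @param max_requests Stop after this many requests (`Inf` to run
#'   forever); mainly for scripted smoke tests.
#' @param scheme Scheme to report to the router for arriving requests
#'   (`"http"` unless a proxy guarantees TLS).
#' @return Invisibly, the number of requests served.
#' @export
portal_serve <- function(portal, port = 6969L, max_requests = Inf, scheme = "http") {
  srv <- serverSocket(port)
  on.exit(close(srv), add = TRUE)
  served <- 0
  while (served < max_requests) {
    con <- socketAccept(srv, blocking = TRUE, open = "r+b", timeout = 10)
    served <- served + 1
    try({
      req_line <- readLines(con, n = 1L)
      headers <- character(0)
      repeat {
        l <- readLines(con, n = 1L)
        if (length(l) == 0L || l == "") break
        headers <- c(headers, l)
      }
      clen <- 0L
      cl <- grep("^content-length:", headers, ignore.case = TRUE, value = TRUE)
      if (length(cl)) clen <- as.integer(trimws(sub("^[^:]*:", "", cl[1L])))
      body <- if (clen > 0L) readBin(con, "raw", n = clen) else raw(0)
      parts <- strsplit(req_line, " ", fixed = TRUE)[[1L]]
      method <- parts[1L]
      target <- parts[2L]
      split_q <- strsplit(target, "?", fixed = TRUE)[[1L]]
      path <- split_q[1L]
      query <- list()
      if (length(split_q) > 1L) {
        for (kv in strsplit(split_q[2L], "&", fixed = TRUE)[[1L]]) {
          p <- strsplit(kv, "=", fixed = TRUE)[[1L]]
          query[[length(query) + 1L]] <- utils::URLdecode(p[2L] %||% "")
          names(query)[length(query)] <- utils::URLdecode(p[1L])
        }
      }
      ans <- portal_handle_request(portal, method, path, query, body, scheme = scheme)
      status_text <- c(`200` = "OK", `201` = "Created", `400` = "Bad Request",
                       `401` = "Unauthorized", `403` = "Forbidden",
                       `404` = "Not Found", `409` = "Conflict")[as.character(ans$status)]
      head <- paste0("HTTP/1.0 ", ans$status, " ", status_text %||% "", "\r\n",
                     "Content-Type: ", ans$content_type, "\r\n",
                     "Content-Length: ", length(ans$body), "\r\n",
                     "Connection: close\r\n\r\n")
      writeBin(c(charToRaw(head), ans$body), con)
      flush(con)
    }, silent = TRUE)
    close(con)
  }
  invisible(served)
}

#' Read and write swarm-simulation configs as YAML
#'
#' The on-disk form mirrors [sim_config()]: `piece_count`, `tick_limit`,
#' `seed`, a `nodes` list (each with `id`, `role`, `seed`, `down`, `up`)
#' and an optional `churn` list (each with `tick`, `id`, `online`).
#'
#' @param path YAML file path.
#' @return `sim_config_read()`: a `sim_config`.
#' @export
sim_config_read <- function(path) {
  y <- yaml::read_yaml(path)
  nodes <- do.call(rbind, lapply(y$nodes, function(n) {
    data.frame(id = as.character(n$id), role = n$role, seed = isTRUE(n$seed),
               down = as.numeric(n$down), up = as.numeric(n$up))
  }))
  churn <- if (!is.null(y$churn)) {
    do.call(rbind, lapply(y$churn, function(e) {
      data.frame(tick = as.integer(e$tick), id = as.character(e$id),
                 online = isTRUE(e$online))
    }))
  }
  sim_config(y$piece_count, nodes, churn = churn,
             tick_limit = y$tick_limit %||% (10L * y$piece_count),
             seed = y$seed %||% 1L)
}

#' @rdname sim_config_read
#' @param config A `sim_config`.
#' @export
sim_config_write <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  y <- list(
    piece_count = config$piece_count,
    tick_limit = config$tick_limit,
    seed = config$seed,
    nodes = lapply(seq_len(nrow(config$nodes)), function(i) {
      as.list(config$nodes[i, c("id", "role", "seed", "down", "up")])
    })
  )
  if (!is.null(config$churn)) {
    y$churn <- lapply(seq_len(nrow(config$churn)), function(i) {
      as.list(config$churn[i, c("tick", "id", "online")])
    })
  }
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Export a simulation trace
#'
#' Writes the transfer log, completion table and availability timeline of
#' a [swarm_simulate()] run as CSV files under a common prefix, plus a
#' one-line JSON summary.
#'
#' @param trace A `sim_trace`.
#' @param prefix Output path prefix (files `<prefix>_transfers.csv`,
#'   `<prefix>_completion.csv`, `<prefix>_availability.csv`,
#'   `<prefix>_summary.json`).
#' @return Invisibly, the paths written.
#' @export
sim_trace_export <- function(trace, prefix) {
  stopifnot(inherits(trace, "sim_trace"))
  paths <- c(
    transfers = paste0(prefix, "_transfers.csv"),
    completion = paste0(prefix, "_completion.csv"),
    availability = paste0(prefix, "_availability.csv"),
    summary = paste0(prefix, "_summary.json")
  )
  utils::write.csv(trace$transfers, paths["transfers"], row.names = FALSE)
  utils::write.csv(trace$completion, paths["completion"], row.names = FALSE)
  utils::write.csv(trace$availability, paths["availability"], row.names = FALSE)
  jsonlite::write_json(list(
    completed_all = trace$completed_all,
    ticks_run = trace$ticks_run,
    transfers = nrow(trace$transfers),
    unrecoverable = trace$unrecoverable
  ), paths["summary"], auto_unbox = TRUE)
  invisible(paths)
}
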