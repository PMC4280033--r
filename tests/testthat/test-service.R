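test_that("the request router serves health, announce, RSS and downloads end-to-end", {
  w <- build_world()
  p <- w$portal
  tok <- w$users$sub$token
  h <- unname(w$hashes["a"])

  health <- portal_handle_request(p, "GET", "/health")
  expect_equal(health$status, 200L)
  expect_equal(jsonlite::fromJSON(rawToChar(health$body))$status, "ok")

  ann <- portal_handle_request(p, "GET", paste0("/", tok, "/announce"),
                               query = list(info_hash = h, peer_id = strrep("r", 20),
                                            port = "6881", left = "0"))
  expect_equal(ann$status, 200L)
  expect_equal(bdecode(ann$body)$complete, 1)

  rss <- portal_handle_request(p, "GET", paste0("/", tok, "/feeds/", w$feeds["a"], ".rss"))
  expect_equal(rss$status, 200L)
  expect_equal(rss$content_type, "application/rss+xml")
  doc <- xml2::read_xml(rawToChar(rss$body))
  url <- xml2::xml_attr(xml2::xml_find_first(doc, "//enclosure"), "url")
  # follow the enclosure URL through the router and get a loadable torrent
  path <- sub("^https://portal.example/bt", "", url)
  dl <- portal_handle_request(p, "GET", path)
  expect_equal(dl$status, 200L)
  expect_identical(format(info_hash(dl$body)), h)

  status <- portal_handle_request(p, "GET", paste0("/", tok, "/feeds/", w$feeds["a"], "/status"))
  peers <- jsonlite::fromJSON(rawToChar(status$body))$peers
  expect_equal(peers$completion_pct, 100)

  scrape <- portal_handle_request(p, "GET", paste0("/", tok, "/scrape"),
                                  query = list(info_hash = h))
  expect_equal(bdecode(scrape$body)$files[[h]]$complete, 1)
})

test_that("the router denies invalid tokens and honors the secure-channel flag", {
  w <- build_world()
  p <- w$portal
  h <- unname(w$hashes["a"])
  bad <- portal_handle_request(p, "GET", "/bogus-token/announce",
                               query = list(info_hash = h, peer_id = strrep("r", 20),
                                            port = "6881", left = "0"))
  expect_equal(bad$status, 401L)
  expect_equal(rawToChar(bdecode(bad$body)$`failure reason`), "unauthorized")

  rss <- portal_handle_request(p, "GET", paste0("/", w$users$none$token,
                                                "/feeds/", w$feeds["a"], ".rss"))
  expect_equal(rss$status, 403L)

  expect_equal(portal_handle_request(p, "GET", "/nowhere")$status, 404L)

  p$config$require_https <- TRUE
  tok <- w$users$sub$token
  plain <- portal_handle_request(p, "GET", paste0("/", tok, "/feeds/", w$feeds["a"], ".rss"),
                                 scheme = "http")
  expect_equal(plain$status, 403L)
  tls <- portal_handle_request(p, "GET", paste0("/", tok, "/feeds/", w$feeds["a"], ".rss"),
                               scheme = "https")
  expect_equal(tls$status, 200L)
})

test_that("publishing and admin actions work through the router", {
  w <- build_world()
  p <- w$portal
  dir <- withr::local_tempdir()
  f <- file.path(dir, "up.bin")
  fx <- fixture_payload(f, 32 * 1024, seed = 401,
                        announce = "http://up.example/a", piece_length = 16384)
  pub <- portal_handle_request(p, "POST",
                               paste0("/", w$users$pub$token, "/feeds/", w$feeds["a"], "/torrents"),
                               body = torrent_bytes(fx$torrent))
  expect_equal(pub$status, 201L)
  hex <- jsonlite::fromJSON(rawToChar(pub$body))$info_hash
  expect_equal(hex, format(info_hash(torrent_privatize(fx$torrent))))
  # duplicate -> 409; subscriber -> 403
  expect_equal(portal_handle_request(p, "POST",
    paste0("/", w$users$pub$token, "/feeds/", w$feeds["a"], "/torrents"),
    body = torrent_bytes(fx$torrent))$status, 409L)
  expect_equal(portal_handle_request(p, "POST",
    paste0("/", w$users$sub$token, "/feeds/", w$feeds["a"], "/torrents"),
    body = torrent_bytes(fx$torrent))$status, 403L)

  # admin approve + grant + rotate flow
  adm <- portal_admin_token(p)
  nu <- portal_register_user(p, "late@example.org", "pw")
  expect_equal(portal_handle_request(p, "POST", paste0("/", adm, "/admin/approve"),
                                     query = list(email = "late@example.org"))$status, 200L)
  expect_equal(portal_handle_request(p, "POST", paste0("/", adm, "/admin/grant"),
                                     query = list(email = "late@example.org",
                                                  feed = as.character(w$feeds["a"]),
                                                  role = "subscriber"))$status, 200L)
  rss <- portal_handle_request(p, "GET", paste0("/", nu$token, "/feeds/", w$feeds["a"], ".rss"))
  expect_equal(rss$status, 200L)
  # non-admin cannot approve
  expect_equal(portal_handle_request(p, "POST",
    paste0("/", w$users$sub$token, "/admin/approve"),
    query = list(email = "late@example.org"))$status, 403L)
  # rotation through the router invalidates the old token
  rot <- portal_handle_request(p, "POST", paste0("/", nu$token, "/admin/rotate"))
  expect_equal(rot$status, 200L)
  old_rss <- portal_handle_request(p, "GET", paste0("/", nu$token, "/feeds/", w$feeds["a"], ".rss"))
  expect_equal(old_rss$status, 403L)
  new_tok <- jsonlite::fromJSON(rawToChar(rot$body))$token
  expect_equal(portal_handle_request(p, "GET",
    paste0("/", new_tok, "/feeds/", w$feeds["a"], ".rss"))$status, 200L)
})

test_that("the command-line tool creates, verifies and simulates", {
  cli <- system.file("exec", "torrentools", package = "torrentools")
  expect_true(nzchar(cli) && file.exists(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  dir <- withr::local_tempdir()
  f <- file.path(dir, "cli.bin")
  fixture_payload(f, 64 * 1024, seed = 501)
  tor <- file.path(dir, "cli.torrent")

  out <- system2(rscript, c(cli, "create-torrent", f,
                            "--announce", "http://tr.example/a",
                            "--piece-size", "16384", "-o", tor),
                 stdout = TRUE, stderr = TRUE)
  expect_equal(attr(out, "status") %||% 0L, 0L)
  expect_true(file.exists(tor))
  tt <- torrent_read(tor)
  expect_equal(as.numeric(tt$info$`piece length`), 16384)

  ver <- system2(rscript, c(cli, "verify", tor, f), stdout = TRUE, stderr = TRUE)
  expect_equal(attr(ver, "status") %||% 0L, 0L)
  expect_match(paste(ver, collapse = "\n"), "100.0%")

  # failure paths exit nonzero with a single-line error
  bad <- suppressWarnings(
    system2(rscript, c(cli, "create-torrent", file.path(dir, "missing.bin"),
                       "--announce", "http://tr.example/a", "-o", tor),
            stdout = TRUE, stderr = TRUE))
  expect_false(identical(attr(bad, "status") %||% 0L, 0L))
  expect_match(paste(bad, collapse = "\n"), "error:")

  # simulate from a YAML config, deterministic across reruns
  cfgp <- file.path(dir, "sim.yaml")
  nodes <- data.frame(id = c("n1", "n2"), role = c("publisher", "subscriber"),
                      seed = c(TRUE, FALSE), down = 1, up = 1)
  sim_config_write(sim_config(6, nodes, tick_limit = 50L), cfgp)
  s1 <- system2(rscript, c(cli, "simulate", cfgp, "-o", file.path(dir, "run1")),
                stdout = TRUE, stderr = TRUE)
  expect_equal(attr(s1, "status") %||% 0L, 0L)
  s2 <- system2(rscript, c(cli, "simulate", cfgp, "-o", file.path(dir, "run2")),
                stdout = TRUE, stderr = TRUE)
  expect_identical(readLines(file.path(dir, "run1_transfers.csv")),
                   readLines(file.path(dir, "run2_transfers.csv")))
})

test_that("the socket server answers a live health probe", {
  rscript <- file.path(R.home("bin"), "Rscript")
  port <- 49000 + (Sys.getpid() %% 1000)
  srv <- sprintf(
    "library(torrentools); p <- portal_create(); portal_serve(p, port = %d, max_requests = 1)",
    port)
  proc <- system2(rscript, c("-e", shQuote(srv)), wait = FALSE)
  deadline <- Sys.time() + 15
  body <- NULL
  while (Sys.time() < deadline && is.null(body)) {
    body <- tryCatch({
      con <- suppressWarnings(
        socketConnection("127.0.0.1", port, open = "r+b", blocking = TRUE, timeout = 5))
      writeLines(c("GET /health HTTP/1.0", "", ""), con, sep = "\r\n")
      flush(con)
      resp <- readLines(con, warn = FALSE)
      close(con)
      if (length(resp) == 0) NULL else resp
    }, error = function(e) { Sys.sleep(0.3); NULL })
  }
  expect_false(is.null(body))
  expect_match(body[1], "200")
  expect_match(paste(body, collapse = ""), "\"status\":\"ok\"")
})

test_that("portal state survives a save/load cycle without leaking secrets", {
  w <- build_world()
  p <- w$portal
  dir <- withr::local_tempdir()
  state <- file.path(dir, "portal.json")
  portal_save(p, state)
  # no clear token or password appears in the state file
  txt <- paste(readLines(state, warn = FALSE), collapse = "")
  expect_false(grepl(w$users$sub$token, txt, fixed = TRUE))
  expect_false(grepl("sub-pw", txt, fixed = TRUE))

  q <- portal_load(state)
  expect_true(portal_check_password(q, "sub@example.org", "sub-pw"))
  expect_equal(portal_role(q, "sub@example.org", w$feeds["a"]), "subscriber")
  # tokens still resolve and torrents are still served after reload
  expect_true(portal_authorize(q, w$users$sub$token, w$feeds["a"], "fetch_rss")$allowed)
  dl <- feed_download_torrent(q, w$feeds["a"], w$hashes["a"], w$users$sub$token)
  expect_identical(format(info_hash(dl)), unname(w$hashes["a"]))
  # swarms are ephemeral by design: reload starts with an empty registry
  expect_length(q$swarms, 0L)
})
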