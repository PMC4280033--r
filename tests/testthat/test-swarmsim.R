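make_nodes <- function(n_sub, down = 1, up = 1, pub_up = up) {
  data.frame(
    id = c("n1", sprintf("n%d", seq_len(n_sub) + 1L)),
    role = c("publisher", rep("subscriber", n_sub)),
    seed = c(TRUE, rep(FALSE, n_sub)),
    down = down, up = c(pub_up, rep(up, n_sub))
  )
}

test_that("aggregate availability equals the union over online nodes", {
  bf <- list(c(TRUE, FALSE, TRUE, TRUE, FALSE), c(FALSE, TRUE, FALSE, FALSE, TRUE))
  av <- availability(bf)
  expect_true(av$complete)
  expect_length(av$missing, 0L)

  # all nodes missing piece 3 (0-based)
  bf2 <- list(c(TRUE, TRUE, TRUE, FALSE, TRUE), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  av2 <- availability(bf2)
  expect_false(av2$complete)
  expect_true(3L %in% av2$missing)

  # offline nodes do not contribute
  av3 <- availability(bf, online = c(TRUE, FALSE))
  expect_false(av3$complete)
  expect_equal(av3$missing, c(1L, 4L))

  expect_error(availability(list(c(TRUE), c(TRUE, FALSE))), "same length")
})

test_that("availability agrees with a brute-force per-piece OR oracle on random 8x64 bitfields", {
  set.seed(4242)
  for (rep in 1:20) {
    bf <- lapply(1:8, function(i) sample(c(TRUE, FALSE), 64, replace = TRUE, prob = c(.3, .7)))
    online <- sample(c(TRUE, FALSE), 8, replace = TRUE)
    if (!any(online)) online[1] <- TRUE
    # independent naive oracle: loop piece by piece, node by node
    oracle_missing <- integer(0)
    for (piece in 1:64) {
      held <- FALSE
      for (node in 1:8) if (online[node] && bf[[node]][piece]) held <- TRUE
      if (!held) oracle_missing <- c(oracle_missing, piece - 1L)
    }
    av <- availability(bf, online)
    expect_equal(av$missing, oracle_missing)
    expect_equal(av$complete, length(oracle_missing) == 0L)
  }
})

test_that("a single seeder feeding one leecher at 1 piece/tick finishes in piece_count ticks", {
  cfg <- sim_config(10, make_nodes(1))
  tr <- swarm_simulate(cfg)
  expect_true(tr$completed_all)
  leech <- tr$completion[tr$completion$node == "n2", ]
  expect_equal(leech$tick, 10L)
  expect_equal(nrow(tr$transfers), 10L)
  # monotone ownership: every transferred piece is distinct
  expect_equal(anyDuplicated(tr$transfers$piece), 0L)
})

test_that("eight nodes with scheduled single-node outages all complete", {
  # 1 publisher seeding + 7 subscribers; one subscriber at a time drops out
  # and returns, availability never breaks (the publisher stays up)
  churn <- do.call(rbind, lapply(1:5, function(k) {
    id <- sprintf("n%d", k + 1L)
    data.frame(tick = c(3L * k, 3L * k + 4L), id = id, online = c(FALSE, TRUE))
  }))
  cfg <- sim_config(16, make_nodes(7, down = 2, up = 2, pub_up = 4), churn = churn,
                    tick_limit = 400L)
  expect_false(cfg$unrecoverable)
  tr <- swarm_simulate(cfg)
  expect_true(tr$completed_all)
  expect_true(all(tr$availability$complete))
  subs <- tr$completion[tr$completion$role == "subscriber", ]
  expect_true(all(!is.na(subs$tick)))
  expect_true(all(vapply(tr$final_bitfields[subs$node], all, TRUE)))
})

test_that("the publisher can be taken offline for good once a dedicated node holds a copy", {
  nodes <- data.frame(
    id = c("pub", "ded", "s1", "s2"),
    role = c("publisher", "dedicated", "subscriber", "subscriber"),
    seed = c(TRUE, FALSE, FALSE, FALSE),
    down = c(0, 4, 1, 1), up = c(4, 4, 1, 1)
  )
  pieces <- 12L
  # dedicated node downloads everything first, then the publisher vanishes
  warm <- ceiling(pieces / 4) + 1L
  churn <- data.frame(tick = warm, id = "pub", online = FALSE)
  cfg <- sim_config(pieces, nodes, churn = churn, tick_limit = 200L)
  tr <- swarm_simulate(cfg)
  expect_true(tr$completed_all)
  # the publisher really was gone: no transfers from it after the cutoff
  late <- tr$transfers[tr$transfers$tick >= warm, ]
  expect_false("pub" %in% late$from)
  expect_true(all(vapply(tr$final_bitfields[c("ded", "s1", "s2")], all, TRUE)))
})

test_that("identical configurations produce identical traces", {
  churn <- data.frame(tick = c(4L, 8L), id = c("n3", "n3"), online = c(FALSE, TRUE))
  cfg1 <- sim_config(20, make_nodes(3, down = 2, up = 2), churn = churn, tick_limit = 100L)
  cfg2 <- sim_config(20, make_nodes(3, down = 2, up = 2), churn = churn, tick_limit = 100L)
  tr1 <- swarm_simulate(cfg1)
  tr2 <- swarm_simulate(cfg2)
  expect_identical(tr1$transfers, tr2$transfers)
  expect_identical(tr1$completion, tr2$completion)
  expect_identical(tr1$final_bitfields, tr2$final_bitfields)
})

test_that("safety: continuous aggregate availability implies all subscribers complete", {
  set.seed(777)
  for (rep in 1:6) {
    n_sub <- sample(3:6, 1L)
    nodes <- make_nodes(n_sub, down = sample(1:3, 1L), up = 2, pub_up = 3)
    # random churn on subscribers only; the seeding publisher stays online so
    # the aggregate always covers all pieces, and every outage is paired with
    # a later return so each subscriber can eventually finish
    outages <- lapply(sample(seq_len(n_sub), sample(1:3, 1L)), function(k) {
      off <- sample(1:20, 1L)
      data.frame(tick = c(off, off + sample(2:6, 1L)),
                 id = sprintf("n%d", k + 1L), online = c(FALSE, TRUE))
    })
    churn <- do.call(rbind, outages)
    cfg <- sim_config(sample(8:24, 1L), nodes, churn = churn, tick_limit = 500L)
    tr <- swarm_simulate(cfg)
    expect_true(all(tr$availability$complete))
    expect_true(tr$completed_all)
  }
})

test_that("a piece absent from every node blocks completion and is flagged unrecoverable", {
  nodes <- data.frame(id = c("a", "b"), role = c("publisher", "subscriber"),
                      seed = FALSE, down = 2, up = 2)
  bf <- list(a = c(TRUE, TRUE, FALSE, TRUE), b = c(TRUE, FALSE, FALSE, FALSE))
  cfg <- sim_config(4, nodes, bitfields = bf, tick_limit = 50L)
  expect_true(cfg$unrecoverable)
  expect_equal(cfg$missing_at_start, 2L)
  tr <- swarm_simulate(cfg) # reported in the trace, not raised
  expect_false(tr$completed_all)
  expect_false(tr$final_bitfields$b[3])
})

test_that("piece conservation: every transfer's provider held the piece at that tick", {
  churn <- data.frame(tick = c(3L, 6L), id = c("n2", "n2"), online = c(FALSE, TRUE))
  cfg <- sim_config(15, make_nodes(3, down = 2, up = 2), churn = churn, tick_limit = 200L)
  tr <- swarm_simulate(cfg)
  # replay the trace against an independently maintained ownership ledger
  own <- lapply(cfg$bitfields, identity)
  last_tick <- 0L
  pending <- list()
  for (i in seq_len(nrow(tr$transfers))) {
    row <- tr$transfers[i, ]
    if (row$tick > last_tick) { # apply previous tick's arrivals
      for (tx in pending) own[[tx$to]][tx$piece + 1L] <- TRUE
      pending <- list()
      last_tick <- row$tick
    }
    expect_true(own[[row$from]][row$piece + 1L],
                label = sprintf("tick %d: %s held piece %d", row$tick, row$from, row$piece))
    pending[[length(pending) + 1L]] <- row
  }
})

test_that("storage-per-device arithmetic and unit conventions", {
  expect_equal(storage_per_device(gib(1), 2, 1), 0.5)
  expect_error(storage_per_device(gib(1), 0, 0.5), "device_count")
  expect_error(storage_per_device(gib(1), 10, 0), "participation")
  expect_error(storage_per_device(gib(1), 10, 1.5), "participation")
  # a 40 PB archive over half of ~2.9M devices lands near 26 (decimal PB)
  # or 29 GiB (binary PB) per device
  expect_equal(storage_per_device(pb(40), 2883000, 0.5), 40e15 / 1441500 / 2^30)
  expect_equal(storage_per_device(pb(40, binary = TRUE), 2883000, 0.5),
               40 * 2^50 / 1441500 / 2^30)
})

test_that("fixtures are reproducible by seed and verify completely", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "s1.bin"); f2 <- file.path(dir, "s2.bin"); f3 <- file.path(dir, "s3.bin")
  a <- fixture_payload(f1, 100000, seed = 9, announce = "http://t.example/a", piece_length = 16384)
  b <- fixture_payload(f2, 100000, seed = 9, announce = "http://t.example/a", piece_length = 16384)
  c <- fixture_payload(f3, 100000, seed = 10, announce = "http://t.example/a", piece_length = 16384)
  expect_identical(a$info_hash, b$info_hash)
  expect_false(identical(a$info_hash, c$info_hash))
  expect_identical(readBin(f1, "raw", 100000), readBin(f2, "raw", 100000))
  expect_equal(torrent_verify(a$torrent, f1)$completion_fraction, 1.0)
})

test_that("simulation configs round-trip through YAML", {
  dir <- withr::local_tempdir()
  churn <- data.frame(tick = 5L, id = "n2", online = FALSE)
  cfg <- sim_config(12, make_nodes(2, down = 2, up = 1), churn = churn,
                    tick_limit = 99L, seed = 7L)
  path <- file.path(dir, "sim.yaml")
  sim_config_write(cfg, path)
  back <- sim_config_read(path)
  expect_equal(back$piece_count, cfg$piece_count)
  expect_equal(back$tick_limit, 99L)
  expect_equal(back$seed, 7L)
  expect_equal(back$nodes$id, cfg$nodes$id)
  expect_equal(back$churn$tick, 5L)
  expect_identical(swarm_simulate(back)$transfers, swarm_simulate(cfg)$transfers)
})
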