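#' Aggregate piece availability across online nodes
#'
#' A payload can be downloaded to completion by any current or future node
#' as long as every piece exists somewhere on the aggregate of *online*
#' nodes — no single machine needs a full copy. This computes that union.
#'
#' @param bitfields A list of logical vectors (or a logical matrix, nodes
#'   in rows), all the same length: per-node piece ownership.
#' @param online Logical vector, one per node; defaults to all online.
#' @return A list: `complete` (is the union all-ones?) and `missing`
#'   (0-based indices of pieces held by no online node).
#' @export
availability <- function(bitfields, online = NULL) {
  if (is.matrix(bitfields)) bitfields <- lapply(seq_len(nrow(bitfields)), function(i) bitfields[i, ])
  stopifnot(is.list(bitfields), length(bitfields) > 0L)
  len <- unique(vapply(bitfields, length, 1L))
  if (length(len) != 1L) stop("availability: bitfields must all have the same length")
  if (is.null(online)) online <- rep(TRUE, length(bitfields))
  stopifnot(length(online) == length(bitfields))
  u <- rep(FALSE, len)
  for (i in which(online)) u <- u | bitfields[[i]]
  list(complete = all(u), missing = which(!u) - 1L)
}

#' Build a swarm-simulation configuration
#'
#' Describes a discrete-tick piece-exchange experiment: a torrent with
#' `piece_count` pieces, a set of nodes with initial bitfields, per-tick
#' transfer capacities and role labels, and a churn schedule of
#' offline/online transitions. The configuration is validated: if at tick
#' 0 the online nodes' bitfields do not jointly cover all pieces, the
#' scenario is flagged `unrecoverable` (it can never complete, whatever
#' the schedule does later cannot conjure missing pieces from thin air —
#' the run still executes so the failure mode can be studied).
#'
#' @param piece_count Number of pieces in the simulated torrent.
#' @param nodes A data frame with one row per node: `id` (unique),
#'   `role` (`"publisher"`, `"subscriber"` or `"dedicated"`), `seed`
#'   (logical: starts with a full bitfield), `down` and `up` (piece/tick
#'   capacities, >= 0). Nodes not seeding start empty unless
#'   `bitfields` supplies them.
#' @param churn Optional data frame of scheduled transitions: `tick`,
#'   `id`, `online` (logical). Applied at the start of the given tick.
#' @param tick_limit Maximum ticks to run.
#' @param seed RNG seed recorded with the config (the exchange rules
#'   themselves are deterministic; the seed feeds payload/fixture
#'   generation when the config is bound to one).
#' @param bitfields Optional named list (by node id) of initial logical
#'   bitfields overriding `seed`.
#' @return A `sim_config` object.
#' @export
sim_config <- function(piece_count, nodes, churn = NULL, tick_limit = 10 * piece_count,
                       seed = 1L, bitfields = NULL) {
  stopifnot(piece_count >= 1, is.data.frame(nodes))
  nodes <- as.data.frame(nodes)
  req <- c("id", "role", "seed", "down", "up")
  if (!all(req %in% names(nodes))) stop("sim_config: nodes needs columns ", paste(req, collapse = ", "))
  if (anyDuplicated(nodes$id)) stop("sim_config: duplicate node ids")
  if (any(nodes$down < 0 | nodes$up < 0)) stop("sim_config: capacities must be >= 0")
  if (!all(nodes$role %in% c("publisher", "subscriber", "dedicated"))) {
    stop("sim_config: roles must be publisher/subscriber/dedicated")
  }
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  bf <- lapply(seq_len(nrow(nodes)), function(i) {
    id <- as.character(nodes$id[i])
    if (!is.null(bitfields) && !is.null(bitfields[[id]])) {
      v <- as.logical(bitfields[[id]])
      if (length(v) != piece_count) stop("sim_config: bitfield length mismatch for node ", id)
      v
    } else {
      rep(isTRUE(nodes$seed[i]), piece_count)
    }
  })
  names(bf) <- as.character(nodes$id)
  if (!is.null(churn)) {
    churn <- as.data.frame(churn)
    if (!all(c("tick", "id", "online") %in% names(churn))) {
      stop("sim_config: churn needs columns tick, id, online")
    }
    if (!all(as.character(churn$id) %in% names(bf))) stop("sim_config: churn references unknown node")
  }
  avail0 <- availability(bf)
  structure(list(
    piece_count = as.integer(piece_count),
    nodes = nodes,
    bitfields = bf,
    churn = churn,
    tick_limit = as.integer(tick_limit),
    seed = as.integer(seed),
    unrecoverable = !avail0$complete,
    missing_at_start = avail0$missing
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config: ", x$piece_count, " pieces, ", nrow(x$nodes), " nodes, tick limit ",
      x$tick_limit, if (x$unrecoverable) ", UNRECOVERABLE" else "", ">\n", sep = "")
  invisible(x)
}

#' Run the deterministic swarm simulation
#'
#' Time advances in discrete ticks. At the start of each tick the churn
#' schedule is applied; then every online node that is missing pieces
#' requests, from the snapshot of what online peers held at the start of
#' the tick, its rarest missing piece (rarity = number of online holders),
#' breaking ties by lowest piece index and then lowest provider id.
#' Transfers consume one unit of the requester's download capacity and the
#' provider's upload capacity; acquired pieces become visible to others at
#' the next tick. The run stops when every subscriber (and dedicated) node
#' holds a full bitfield, or at the tick limit. Given the same
#' configuration the trace is identical — the exchange rules consume no
#' randomness.
#'
#' @param config A `sim_config`.
#' @return A `sim_trace`: list with `transfers` (tibble: tick, from, to,
#'   piece), `completion` (tibble: node, role, tick of completion, NA if
#'   never), `availability` (tibble per tick: union complete?),
#'   `final_bitfields` (named list), `completed_all` (did every
#'   subscriber/dedicated node finish?), `ticks_run`.
#' @export
swarm_simulate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  bf <- config$bitfields
  ids <- names(bf)
  nodes <- config$nodes
  online <- rep(TRUE, length(ids))
  names(online) <- ids
  completion <- rep(NA_integer_, length(ids))
  names(completion) <- ids
  for (id in ids) if (all(bf[[id]])) completion[id] <- 0L

  transfers <- list()
  avail_rows <- list()
  want_ids <- ids[nodes$role %in% c("subscriber", "dedicated")]

  tick <- 0L
  while (tick < config$tick_limit) {
    tick <- tick + 1L
    if (!is.null(config$churn)) {
      ev <- config$churn[config$churn$tick == tick, , drop = FALSE]
      for (j in seq_len(nrow(ev))) online[[as.character(ev$id[j])]] <- isTRUE(ev$online[j])
    }
    snapshot <- bf # piece visibility frozen at tick start
    on_ids <- ids[online]
    av <- availability(snapshot[ids], online)
    avail_rows[[tick]] <- tibble::tibble(tick = tick, complete = av$complete,
                                         n_online = length(on_ids))
    if (length(on_ids) >= 1L) {
      # per-piece count of online holders, from the snapshot
      holders <- matrix(FALSE, nrow = length(on_ids), ncol = config$piece_count,
                        dimnames = list(on_ids, NULL))
      for (id in on_ids) holders[id, ] <- snapshot[[id]]
      rarity <- colSums(holders)
      up_left <- stats::setNames(nodes$up[match(on_ids, as.character(nodes$id))], on_ids)
      for (id in on_ids) {
        down_left <- nodes$down[match(id, as.character(nodes$id))]
        while (down_left > 0) {
          missing <- which(!bf[[id]])
          if (length(missing) == 0L) break
          # pieces obtainable: some online provider (not self) holds it in the
          # snapshot and has upload capacity left this tick
          providers_ok <- up_left > 0 & on_ids != id
          if (!any(providers_ok)) break
          obtainable <- missing[rarity[missing] > 0 &
                                  colSums(holders[providers_ok, missing, drop = FALSE]) > 0]
          if (length(obtainable) == 0L) break
          pick <- obtainable[order(rarity[obtainable], obtainable)][1L]
          prov <- on_ids[providers_ok & holders[, pick]][1L]
          if (is.na(prov)) break
          bf[[id]][pick] <- TRUE
          up_left[prov] <- up_left[prov] - 1
          down_left <- down_left - 1
          transfers[[length(transfers) + 1L]] <-
            tibble::tibble(tick = tick, from = prov, to = id, piece = pick - 1L)
          if (all(bf[[id]]) && is.na(completion[id])) completion[id] <- tick
        }
      }
    }
    if (all(!is.na(completion[want_ids]))) break
  }

  structure(list(
    transfers = if (length(transfers)) do.call(rbind, transfers) else
      tibble::tibble(tick = integer(), from = character(), to = character(), piece = integer()),
    completion = tibble::tibble(
      node = ids,
      role = nodes$role[match(ids, as.character(nodes$id))],
      tick = as.integer(completion)
    ),
    availability = if (length(avail_rows)) do.call(rbind, avail_rows) else
      tibble::tibble(tick = integer(), complete = logical(), n_online = integer()),
    final_bitfields = bf,
    completed_all = all(!is.na(completion[want_ids])),
    ticks_run = tick,
    unrecoverable = config$unrecoverable
  ), class = "sim_trace")
}

#' @export
print.sim_trace <- function(x, ...) {
  cat("<sim_trace: ", x$ticks_run, " ticks, ", nrow(x$transfers), " transfers, ",
      if (x$completed_all) "all target nodes complete" else "INCOMPLETE", ">\n", sep = "")
  invisible(x)
}

#' Volunteer storage required per device
#'
#' For a replicated archive spread across volunteer devices: if
#' `total_bytes` must be held collectively by `device_count` devices of
#' which a fraction `participation` actually take part, each participant
#' donates `total_bytes / (device_count * participation)`.
#'
#' Unit conventions matter at these scales: by default petabyte inputs are
#' taken as decimal (1 PB = 10^15 bytes) while the per-device result is
#' reported in binary gibibytes (1 GiB = 2^30 bytes), the way storage
#' vendors and operating systems respectively report sizes; set
#' `binary = TRUE` to interpret everything in powers of two.
#'
#' @param total_bytes Archive size in bytes (use [pb()]/[gib()] helpers).
#' @param device_count Number of devices on the network (> 0).
#' @param participation Fraction of devices participating, in (0, 1].
#' @return Donated storage per device, in GiB.
#' @examples
#' storage_per_device(pb(40), 2883000, 0.5) # ~26 GiB/device
#' @export
storage_per_device <- function(total_bytes, device_count, participation) {
  if (!is.numeric(device_count) || device_count <= 0) stop("storage_per_device: device_count must be > 0")
  if (!is.numeric(participation) || participation <= 0 || participation > 1) {
    stop("storage_per_device: participation must be in (0, 1]")
  }
  participating <- device_count * participation
  if (participating < 1) stop("storage_per_device: fewer than one participating device")
  (total_bytes / participating) / 2^30
}

#' Byte-unit helpers
#' @param x Size in the named unit.
#' @param binary Interpret PB as 2^50 (pebibytes) instead of 10^15.
#' @return Size in bytes.
#' @export
pb <- function(x, binary = FALSE) x * if (binary) 2^50 else 1e15

#' @rdname pb
#' @export
gib <- function(x) x * 2^30

#' @rdname pb
#' @export
mib <- function(x) x * 2^20

#' Generate a reproducible random payload fixture
#'
#' Writes `size` bytes of seeded pseudo-random binary data to `path` and
#' (optionally) builds the matching torrent. The same seed always yields
#' the same bytes, hence the same piece digests and info-hash — different
#' seeds yield different payloads.
#'
#' @param path Output file path.
#' @param size Payload size in bytes (> 0).
#' @param seed Integer seed.
#' @param announce If non-`NULL`, also create a torrent for the payload
#'   with this announce URL.
#' @param piece_length Piece size for the torrent.
#' @return A list: `path`, `size`, `seed`, and when `announce` is given
#'   `torrent` (a `metainfo`) and `info_hash` (hex).
#' @export
fixture_payload <- function(path, size, seed = 1L, announce = NULL,
                            piece_length = 4 * 1048576) {
  stopifnot(size > 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  con <- file(path, "wb")
  left <- size
  chunk <- 1048576
  while (left > 0) {
    n <- min(chunk, left)
    writeBin(as.raw(sample.int(256L, n, replace = TRUE) - 1L), con)
    left <- left - n
  }
  close(con)
  out <- list(path = path, size = size, seed = seed)
  if (!is.null(announce)) {
    # name derives from size+seed, not the path, so the same seed yields the
    # same info-hash wherever the fixture lands on disk
    out$torrent <- torrent_create(path, announce, piece_length = piece_length,
                                  name = sprintf("payload-%.0f-seed%d", size, seed))
    out$info_hash <- format(info_hash(out$torrent))
  }
  out
}
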