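#' Create a .torrent metainfo object from payload files
#'
#' Builds a BitTorrent v1 metainfo structure: the payload is split into
#' fixed-size pieces, each piece is checksummed with SHA-1, and the digests
#' are concatenated into the `pieces` field of the `info` dictionary. The
#' metainfo describes the payload but never contains it.
#'
#' A single file produces single-file mode (`length` in `info`); a directory
#' produces multi-file mode (`files` list). Files in a directory are ordered
#' lexicographically by path components, bytewise, so the same directory
#' always yields the same info-hash regardless of filesystem enumeration
#' order. The piece stream runs across file boundaries.
#'
#' @param path A readable file or directory.
#' @param announce Absolute HTTP(S) tracker URL.
#' @param piece_length Piece size in bytes; at least 16 KiB. Default 4 MiB,
#'   a common choice for multi-GiB scientific payloads.
#' @param private Force the BEP-0027 private flag (`1`) in the info dict.
#' @param name Override the torrent name (defaults to the base name of
#'   `path`).
#' @param creation_date POSIXct or epoch seconds; `NULL` omits the field.
#' @return An object of class `metainfo`: a list with `announce`, `info`
#'   and optional `creation date` entries, directly encodable with
#'   [bencode()].
#' @export
torrent_create <- function(path, announce, piece_length = 4 * 1048576,
                           private = FALSE, name = NULL, creation_date = NULL) {
  stopifnot(length(path) == 1L)
  if (!file.exists(path)) stop("torrent_create: path does not exist: ", path)
  if (piece_length < 16384) stop("torrent_create: piece_length must be at least 16 KiB")
  check_announce_url(announce)

  if (dir.exists(path)) {
    rel <- sort_paths_bytewise(list.files(path, recursive = TRUE, all.files = FALSE))
    if (length(rel) == 0L) stop("torrent_create: directory contains no files")
    abs <- file.path(path, rel)
    lens <- file.size(abs)
    if (anyNA(lens)) stop("torrent_create: unreadable file under ", path)
    if (sum(lens) == 0) stop("torrent_create: total payload is zero bytes")
    files <- lapply(seq_along(rel), function(i) {
      list(length = as.numeric(lens[i]),
           path = as.list(strsplit(rel[i], "/", fixed = TRUE)[[1L]]))
    })
    pieces <- hash_piece_stream(abs, lens, piece_length)
    info <- list(
      name = if (is.null(name)) basename(normalizePath(path)) else name,
      `piece length` = as.numeric(piece_length),
      pieces = pieces,
      files = files
    )
  } else {
    len <- file.size(path)
    if (is.na(len)) stop("torrent_create: unreadable file: ", path)
    if (len == 0) stop("torrent_create: total payload is zero bytes")
    pieces <- hash_piece_stream(path, len, piece_length)
    info <- list(
      name = if (is.null(name)) basename(path) else name,
      `piece length` = as.numeric(piece_length),
      length = as.numeric(len),
      pieces = pieces
    )
  }
  if (private) info$private <- 1
  mi <- list(announce = announce, info = info)
  if (!is.null(creation_date)) mi$`creation date` <- as.numeric(creation_date)
  structure(mi, class = "metainfo")
}

check_announce_url <- function(announce) {
  if (!is.character(announce) || length(announce) != 1L ||
      !grepl("^https?://[^/[:space:]]+", announce)) {
    stop("announce must be an absolute http(s) URL")
  }
  invisible(announce)
}

# bytewise lexicographic sort of relative paths, stable across locales
sort_paths_bytewise <- function(paths) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  sort(paths, method = "radix")
}

# SHA-1 digests over the concatenated payload stream, one per piece.
# Reads files sequentially in piece-sized chunks; never loads the payload
# whole. Returns the concatenated 20-byte digests as one raw vector.
hash_piece_stream <- function(files, lengths, piece_length) {
  total <- sum(lengths)
  n_pieces <- ceiling(total / piece_length)
  digests <- vector("list", n_pieces)
  buf <- raw(0)
  pi <- 1L
  for (f in files) {
    con <- file(f, "rb")
    repeat {
      chunk <- readBin(con, "raw", n = piece_length)
      if (length(chunk) == 0L) break
      buf <- c(buf, chunk)
      while (length(buf) >= piece_length) {
        digests[[pi]] <- digest::digest(buf[seq_len(piece_length)], algo = "sha1",
                                        serialize = FALSE, raw = TRUE)
        buf <- buf[-seq_len(piece_length)]
        pi <- pi + 1L
      }
    }
    close(con)
  }
  if (length(buf) > 0L) {
    digests[[pi]] <- digest::digest(buf, algo = "sha1", serialize = FALSE, raw = TRUE)
  }
  do.call(c, digests)
}

#' Number of pieces and payload size of a metainfo
#' @param torrent A `metainfo` object.
#' @return `torrent_piece_count()`: integer; `torrent_total_bytes()`: numeric.
#' @export
torrent_piece_count <- function(torrent) {
  length(torrent$info$pieces) %/% 20L
}

#' @rdname torrent_piece_count
#' @export
torrent_total_bytes <- function(torrent) {
  info <- torrent$info
  if (!is.null(info$length)) return(as.numeric(info$length))
  sum(vapply(info$files, function(f) as.numeric(f$length), 1))
}

#' Compute the info-hash of a torrent
#'
#' The info-hash is the SHA-1 digest of the bencoded `info` dictionary and
#' is the global identity of a torrent: the tracker keys swarms by it, and
#' any change to the info dict (including toggling the private flag)
#' produces a different hash. For raw torrent bytes the digest is taken over
#' the verbatim `info` byte span ([bencode_slice()]); for a `metainfo`
#' object, over its canonical encoding.
#'
#' @param x A `metainfo` object or raw vector of a bencoded torrent.
#' @return An `info_hash` object: the 20 raw digest bytes with `hex` and
#'   URL-escaped renderings accessible via `format()`/`as.character()` and
#'   [info_hash_urlencode()].
#' @export
info_hash <- function(x) {
  info_bytes <- if (is.raw(x)) {
    bencode_slice(x, "info")
  } else if (inherits(x, "metainfo")) {
    bencode(x$info)
  } else {
    stop("info_hash: need a metainfo object or raw torrent bytes")
  }
  structure(digest::digest(info_bytes, algo = "sha1", serialize = FALSE, raw = TRUE),
            class = "info_hash")
}

#' @export
format.info_hash <- function(x, ...) paste(sprintf("%02x", as.integer(unclass(x))), collapse = "")

#' @export
as.character.info_hash <- function(x, ...) format(x)

#' @export
print.info_hash <- function(x, ...) {
  cat("<info-hash ", format(x), ">\n", sep = "")
  invisible(x)
}

#' @rdname info_hash
#' @param hash An `info_hash` (or 20 raw bytes).
#' @export
info_hash_urlencode <- function(hash) {
  paste(sprintf("%%%02x", as.integer(unclass(hash))), collapse = "")
}

# canonical hex for arbitrary raw
raw_to_hex <- function(r) paste(sprintf("%02x", as.integer(r)), collapse = "")
hex_to_raw <- function(h) as.raw(strtoi(substring(h, seq(1, nchar(h), 2), seq(2, nchar(h), 2)), 16L))

#' Force the private flag on a torrent
#'
#' Sets `private = 1` in the info dictionary (BEP-0027), telling compliant
#' clients to use only the embedded tracker — no DHT or peer exchange — so
#' swarm membership stays under the portal's control. All other info fields
#' are untouched. Idempotent: an already-private torrent is returned
#' unchanged, so its info-hash is stable.
#'
#' @param torrent A `metainfo` object.
#' @return The privatized `metainfo`.
#' @export
torrent_privatize <- function(torrent) {
  stopifnot(inherits(torrent, "metainfo"))
  if (identical(as.numeric(torrent$info$private), 1)) return(torrent)
  torrent$info$private <- 1
  torrent
}

#' Embed a user's authorization token in the announce URL
#'
#' The portal customizes the tracker URL per user: the token is placed as a
#' path segment, `<base>/<token>/announce`, so the tracker can authenticate
#' every announce. Only the announce URL changes — the info dictionary, and
#' therefore the info-hash, is untouched, so every user's torrent joins the
#' same swarm.
#'
#' @param torrent A `metainfo` object.
#' @param tracker_base Base tracker URL (no trailing slash needed).
#' @param token The user's authorization token (non-empty string).
#' @return The `metainfo` with a tokenized announce URL.
#' @export
torrent_tokenize <- function(torrent, tracker_base, token) {
  stopifnot(inherits(torrent, "metainfo"))
  if (!is.character(token) || length(token) != 1L || is.na(token) || !nzchar(token)) {
    stop("torrent_tokenize: token must be a non-empty string")
  }
  check_announce_url(tracker_base)
  base <- sub("/+$", "", tracker_base)
  torrent$announce <- paste0(base, "/", token, "/announce")
  torrent
}

#' Verify a payload against a torrent's piece checksums
#'
#' Recomputes the SHA-1 digest of every piece of the payload at `path` and
#' compares each with the digest recorded in the torrent. Missing or
#' unreadable files simply yield failed pieces; verification never errors on
#' damaged data.
#'
#' @param torrent A `metainfo` object.
#' @param path The payload file (single-file mode) or directory containing
#'   the payload files (multi-file mode).
#' @return A `verification_report`: list with `piece_ok` (logical per
#'   piece), `completion_fraction` (passed / total), and `missing` (0-based
#'   indices of failed pieces).
#' @export
torrent_verify <- function(torrent, path) {
  stopifnot(inherits(torrent, "metainfo"))
  info <- torrent$info
  piece_length <- as.numeric(info$`piece length`)
  n_pieces <- torrent_piece_count(torrent)
  expected <- split_digests(info$pieces)

  if (!is.null(info$length)) {
    files <- path
    lengths <- as.numeric(info$length)
  } else {
    rel <- vapply(info$files, function(f) paste(unlist(f$path), collapse = "/"), "")
    files <- file.path(path, rel)
    lengths <- vapply(info$files, function(f) as.numeric(f$length), 1)
  }

  actual <- hash_piece_stream_tolerant(files, lengths, piece_length)
  piece_ok <- vapply(seq_len(n_pieces), function(i) {
    !is.null(actual[[i]]) && identical(actual[[i]], expected[[i]])
  }, TRUE)
  structure(list(
    piece_ok = piece_ok,
    completion_fraction = sum(piece_ok) / n_pieces,
    missing = which(!piece_ok) - 1L
  ), class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  cat(sprintf("payload verification: %d/%d pieces ok (%.1f%% complete)\n",
              sum(x$piece_ok), length(x$piece_ok), 100 * x$completion_fraction))
  if (length(x$missing)) cat("failed pieces:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

split_digests <- function(pieces) {
  n <- length(pieces) %/% 20L
  lapply(seq_len(n), function(i) pieces[((i - 1L) * 20L + 1L):(i * 20L)])
}

# Like hash_piece_stream but tolerant: a missing/short file contributes
# nothing for its byte range, so the affected pieces hash differently (or not
# at all) and fail verification instead of erroring.
hash_piece_stream_tolerant <- function(files, lengths, piece_length) {
  total <- sum(lengths)
  n_pieces <- ceiling(total / piece_length)
  digests <- vector("list", n_pieces)
  buf <- raw(0)
  pi <- 1L
  broken <- FALSE # once the stream diverges in length, later pieces misalign anyway
  for (i in seq_along(files)) {
    f <- files[i]
    want <- lengths[i]
    got <- 0
    if (file.exists(f) && !dir.exists(f)) {
      con <- try(file(f, "rb"), silent = TRUE)
      if (!inherits(con, "try-error")) {
        repeat {
          chunk <- readBin(con, "raw", n = piece_length)
          if (length(chunk) == 0L) break
          if (got + length(chunk) > want) chunk <- chunk[seq_len(want - got)]
          got <- got + length(chunk)
          buf <- c(buf, chunk)
          while (length(buf) >= piece_length) {
            if (pi <= n_pieces) {
              digests[[pi]] <- digest::digest(buf[seq_len(piece_length)], algo = "sha1",
                                              serialize = FALSE, raw = TRUE)
            }
            buf <- buf[-seq_len(piece_length)]
            pi <- pi + 1L
          }
          if (got >= want) break
        }
        close(con)
      }
    }
    if (got < want) broken <- TRUE
    if (broken) break
  }
  if (!broken && length(buf) > 0L && pi <= n_pieces) {
    digests[[pi]] <- digest::digest(buf, algo = "sha1", serialize = FALSE, raw = TRUE)
  }
  digests
}

#' Read and write .torrent files
#'
#' `torrent_read()` parses a bencoded .torrent file into a `metainfo`
#' object (leniently: real-world torrents with non-canonical key order are
#' accepted); `torrent_write()` serializes one canonically. A write/read
#' round trip is lossless.
#'
#' @param path File path.
#' @param torrent A `metainfo` object.
#' @param strict Reject non-canonical files when reading.
#' @return `torrent_read()`: a `metainfo`; `torrent_write()`: the path,
#'   invisibly.
#' @export
torrent_read <- function(path, strict = FALSE) {
  data <- readBin(path, "raw", n = file.size(path))
  torrent_from_bytes(data, strict = strict)
}

#' @rdname torrent_read
#' @param data Raw vector of bencoded torrent bytes.
#' @export
torrent_from_bytes <- function(data, strict = FALSE) {
  v <- tryCatch(bdecode(data, strict = strict),
                error = function(e) stop("not a valid torrent: ", conditionMessage(e), call. = FALSE))
  if (!is.list(v) || is.null(names(v)) || is.null(v$info)) {
    stop("not a valid torrent: missing info dictionary")
  }
  mi <- metainfo_decode_text(v)
  structure(mi, class = "metainfo")
}

# decoded bencode uses raw byte-strings throughout; convert the well-known
# textual fields to character for ergonomic access, leaving pieces raw
metainfo_decode_text <- function(v) {
  to_chr <- function(x) if (is.raw(x)) rawToChar(x) else x
  v$announce <- to_chr(v$announce)
  if (!is.null(v$comment)) v$comment <- to_chr(v$comment)
  if (!is.null(v$`created by`)) v$`created by` <- to_chr(v$`created by`)
  if (!is.null(v$info$name)) v$info$name <- to_chr(v$info$name)
  if (!is.null(v$info$files)) {
    v$info$files <- lapply(v$info$files, function(f) {
      f$path <- lapply(f$path, to_chr)
      f
    })
  }
  v
}

#' @rdname torrent_read
#' @export
torrent_write <- function(torrent, path) {
  stopifnot(inherits(torrent, "metainfo"))
  writeBin(torrent_bytes(torrent), path)
  invisible(path)
}

#' @rdname torrent_read
#' @export
torrent_bytes <- function(torrent) {
  stopifnot(inherits(torrent, "metainfo"))
  bencode(unclass(torrent))
}

#' @export
print.metainfo <- function(x, ...) {
  cat("<torrent ", x$info$name %||% "?", ">\n", sep = "")
  cat("  announce:     ", x$announce, "\n", sep = "")
  cat("  piece length: ", as.numeric(x$info$`piece length`), " bytes\n", sep = "")
  cat("  pieces:       ", torrent_piece_count(x), "\n", sep = "")
  cat("  total bytes:  ", torrent_total_bytes(x), "\n", sep = "")
  cat("  private:      ", identical(as.numeric(x$info$private), 1), "\n", sep = "")
  cat("  info-hash:    ", format(info_hash(x)), "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
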