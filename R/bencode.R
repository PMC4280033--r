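#' Bencode encoding and decoding
#'
#' Bencoding is the serialization format used by .torrent metainfo files and
#' tracker responses. It has four kinds of values: byte-strings
#' (`<length>:<bytes>`), integers (`i<digits>e`), lists (`l...e`) and
#' dictionaries (`d...e`) whose keys are byte-strings sorted by raw byte
#' order. The encoding of a value is canonical: a given value has exactly one
#' valid serialization, which is what makes SHA-1 info-hashes stable
#' identifiers.
#'
#' Mapping to R values:
#' * byte-strings encode from `raw` vectors or `character` scalars
#'   (converted to UTF-8 bytes); they always decode to `raw`.
#' * integers encode from whole `numeric`/`integer` scalars and decode to
#'   `numeric` (exact up to 2^53, which comfortably covers multi-hundred-GiB
#'   file lengths; larger magnitudes are an error rather than a silent loss
#'   of precision).
#' * dictionaries are named lists, lists are unnamed lists. An empty named
#'   list encodes as an empty dictionary; `structure(list(), names =
#'   character())` produces one.
#'
#' @param x An R value: raw vector, character scalar, whole numeric scalar,
#'   or a (possibly named) list of such values.
#' @return `bencode()` returns a raw vector holding the canonical encoding.
#' @examples
#' rawToChar(bencode(0))                  # "i0e"
#' rawToChar(bencode(list(announce = "https://t/abc/announce")))
#' bdecode(bencode(list(1, 2)))
#' @export
bencode <- function(x) {
  buf <- list()
  emit <- function(r) buf[[length(buf) + 1L]] <<- r
  benc_emit(x, emit)
  do.call(c, buf)
}

benc_emit <- function(x, emit) {
  if (is.raw(x)) {
    emit(charToRaw(paste0(length(x), ":")))
    emit(x)
  } else if (is.character(x)) {
    if (length(x) != 1L || is.na(x)) stop("bencode: character values must be length-1 and non-NA")
    r <- charToRaw(enc2utf8(x))
    emit(charToRaw(paste0(length(r), ":")))
    emit(r)
  } else if (is.numeric(x)) {
    if (length(x) != 1L || is.na(x)) stop("bencode: numeric values must be length-1 and non-NA")
    if (x != trunc(x)) stop("bencode: integers only, got fractional value")
    if (abs(x) > 2^53) stop("bencode: integer magnitude exceeds 2^53")
    emit(charToRaw(sprintf("i%se", format(x, scientific = FALSE))))
  } else if (is.list(x)) {
    nm <- names(x)
    if (is.null(nm)) {
      emit(as.raw(0x6c)) # l
      for (el in x) benc_emit(el, emit)
      emit(as.raw(0x65)) # e
    } else {
      if (anyNA(nm) || any(nm == "")) stop("bencode: dictionary keys must all be non-empty")
      if (anyDuplicated(nm)) stop("bencode: duplicate dictionary keys")
      keys <- lapply(nm, charToRaw)
      ord <- order_raw_keys(keys)
      emit(as.raw(0x64)) # d
      for (i in ord) {
        k <- keys[[i]]
        emit(charToRaw(paste0(length(k), ":")))
        emit(k)
        benc_emit(x[[i]], emit)
      }
      emit(as.raw(0x65)) # e
    }
  } else {
    stop("bencode: unsupported value of class ", paste(class(x), collapse = "/"))
  }
}

# Sort raw-byte keys lexicographically, bytewise (not locale collation).
order_raw_keys <- function(keys) {
  if (length(keys) <= 1L) return(seq_along(keys))
  # pad to equal length with -1 sentinel so shorter keys sort first
  maxlen <- max(vapply(keys, length, 1L))
  mat <- vapply(keys, function(k) {
    v <- rep(-1L, maxlen)
    if (length(k)) v[seq_along(k)] <- as.integer(k)
    v
  }, integer(maxlen))
  if (maxlen == 1L) mat <- matrix(mat, nrow = 1L)
  do.call(order, lapply(seq_len(maxlen), function(i) mat[i, ]))
}

raw_key_sorted <- function(keys) {
  identical(order_raw_keys(keys), seq_along(keys))
}

#' Decode a bencoded document
#'
#' @param data Raw vector containing one complete bencoded value. Trailing
#'   bytes after the top-level value are an error.
#' @param strict If `TRUE` (default) reject non-canonical input: integer
#'   leading zeros, negative zero, unsorted or duplicate dictionary keys.
#'   With `strict = FALSE` such real-world documents are accepted (duplicate
#'   keys still rejected); re-encoding with [bencode()] then yields the
#'   canonical form.
#' @return The decoded value; see [bencode()] for the type mapping.
#'   Parse failures raise an error naming the byte offset.
#' @export
bdecode <- function(data, strict = TRUE) {
  if (is.character(data)) data <- charToRaw(data)
  stopifnot(is.raw(data))
  st <- new.env(parent = emptyenv())
  st$pos <- 1L
  v <- bdec_value(data, st, strict)
  if (st$pos <= length(data)) {
    stop("bdecode: trailing bytes after top-level value at offset ", st$pos - 1L)
  }
  v
}

bdec_err <- function(st, msg) stop("bdecode: ", msg, " at offset ", st$pos - 1L, call. = FALSE)

bdec_byte <- function(data, st) {
  if (st$pos > length(data)) bdec_err(st, "truncated input")
  b <- data[st$pos]
  st$pos <- st$pos + 1L
  b
}

bdec_peek <- function(data, st) {
  if (st$pos > length(data)) bdec_err(st, "truncated input")
  data[st$pos]
}

bdec_value <- function(data, st, strict) {
  b <- bdec_peek(data, st)
  i <- as.integer(b)
  if (i >= 0x30 && i <= 0x39) {
    bdec_string(data, st, strict)
  } else if (b == 0x69) { # i
    bdec_int(data, st, strict)
  } else if (b == 0x6c) { # l
    st$pos <- st$pos + 1L
    out <- list()
    while (bdec_peek(data, st) != 0x65) out[[length(out) + 1L]] <- bdec_value(data, st, strict)
    st$pos <- st$pos + 1L
    out
  } else if (b == 0x64) { # d
    st$pos <- st$pos + 1L
    keys <- list()
    vals <- list()
    while (bdec_peek(data, st) != 0x65) {
      kb <- bdec_peek(data, st)
      if (!(as.integer(kb) >= 0x30 && as.integer(kb) <= 0x39)) bdec_err(st, "dictionary key is not a byte-string")
      keys[[length(keys) + 1L]] <- bdec_string(data, st, strict)
      vals[[length(vals) + 1L]] <- bdec_value(data, st, strict)
    }
    st$pos <- st$pos + 1L
    knames <- vapply(keys, function(k) {
      if (any(k == 0)) bdec_err(st, "NUL byte in dictionary key")
      rawToChar(k)
    }, "")
    if (anyDuplicated(knames)) bdec_err(st, "duplicate dictionary key")
    if (strict && !raw_key_sorted(keys)) bdec_err(st, "dictionary keys not in canonical sort order")
    names(vals) <- knames
    vals
  } else {
    bdec_err(st, sprintf("unexpected byte 0x%02x", i))
  }
}

bdec_string <- function(data, st, strict = TRUE) {
  n <- bdec_digits(data, st, stop_byte = 0x3a, strict_zeros = strict) # ':'
  if (n < 0) bdec_err(st, "negative string length")
  if (st$pos + n - 1L > length(data)) bdec_err(st, "truncated byte-string")
  out <- if (n == 0) raw(0) else data[st$pos:(st$pos + n - 1L)]
  st$pos <- st$pos + as.integer(n)
  out
}

bdec_int <- function(data, st, strict) {
  st$pos <- st$pos + 1L # consume 'i'
  neg <- FALSE
  if (bdec_peek(data, st) == 0x2d) { # '-'
    neg <- TRUE
    st$pos <- st$pos + 1L
  }
  start <- st$pos
  n <- bdec_digits(data, st, stop_byte = 0x65, strict_zeros = strict)
  ndigits <- st$pos - 1L - start
  if (ndigits < 1L) bdec_err(st, "integer with no digits")
  if (neg && n == 0) bdec_err(st, "negative zero")
  if (neg) -n else n
}

# Reads ASCII digits until stop_byte; consumes the stop byte. Returns numeric.
bdec_digits <- function(data, st, stop_byte, strict_zeros = TRUE) {
  digits <- integer(0)
  repeat {
    b <- bdec_byte(data, st)
    bi <- as.integer(b)
    if (b == stop_byte) break
    if (bi < 0x30 || bi > 0x39) bdec_err(st, "malformed length/integer digits")
    digits <- c(digits, bi - 0x30L)
    if (length(digits) > 17L) bdec_err(st, "integer exceeds 2^53")
  }
  if (length(digits) == 0L) bdec_err(st, "missing digits")
  if (strict_zeros && length(digits) > 1L && digits[1L] == 0L) bdec_err(st, "leading zero")
  val <- sum(digits * 10^rev(seq_along(digits) - 1))
  if (val > 2^53) bdec_err(st, "integer exceeds 2^53")
  val
}

#' Extract the raw byte span of one top-level dictionary entry
#'
#' Returns the exact contiguous bytes of the value stored under
#' `key` in a bencoded dictionary, as they appear in `data`. This is how the
#' info-hash of a third-party torrent is computed: SHA-1 over the verbatim
#' `info` bytes, not over a re-encoding.
#'
#' @param data Raw vector; must decode to a bencoded dictionary.
#' @param key Character scalar or raw vector naming the top-level entry.
#' @return Raw vector: the byte span of that entry's value.
#' @export
bencode_slice <- function(data, key) {
  if (is.character(data)) data <- charToRaw(data)
  if (is.raw(key)) key <- rawToChar(key)
  stopifnot(is.raw(data), is.character(key), length(key) == 1L)
  st <- new.env(parent = emptyenv())
  st$pos <- 1L
  if (bdec_byte(data, st) != 0x64) stop("bencode_slice: top-level value is not a dictionary")
  while (bdec_peek(data, st) != 0x65) {
    k <- bdec_string(data, st, strict = FALSE)
    start <- st$pos
    bdec_value(data, st, strict = FALSE) # skip value, tolerate lenient docs
    if (rawToChar(k) == key) return(data[start:(st$pos - 1L)])
  }
  stop("bencode_slice: key ", shQuote(key), " not present in dictionary")
}
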