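# Independent info-hash oracle: a standalone bencode parser (stdlib only)
# that locates the verbatim byte span of the top-level "info" entry of a
# .torrent file and prints the SHA-1 hex digest of that span.
import hashlib
import sys


def parse(data, pos):
    """Return position just past the value starting at pos."""
    c = data[pos]
    if c == ord("i"):
        end = data.index(b"e", pos)
        return end + 1
    if c == ord("l") or c == ord("d"):
        pos += 1
        while data[pos] != ord("e"):
            pos = parse(data, pos)
        return pos + 1
    if ord("0") <= c <= ord("9"):
        colon = data.index(b":", pos)
        n = int(data[pos:colon])
        return colon + 1 + n
    raise ValueError("bad byte at %d" % pos)


def info_span(data):
    assert data[0] == ord("d")
    pos = 1
    while data[pos] != ord("e"):
        colon = data.index(b":", pos)
        n = int(data[pos:colon])
        key = data[colon + 1 : colon + 1 + n]
        pos = colon + 1 + n
        start = pos
        pos = parse(data, pos)
        if key == b"info":
            return data[start:pos]
    raise KeyError("info")


if __name__ == "__main__":
    with open(sys.argv[1], "rb") as fh:
        data = fh.read()
    print(hashlib.sha1(info_span(data)).hexdigest())
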