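# Index file format (little-endian):
#   magic "SIGF", version u16, k u16, n u16, entry_width u8, canonical u8,
#   phases u8, omega u64, m u64, master_seed u64, n x seed u64, G u32,
#   genome table in gid order (name_len u32 + UTF-8 name + genome length u64),
#   m packed signed entries (entry_width bytes each),
#   CRC-32 (u32) of all preceding bytes.

FORMAT_VERSION <- 1L

write_u32 <- function(con, x) {
  x <- as.numeric(x)
  v <- ifelse(x >= 2^31, x - 2^32, x)
  writeBin(as.integer(v), con, size = 4, endian = "little")
}

read_u32 <- function(con, n = 1L) {
  v <- readBin(con, integer(), n = n, size = 4, endian = "little")
  if (length(v) < n) stop("index file is truncated")
  ifelse(v < 0, v + 2^32, as.numeric(v))
}

write_u64 <- function(con, x) {
  x <- as.numeric(x)   # exact for values < 2^53, ample for every field here
  write_u32(con, x %% 2^32)
  write_u32(con, x %/% 2^32)
}

read_u64_1 <- function(con) {
  lo <- read_u32(con, 1L)
  hi <- read_u32(con, 1L)
  lo + hi * 2^32
}

write_u16 <- function(con, x) writeBin(as.integer(x), con, size = 2, endian = "little")

read_u16 <- function(con, n = 1L) {
  v <- readBin(con, integer(), n = n, size = 2, signed = FALSE, endian = "little")
  if (length(v) < n) stop("index file is truncated")
  v
}

#' Write a signature index to disk
#'
#' Serializes the index in a little-endian binary format (magic `SIGF`) that
#' records every build parameter -- including the hash seeds -- followed by
#' the packed entry array and a CRC-32 checksum, so that
#' `read_index(write_index(x))` reproduces every field and every entry
#' bit-exactly and subsequent queries are identical.
#'
#' @param index A `signature_index`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "signature_index"))
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw("SIGF"), con)
  write_u16(con, FORMAT_VERSION)
  write_u16(con, index$k)
  write_u16(con, index$family$n)
  writeBin(as.raw(index$entry_width), con)
  writeBin(as.raw(as.integer(index$canonical)), con)
  writeBin(as.raw(index$phases), con)
  write_u64(con, index$omega)
  write_u64(con, index$m)
  write_u64(con, index$family$master_seed)
  for (s in index$family$seeds) write_u64(con, s)
  tab <- index$genome_table
  write_u32(con, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    nm <- charToRaw(enc2utf8(tab$name[i]))
    write_u32(con, length(nm))
    writeBin(nm, con)
    write_u64(con, tab$length[i])
  }
  if (index$entry_width == 2L) {
    rng <- range(index$entries)
    if (rng[1] < -32768 || rng[2] > 32767)
      stop("entries out of range for entry_width = 2")
  }
  writeBin(index$entries, con, size = index$entry_width, endian = "little")
  payload <- rawConnectionValue(con)
  crc <- cpp_crc32(payload)
  con2 <- file(path, "wb")
  on.exit(close(con2), add = TRUE)
  writeBin(payload, con2)
  write_u32(con2, crc)
  invisible(path)
}

#' Read a signature index from disk
#'
#' Verifies the magic bytes, format version and CRC-32 checksum, then
#' restores every field of the index.  Build-time signature position lists
#' are not part of the file format and come back `NULL`.
#'
#' @param path Path written by [write_index()].
#' @return A `signature_index`.
#' @export
read_index <- function(path) {
  all_bytes <- readBin(path, raw(), n = file.info(path)$size)
  if (length(all_bytes) < 8) stop("index file is truncated")
  payload <- all_bytes[seq_len(length(all_bytes) - 4L)]
  tail4 <- all_bytes[(length(all_bytes) - 3L):length(all_bytes)]
  con <- rawConnection(tail4, "rb")
  stored_crc <- read_u32(con)
  close(con)
  if (cpp_crc32(payload) != stored_crc)
    stop("index file failed its CRC-32 integrity check")
  con <- rawConnection(payload, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readBin(con, raw(), n = 4)
  if (!identical(rawToChar(magic), "SIGF"))
    stop("not a signature index file (bad magic)")
  version <- read_u16(con)
  if (version != FORMAT_VERSION)
    stop("unsupported index format version ", version)
  k <- read_u16(con)
  n <- read_u16(con)
  entry_width <- as.integer(readBin(con, raw(), n = 1))
  canonical <- as.logical(as.integer(readBin(con, raw(), n = 1)))
  phases <- as.integer(readBin(con, raw(), n = 1))
  omega <- read_u64_1(con)
  m <- read_u64_1(con)
  master_seed <- read_u64_1(con)
  seeds <- vapply(seq_len(n), function(i) read_u64_1(con), numeric(1))
  G <- read_u32(con)
  nms <- character(G); lens <- numeric(G)
  for (i in seq_len(G)) {
    nl <- read_u32(con)
    nms[i] <- rawToChar(readBin(con, raw(), n = nl))
    lens[i] <- read_u64_1(con)
  }
  entries <- readBin(con, integer(), n = m, size = entry_width,
                     endian = "little", signed = TRUE)
  if (length(entries) != m) stop("index file is truncated")
  family <- structure(
    list(n = as.integer(n), m = m, seeds = seeds, master_seed = master_seed),
    class = "hash_family")
  structure(
    list(entries = entries, m = m, k = as.integer(k), family = family,
         genome_table = data.frame(gid = seq_len(G), name = nms, length = lens,
                                   stringsAsFactors = FALSE),
         phases = phases, omega = omega, canonical = canonical,
         entry_width = entry_width, signatures = NULL),
    class = "signature_index"
  )
}
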