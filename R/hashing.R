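#' Create a seeded hash family
#'
#' A hash family is a set of `n` seeded, non-cryptographic hash functions
#' mapping a k-mer to positions in `[0, m)`.  The `n` pairwise-distinct seeds
#' are derived deterministically from a single master seed, so an index built
#' on one machine classifies identically on any other.
#'
#' @param m Index size in entries (`>= 1`).
#' @param n Number of hash functions (`>= 1`).
#' @param master_seed Integer master seed from which the `n` seeds are derived.
#' @return An object of class `hash_family` with fields `n`, `m`, `seeds`
#'   and `master_seed`.
#' @examples
#' fam <- hash_family(m = 2^16, n = 2, master_seed = 1)
#' hash_kmer(fam, "ACGTACGTAC")
#' @export
hash_family <- function(m, n = 2L, master_seed = 1L) {
  m <- as.numeric(m)
  n <- as.integer(n)
  if (length(m) != 1 || is.na(m) || m < 1) stop("m must be a single value >= 1")
  if (length(n) != 1 || is.na(n) || n < 1) stop("n must be a single integer >= 1")
  master_seed <- as.numeric(master_seed)
  if (length(master_seed) != 1 || is.na(master_seed) || master_seed < 0)
    stop("master_seed must be a single non-negative integer")
  seeds <- cpp_derive_seeds(master_seed, n)
  stopifnot(!anyDuplicated(seeds))
  structure(
    list(n = n, m = floor(m), seeds = seeds, master_seed = master_seed),
    class = "hash_family"
  )
}

#' @export
print.hash_family <- function(x, ...) {
  cat(sprintf("<hash_family> n = %d hash functions over m = %s entries (master seed %s)\n",
              x$n, format(x$m, big.mark = ","), format(x$master_seed)))
  invisible(x)
}

#' Extract k-mers from a DNA sequence
#'
#' Slides a window of length `k` along the sequence and returns every window
#' made only of A/C/G/T, with its 0-based start position.  Windows containing
#' any other character (N, IUPAC ambiguity codes, ...) are skipped entirely
#' because they cannot be hashed consistently.  Lowercase input is accepted
#' and uppercased.
#'
#' @param sequence A single DNA string.
#' @param k K-mer length (`>= 1`).  If `k` exceeds the sequence length the
#'   result is empty (not an error).
#' @param canonical If `TRUE` (default) each k-mer is replaced by the
#'   lexicographic minimum of itself and its reverse complement, making
#'   downstream classification strand-insensitive.
#' @return A data.frame with columns `pos` (0-based integer) and `kmer`.
#' @examples
#' extract_kmers("ACNGT", k = 2, canonical = FALSE)
#' @export
extract_kmers <- function(sequence, k, canonical = TRUE) {
  if (length(sequence) != 1 || !is.character(sequence))
    stop("sequence must be a single string")
  k <- as.integer(k)
  if (is.na(k) || k < 1) stop("k must be an integer >= 1")
  res <- cpp_extract_kmers(toupper(sequence), k, isTRUE(canonical))
  data.frame(pos = res$pos, kmer = res$kmer, stringsAsFactors = FALSE)
}

#' Hash a k-mer with every function of a family
#'
#' @param family A [hash_family()].
#' @param key A k-mer string over {A,C,G,T} (canonicalize first if the index
#'   was built with canonical k-mers).
#' @return A numeric vector of `family$n` positions in `[0, family$m)`, one
#'   per hash function, in seed order.  Duplicate values are possible and
#'   preserved.
#' @export
hash_kmer <- function(family, key) {
  stopifnot(inherits(family, "hash_family"))
  if (length(key) != 1 || !is.character(key) || !nzchar(key))
    stop("key must be a single non-empty string")
  as.vector(cpp_hash_kmers(toupper(key), family$seeds, family$m))
}

# vectorized internal variant: n x N matrix of positions
hash_kmers <- function(family, keys) {
  cpp_hash_kmers(keys, family$seeds, family$m)
}

#' Canonicalize k-mers
#'
#' Returns, for each input k-mer, the lexicographic minimum of the k-mer and
#' its reverse complement.
#'
#' @param keys Character vector of k-mers over {A,C,G,T}.
#' @return Character vector of canonical representatives.
#' @export
canonical_kmers <- function(keys) {
  cpp_canonical_kmers(toupper(keys))
}

#' Suggested number of hash functions for a plain Bloom filter
#'
#' The classical optimum `(m / elements) * ln 2`, rounded to the nearest
#' integer and clamped to at least 1.
#'
#' @param m Index size in entries.
#' @param elements Number of stored k-mers (`>= 1`).
#' @return Suggested integer hash count.
#' @examples
#' optimal_num_hashes(1000, 100)  # 7
#' @export
optimal_num_hashes <- function(m, elements) {
  m <- as.numeric(m); elements <- as.numeric(elements)
  if (length(m) != 1 || is.na(m) || m < 1) stop("m must be >= 1")
  if (length(elements) != 1 || is.na(elements) || elements < 1)
    stop("elements must be >= 1")
  as.integer(max(1, floor(m / elements * log(2) + 0.5)))
}
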