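#' Classify a single k-mer against the index
#'
#' Looks up the `n` entry values at the k-mer's hash positions.  If any entry
#' is 0 the k-mer was never stored (the no-false-negative side of a Bloom
#' filter: a stored signature always stamped all `n` entries), so the call is
#' absent.  If all `n` entries hold the same positive id, that genome is
#' called.  Anything else -- a dirty entry or conflicting ids -- is dirty.
#'
#' @param index A `signature_index`.
#' @param key A k-mer of length `index$k` (canonicalized internally when the
#'   index uses canonical k-mers).
#' @return An integer: 0 (absent), -1 (dirty), or a genome id.
#' @export
classify_kmer <- function(index, key) {
  stopifnot(inherits(index, "signature_index"))
  if (length(key) != 1 || nchar(key) != index$k)
    stop("key must be a single k-mer of length ", index$k)
  classify_kmers(index, key)
}

#' Classify many k-mers at once
#'
#' Vectorized form of [classify_kmer()].
#'
#' @param index A `signature_index`.
#' @param keys Character vector of k-mers, each of length `index$k`.
#' @return Integer vector of calls (0 absent, -1 dirty, gid).
#' @export
classify_kmers <- function(index, keys) {
  stopifnot(inherits(index, "signature_index"))
  if (length(keys) == 0) return(integer(0))
  if (any(nchar(keys) != index$k))
    stop("all keys must have length ", index$k)
  cpp_classify_kmers(index$entries, toupper(keys), index$family$seeds,
                     index$m, index$canonical)
}

#' Turn a vector of per-k-mer calls into a read assignment
#'
#' The aggregation rules shared by all read-level classifiers, applied to the
#' multiset `V` of per-k-mer calls in scan order:
#' \describe{
#'   \item{majority}{the positive id whose count exceeds 50% of the positive
#'     calls; ties and the absence of positives discard the read.  Only
#'     positive calls enter the denominator: after signature thinning most
#'     k-mers of a genuine read are absent, and counting those would discard
#'     nearly everything.}
#'   \item{first_hit}{the first positive call in scan order.}
#'   \item{one_or_nothing}{the single distinct positive id; any disagreement
#'     (or none at all) discards.}
#' }
#' A read whose calls are all 0/-1 is discarded under every strategy.
#'
#' @param calls Integer vector of per-k-mer calls in scan order.
#' @param strategy One of `"majority"`, `"first_hit"`, `"one_or_nothing"`.
#' @return Genome id, or `NA_integer_` for a discarded read.
#' @export
assign_from_calls <- function(calls,
                              strategy = c("majority", "first_hit", "one_or_nothing")) {
  strategy <- match.arg(strategy)
  pos <- calls[calls > 0]
  if (length(pos) == 0) return(NA_integer_)
  switch(strategy,
    majority = {
      tab <- table(pos)
      top <- which.max(tab)
      if (tab[[top]] * 2L > length(pos)) as.integer(names(tab)[top])
      else NA_integer_
    },
    first_hit = as.integer(pos[1]),
    one_or_nothing = {
      u <- unique(pos)
      if (length(u) == 1L) as.integer(u) else NA_integer_
    })
}

#' Classify one read
#'
#' Computes the per-k-mer calls over every valid k-mer window of the read and
#' aggregates them with the chosen strategy.  Reads shorter than `k` are
#' discarded.  The first-hit strategy uses a fast path that stops scanning at
#' the first positive call, in which case the call counts are not reported.
#'
#' @param index A `signature_index`.
#' @param sequence Read sequence (a single string).
#' @param strategy Assignment strategy; see [assign_from_calls()].
#' @return A list with `gid` (`NA_integer_` if discarded), `n_positive` and
#'   `n_total` (both `NA` under the first-hit fast path).
#' @export
classify_read <- function(index, sequence,
                          strategy = c("majority", "first_hit", "one_or_nothing")) {
  stopifnot(inherits(index, "signature_index"))
  strategy <- match.arg(strategy)
  sequence <- toupper(sequence)
  if (nchar(sequence) < index$k)
    return(list(gid = NA_integer_, n_positive = NA_integer_, n_total = NA_integer_))
  if (strategy == "first_hit") {
    hit <- cpp_first_hit(index$entries, sequence, index$k, index$family$seeds,
                         index$m, index$canonical)
    return(list(gid = if (hit > 0) hit else NA_integer_,
                n_positive = NA_integer_, n_total = NA_integer_))
  }
  calls <- cpp_classify_sequence(index$entries, sequence, index$k,
                                 index$family$seeds, index$m, index$canonical)
  list(gid = assign_from_calls(calls, strategy),
       n_positive = sum(calls > 0L), n_total = length(calls))
}

#' @rdname classify_read
#' @export
classify_read_majority <- function(index, sequence)
  classify_read(index, sequence, "majority")

#' @rdname classify_read
#' @export
classify_read_first_hit <- function(index, sequence)
  classify_read(index, sequence, "first_hit")

#' @rdname classify_read
#' @export
classify_read_one_or_nothing <- function(index, sequence)
  classify_read(index, sequence, "one_or_nothing")

#' Classify a sample of reads
#'
#' Each read is retained independently with probability `sample_fraction`
#' (a seeded Bernoulli draw -- processing a small random sample of the reads
#' is usually enough to detect which genomes are present), and every retained
#' read is classified with the chosen strategy.  Per-read classification is a
#' pure function of (index, read), so the result does not depend on
#' processing order or on how reads are partitioned across threads.
#'
#' @param index A `signature_index`.
#' @param reads A FASTA/FASTQ path (optionally gzipped), a
#'   `Biostrings::DNAStringSet`, or a named character vector of sequences.
#' @param strategy Assignment strategy; see [assign_from_calls()].
#' @param sample_fraction Retention probability in (0, 1].
#' @param seed Seed for the retention draw.
#' @param threads Number of worker processes (classification is pure per
#'   read, so any value yields the same assignments).
#' @return A data.frame with columns `read_id`, `strategy`, `gid`
#'   (`NA` = discarded), `n_positive`, `n_total`.
#' @export
query_sample <- function(index, reads,
                         strategy = c("majority", "first_hit", "one_or_nothing"),
                         sample_fraction = 1, seed = 1L, threads = 1L) {
  stopifnot(inherits(index, "signature_index"))
  strategy <- match.arg(strategy)
  if (!is.numeric(sample_fraction) || sample_fraction <= 0 || sample_fraction > 1)
    stop("sample_fraction must be in (0, 1]")
  reads <- as_read_vector(reads)
  keep <- if (sample_fraction < 1)
    with_seed(seed, runif(length(reads)) < sample_fraction)
  else rep(TRUE, length(reads))
  reads <- reads[keep]
  short <- sum(nchar(reads) < index$k)
  if (short > 0)
    message(short, " read(s) shorter than k = ", index$k, " discarded")
  classify1 <- function(s) classify_read(index, s, strategy)
  res <- if (threads > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(reads, classify1, mc.cores = as.integer(threads))
  } else {
    lapply(reads, classify1)
  }
  data.frame(
    read_id = if (is.null(names(reads))) as.character(seq_along(reads)) else names(reads),
    strategy = strategy,
    gid = vapply(res, `[[`, integer(1), "gid"),
    n_positive = vapply(res, `[[`, integer(1), "n_positive"),
    n_total = vapply(res, `[[`, integer(1), "n_total"),
    stringsAsFactors = FALSE
  )
}

as_read_vector <- function(reads) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads, ignore.case = TRUE))
      "fastq" else "fasta"
    ss <- Biostrings::readDNAStringSet(reads, format = fmt)
    out <- as.character(ss)
    names(out) <- sub("\\s.*$", "", names(ss))
    return(out)
  }
  if (methods::is(reads, "DNAStringSet")) {
    out <- as.character(reads)
    names(out) <- names(reads)
    return(out)
  }
  if (is.character(reads)) return(toupper(reads))
  stop("reads must be a file path, a DNAStringSet or a character vector")
}

#' Write read assignments as TSV
#'
#' One row per read: `read_id`, `strategy`, outcome (`gid` or `-` for a
#' discarded read), positive k-mer calls, total k-mer calls (`-` placeholders
#' under the first-hit fast path).
#'
#' @param assignments Output of [query_sample()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_assignments <- function(assignments, path) {
  out <- assignments
  for (cc in c("gid", "n_positive", "n_total")) {
    out[[cc]] <- as.character(out[[cc]])
    out[[cc]][is.na(out[[cc]])] <- "-"
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
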