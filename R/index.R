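#' Build the signature index over a community
#'
#' Constructs the modified Bloom filter `F`: an array of `m` entries, each
#' holding 0 (never touched), -1 (dirty) or a genome id.  Every genome is
#' processed in order with the marking pass (phase 1); with `phases = 2` all
#' genomes are processed again, which is what makes the signature marks of
#' every genome -- not just the last one -- reflect hash-value uniqueness.
#' When `omega > 0`, phase 2 ends each genome with a thinning pass that keeps
#' only signatures spaced more than `omega` apart along each contig and
#' dirties the rest.
#'
#' @param genomes A [genome_set()] in processing order.
#' @param m Index size in entries (not bytes; see [index_entries_for_bytes()]).
#' @param n Number of hash functions.
#' @param k K-mer length.
#' @param phases 1 or 2.  After a 1-phase build only the last genome's marks
#'   are trustworthy; 2 phases is the normal mode.
#' @param omega Signature spacing for the thinning pass; `0` disables it.
#'   Defaults to `k`, so adjacent kept signatures cannot overlap.  Never run
#'   in 1-phase builds.
#' @param master_seed Master seed for the hash family.
#' @param canonical Use canonical (strand-insensitive) k-mers.  Keep the
#'   default unless reads are known to come from one strand only.
#' @param entry_width Serialized entry width in bytes: 4 (default) or 2
#'   (halves the file for communities of fewer than 32,767 genomes).
#' @return An object of class `signature_index` with fields `entries` (integer
#'   vector of length `m`), `m`, `k`, `family`, `genome_table`, `phases`,
#'   `omega`, `canonical`, `entry_width`, and `signatures`: the per-genome,
#'   per-contig 0-based positions of the signature k-mers kept at the end of
#'   phase 2 (`NULL` after a 1-phase build and after deserialization).
#' @examples
#' gs <- generate_community(n_genomes = 3, genome_length = 500, seed = 1)
#' idx <- build_index(gs, m = 2^16, n = 2, k = 31, omega = 0)
#' @export
build_index <- function(genomes, m, n = 2L, k = 31L, phases = 2L, omega = k,
                        master_seed = 1L, canonical = TRUE, entry_width = 4L) {
  stopifnot(inherits(genomes, "genome_set"))
  m <- as.numeric(m); k <- as.integer(k)
  phases <- as.integer(phases)
  omega <- as.numeric(omega)
  entry_width <- as.integer(entry_width)
  if (is.na(m) || m < 1) stop("m must be >= 1")
  if (is.na(k) || k < 1) stop("k must be >= 1")
  if (!phases %in% c(1L, 2L)) stop("phases must be 1 or 2")
  if (is.na(omega) || omega < 0) stop("omega must be >= 0")
  if (!entry_width %in% c(2L, 4L)) stop("entry_width must be 2 or 4")
  if (entry_width == 2L && length(genomes) > 32766L)
    stop("entry_width = 2 supports at most 32,766 genomes")
  tab <- genome_table(genomes)
  if (anyDuplicated(tab$name)) stop("duplicate genome names")
  family <- hash_family(m, n, master_seed)
  canonical <- isTRUE(canonical)

  entries <- integer(m)
  for (r in genomes)
    cpp_process_genome(entries, as.list(r$sequences), r$gid, k, family$seeds,
                       family$m, 1L, omega, canonical)
  signatures <- NULL
  if (phases == 2L) {
    signatures <- vector("list", length(genomes))
    names(signatures) <- tab$name
    for (r in genomes) {
      res <- cpp_process_genome(entries, as.list(r$sequences), r$gid, k,
                                family$seeds, family$m, 2L, omega, canonical)
      signatures[[r$gid]] <- res$selected
    }
  }
  structure(
    list(entries = entries, m = family$m, k = k, family = family,
         genome_table = tab, phases = phases, omega = omega,
         canonical = canonical, entry_width = entry_width,
         signatures = signatures),
    class = "signature_index"
  )
}

#' @export
print.signature_index <- function(x, ...) {
  st <- tabulate(factor(sign(x$entries), levels = c(-1, 0, 1)), nbins = 3)
  cat(sprintf("<signature_index> m = %s entries, k = %d, n = %d, %d genome(s)\n",
              format(x$m, big.mark = ","), x$k, x$family$n, nrow(x$genome_table)))
  cat(sprintf("  phases = %d, omega = %s, canonical = %s, entry width = %d bytes\n",
              x$phases, format(x$omega), x$canonical, x$entry_width))
  cat(sprintf("  entries: %s empty, %s dirty, %s genome-marked\n",
              format(st[2], big.mark = ","), format(st[1], big.mark = ","),
              format(st[3], big.mark = ",")))
  invisible(x)
}

#' Run one marking pass over a single genome
#'
#' Applies the genome-processing pass to a copy of the index: for each valid
#' k-mer the `n` hash positions are looked up; if any entry holds neither 0
#' nor this genome's id the k-mer is non-unique and all its entries are set
#' to -1, otherwise all are stamped with the genome id.  In phase 2 the
#' positions of unique k-mers are collected and, when the index was built
#' with `omega > 0`, thinned at the end of the pass.
#'
#' @param index A `signature_index`.
#' @param genome One record of a [genome_set()] (fields `gid`, `name`,
#'   `sequences`), with `gid` present in the index's genome table.
#' @param phase 1 or 2.
#' @return A list with `index` (the updated copy) and, for phase 2,
#'   `positions` and `selected`: per-contig 0-based signature positions
#'   before and after thinning (`NULL` for phase 1).
#' @export
process_genome <- function(index, genome, phase) {
  stopifnot(inherits(index, "signature_index"))
  if (!genome$gid %in% index$genome_table$gid)
    stop("gid ", genome$gid, " is not in the index genome table")
  phase <- as.integer(phase)
  entries <- copy_entries(index$entries)
  res <- cpp_process_genome(entries, as.list(toupper(genome$sequences)),
                            as.integer(genome$gid), index$k,
                            index$family$seeds, index$m, phase, index$omega,
                            index$canonical)
  index$entries <- entries
  list(index = index,
       positions = if (phase == 2L) res$positions else NULL,
       selected = if (phase == 2L) res$selected else NULL)
}

#' Thin the signatures of one contig
#'
#' Standalone signature-thinning pass on a copy of the index.  The first
#' position is always kept; a later position is kept only when it exceeds the
#' last kept position by more than `omega`.  Dropped positions have all their
#' hash entries dirtied during the scan; kept positions are re-stamped with
#' the genome id afterwards.  The dirty-then-restamp order is preserved from
#' the published procedure: when a dropped k-mer shares hash entries with a
#' kept one, the re-stamp can partially resurrect it.
#'
#' @param index A `signature_index`.
#' @param genome A genome record (single contig used via `contig`).
#' @param positions Ascending 0-based signature positions on that contig.
#' @param omega Spacing (`>= 0`).
#' @param contig Which contig of the genome the positions refer to.
#' @return A list with `index` (updated copy) and `selected` (kept positions).
#' @export
reduce_signatures <- function(index, genome, positions, omega, contig = 1L) {
  stopifnot(inherits(index, "signature_index"))
  if (length(positions) == 0)
    return(list(index = index, selected = integer(0)))
  if (is.unsorted(positions)) stop("positions must be sorted ascending")
  if (omega < 0) stop("omega must be >= 0")
  entries <- copy_entries(index$entries)
  sel <- cpp_reduce(entries, toupper(genome$sequences[[contig]]),
                    as.integer(positions), as.integer(genome$gid), index$k,
                    index$family$seeds, index$m, as.numeric(omega),
                    index$canonical)
  index$entries <- entries
  list(index = index, selected = sel)
}

#' Convert a byte size to an entry count
#'
#' The index size is always specified in entries; this helper converts
#' byte-style sizes such as `"8GB"` given an entry width.
#'
#' @param size A number of bytes or a string like `"512MB"`, `"8GB"`
#'   (binary units: KB = 2^10, MB = 2^20, GB = 2^30).
#' @param entry_width Bytes per entry (4 or 2).
#' @return Number of entries (floored).
#' @examples
#' index_entries_for_bytes("8GB", entry_width = 4)
#' @export
index_entries_for_bytes <- function(size, entry_width = 4L) {
  if (is.character(size)) {
    mm <- regmatches(size, regexec("^\\s*([0-9.]+)\\s*([KMGT]?B?)\\s*$",
                                   toupper(size)))[[1]]
    if (length(mm) == 0) stop("cannot parse size '", size, "'")
    mult <- c(B = 1, KB = 2^10, MB = 2^20, GB = 2^30, TB = 2^40,
              K = 2^10, M = 2^20, G = 2^30, T = 2^40, "1" = 1)
    u <- mm[3]; if (!nzchar(u)) u <- "B"
    size <- as.numeric(mm[2]) * mult[[u]]
  }
  floor(as.numeric(size) / as.integer(entry_width))
}
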