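#' Brute-force enumeration of hash-unique k-mers
#'
#' Test-scale oracle formalizing the definition of a genomic signature: a
#' k-mer of genome `g` is unique iff none of its `n` hash positions is touched
#' by any k-mer occurring in a different genome.  Computed by enumerating the
#' hash footprint of every distinct k-mer of every genome with plain set
#' arithmetic -- no index array, no processing order -- so it is independent
#' of the incremental build it is used to check.  K-mer extraction and
#' reverse-complementation here go through string slicing and Biostrings
#' rather than the package's own C++ path.
#'
#' @param genomes A [genome_set()] (small enough to enumerate).
#' @param family The [hash_family()] under test.
#' @param k K-mer length.
#' @param canonical Canonicalize k-mers as the build would.
#' @return A named list, one element per genome, each a data.frame with
#'   columns `kmer`, `contig`, `pos` (0-based): every occurrence of every
#'   hash-unique k-mer of that genome.
#' @export
oracle_unique_kmers <- function(genomes, family, k, canonical = TRUE) {
  stopifnot(inherits(genomes, "genome_set"), inherits(family, "hash_family"))
  k <- as.integer(k)

  occ <- list()  # per genome: data.frame(kmer, contig, pos)
  for (r in genomes) {
    parts <- list()
    for (ci in seq_along(r$sequences)) {
      s <- r$sequences[[ci]]
      L <- nchar(s)
      if (L < k) next
      starts <- seq_len(L - k + 1L)
      km <- substring(s, starts, starts + k - 1L)
      ok <- !grepl("[^ACGT]", km)
      km <- km[ok]; starts <- starts[ok]
      if (length(km) == 0) next
      if (canonical) {
        rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(km)))
        km <- pmin(km, rc)
      }
      parts[[length(parts) + 1L]] <-
        data.frame(kmer = km, contig = ci, pos = starts - 1L,
                   stringsAsFactors = FALSE)
    }
    occ[[r$name]] <- if (length(parts)) do.call(rbind, parts) else
      data.frame(kmer = character(0), contig = integer(0), pos = integer(0))
  }

  # distinct k-mers per genome and their hash footprints
  distinct <- lapply(occ, function(d) unique(d$kmer))
  gids <- vapply(genomes, `[[`, integer(1), "gid")
  pos_gid <- lapply(seq_along(genomes), function(i) {
    km <- distinct[[i]]
    if (length(km) == 0)
      return(list(pos = numeric(0), kmer_idx = integer(0)))
    H <- hash_kmers(family, km)           # n x N positions
    list(pos = as.vector(H), kmer_idx = rep(seq_along(km), each = family$n))
  })

  # which gids touch each position (set arithmetic over all genomes)
  all_pos <- unlist(lapply(pos_gid, `[[`, "pos"), use.names = FALSE)
  all_gid <- unlist(lapply(seq_along(genomes), function(i)
    rep(gids[i], length(pos_gid[[i]]$pos))), use.names = FALSE)
  pg <- unique(data.frame(pos = all_pos, gid = all_gid))
  multi <- unique(pg$pos[duplicated(pg$pos)])     # touched by >= 2 genomes

  out <- list()
  for (i in seq_along(genomes)) {
    km <- distinct[[i]]
    if (length(km) == 0) {
      out[[genomes[[i]]$name]] <- occ[[i]][0, ]
      next
    }
    foreign <- pos_gid[[i]]$pos %in% multi
    bad_kmer <- unique(pos_gid[[i]]$kmer_idx[foreign])
    uniq <- km[setdiff(seq_along(km), bad_kmer)]
    d <- occ[[i]]
    out[[genomes[[i]]$name]] <- d[d$kmer %in% uniq, , drop = FALSE]
  }
  out
}
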