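#' Generate a synthetic community of reference genomes
#'
#' Draws `n_genomes` i.i.d. uniform A/C/G/T genomes and, when
#' `shared_fraction > 0`, overwrites that fraction of each genome with
#' contiguous blocks copied verbatim from a common pool sequence.  The shared
#' blocks directly control the quantity that matters to signature indexing --
#' the fraction of k-mers shared between genomes -- and so emulate related
#' strains without simulating a phylogeny.  Fully deterministic under `seed`.
#'
#' @param n_genomes Number of genomes.
#' @param genome_length Length in bp, recycled across genomes.
#' @param shared_fraction Fraction of each genome copied from the shared pool,
#'   in `[0, 1)`.
#' @param block_length Length of each copied block (bp).
#' @param seed Seed for all draws.
#' @param names Genome names; default `genome_001`, ...
#' @return A [genome_set()] of single-contig genomes.
#' @examples
#' gs <- generate_community(n_genomes = 5, genome_length = 2000, seed = 42)
#' @export
generate_community <- function(n_genomes = 5L, genome_length = 2000L,
                               shared_fraction = 0, block_length = 500L,
                               seed = 1L, names = NULL) {
  n_genomes <- as.integer(n_genomes)
  if (is.na(n_genomes) || n_genomes < 1) stop("n_genomes must be >= 1")
  if (shared_fraction < 0 || shared_fraction >= 1)
    stop("shared_fraction must be in [0, 1)")
  lengths <- rep_len(as.integer(genome_length), n_genomes)
  if (any(lengths < 1)) stop("genome_length must be >= 1")
  if (is.null(names)) names <- sprintf("genome_%03d", seq_len(n_genomes))

  seqs <- with_seed(seed, {
    # the pool plays the role of a common ancestor: same length as the
    # largest genome, so high shared fractions force overlapping copies
    pool <- random_dna(max(lengths))
    lapply(seq_len(n_genomes), function(i) {
      L <- lengths[i]
      g <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      if (shared_fraction > 0) {
        # copy randomly chosen, tile-aligned blocks from the pool to the same
        # coordinates in the genome (syntenic, as homologous strain regions
        # are), so the shared k-mer fraction between two genomes tracks
        # shared_fraction instead of the accidental overlap of random offsets
        tiles <- seq.int(1L, L, by = block_length)
        n_blocks <- min(ceiling(shared_fraction * L / block_length), length(tiles))
        budget <- round(shared_fraction * L)
        for (t in tiles[sample.int(length(tiles), n_blocks)]) {
          bl <- min(block_length, L - t + 1L, budget)
          if (bl <= 0) break
          g[t:(t + bl - 1L)] <- strsplit(substr(pool, t, t + bl - 1L), "")[[1]]
          budget <- budget - bl
        }
      }
      paste(g, collapse = "")
    })
  })
  base::names(seqs) <- names
  genome_set(seqs)
}

random_dna <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

#' Simulate shotgun reads from a community
#'
#' Draws reads uniformly along each genome to the requested per-genome
#' coverage (`ceiling(coverage * genome_length / read_length)` reads), picks
#' the strand uniformly, and substitutes each base independently with
#' probability `error_rate` for a uniformly chosen different base.  This
#' substitution-only model captures the failure mode that matters for k-mer
#' lookup -- a corrupted k-mer missing its signature or colliding elsewhere --
#' without modelling indels or quality profiles.  A truth table mapping every
#' read to its genome, position and strand is returned alongside.
#'
#' @param genomes A [genome_set()].
#' @param read_length Read length in bp (`>=` the index k for useful queries).
#' @param coverage Per-genome fold coverage.
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param seed Seed for all draws.
#' @param from_gids Restrict the sample to these genome ids (default: all),
#'   emulating a sample containing a subset of the reference community.
#' @return A list with `reads` (named character vector) and `truth`
#'   (data.frame `read_id`, `gid`, `name`, `contig`, `pos` (0-based on the
#'   forward strand), `strand`).
#' @export
simulate_reads <- function(genomes, read_length = 100L, coverage = 2,
                           error_rate = 0.01, seed = 1L, from_gids = NULL) {
  stopifnot(inherits(genomes, "genome_set"))
  read_length <- as.integer(read_length)
  if (is.na(read_length) || read_length < 1) stop("read_length must be >= 1")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  if (coverage <= 0) stop("coverage must be > 0")
  if (is.null(from_gids)) from_gids <- vapply(genomes, `[[`, integer(1), "gid")

  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    all_reads <- character(0)
    truth <- list()
    for (r in genomes) {
      if (!r$gid %in% from_gids) next
      L <- sum(nchar(r$sequences))
      if (all(nchar(r$sequences) < read_length))
        stop("read_length ", read_length, " exceeds every contig of genome '",
             r$name, "'")
      n_reads <- ceiling(coverage * L / read_length)
      starts_per_contig <- pmax(nchar(r$sequences) - read_length + 1L, 0L)
      ctg <- sample.int(length(r$sequences), n_reads, replace = TRUE,
                        prob = starts_per_contig)
      pos <- vapply(ctg, function(ci) sample.int(starts_per_contig[ci], 1L),
                    integer(1))
      strand <- sample(c("+", "-"), n_reads, replace = TRUE)
      sq <- substring(r$sequences[ctg], pos, pos + read_length - 1L)
      rev <- strand == "-"
      if (any(rev))
        sq[rev] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(sq[rev])))
      if (error_rate > 0) {
        mat <- matrix(unlist(strsplit(sq, "")), nrow = read_length)
        hit <- matrix(runif(length(mat)) < error_rate, nrow = read_length)
        if (any(hit)) {
          # substitute with a uniformly chosen different base
          shift <- sample.int(3L, sum(hit), replace = TRUE)
          old <- match(mat[hit], bases)
          mat[hit] <- bases[((old - 1L + shift) %% 4L) + 1L]
        }
        sq <- apply(mat, 2, paste, collapse = "")
      }
      ids <- sprintf("%s_read_%05d", r$name, seq_len(n_reads))
      names(sq) <- ids
      all_reads <- c(all_reads, sq)
      truth[[length(truth) + 1L]] <- data.frame(
        read_id = ids, gid = r$gid, name = r$name, contig = ctg,
        pos = pos - 1L, strand = strand, stringsAsFactors = FALSE)
    }
    list(reads = all_reads, truth = do.call(rbind, truth))
  })
}

#' Write simulated reads (FASTQ/FASTA) and their truth table
#'
#' @param sim Output of [simulate_reads()].
#' @param reads_path Destination for the reads; `.fastq`/`.fq` writes FASTQ
#'   (constant qualities), anything else FASTA.
#' @param truth_path Optional destination for the truth table (TSV).
#' @return Invisibly, `reads_path`.
#' @export
write_reads <- function(sim, reads_path, truth_path = NULL) {
  ss <- Biostrings::DNAStringSet(sim$reads)
  names(ss) <- names(sim$reads)
  if (grepl("\\.(fq|fastq)(\\.gz)?$", reads_path, ignore.case = TRUE)) {
    quals <- Biostrings::BStringSet(strrep("I", nchar(sim$reads)))
    Biostrings::writeXStringSet(ss, reads_path, format = "fastq",
                                qualities = quals)
  } else {
    Biostrings::writeXStringSet(ss, reads_path)
  }
  if (!is.null(truth_path))
    utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(reads_path)
}
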