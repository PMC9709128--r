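# Shared fixtures: everything is generated in code under fixed seeds.

random_kmers <- function(n, k, seed) {
  with_seed(seed, {
    m <- matrix(sample(c("A", "C", "G", "T"), n * k, replace = TRUE), nrow = n)
    apply(m, 1, paste, collapse = "")
  })
}

with_seed <- bloomsig:::with_seed

# standard small community + phase-2 index used by several files
small_index <- function(seed = 1, n = 2, m = 2^16, omega = 0, phases = 2,
                        G = 5, len = 2000, k = 31) {
  gs <- generate_community(n_genomes = G, genome_length = len, seed = seed)
  idx <- build_index(gs, m = m, n = n, k = k, phases = phases, omega = omega,
                     master_seed = seed)
  list(genomes = gs, index = idx)
}

# classification of every distinct k-mer of every genome, as a named list of
# integer call vectors (names are the canonical k-mers)
community_calls <- function(index, genomes) {
  lapply(genomes, function(r) {
    km <- unique(unlist(lapply(r$sequences, function(s)
      extract_kmers(s, index$k, canonical = index$canonical)$kmer)))
    calls <- classify_kmers(index, km)
    names(calls) <- km
    calls
  })
}

# independent reverse complement (Biostrings, not the package's C++ path)
bs_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
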