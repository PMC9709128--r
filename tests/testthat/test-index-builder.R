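test_that("a single genome stamps only its own id, never dirty", {
  gs <- genome_set(list(g1 = "ACGTACGT"))
  idx <- build_index(gs, m = 64, n = 1, k = 4, phases = 1, omega = 0,
                     canonical = FALSE)
  # same-genome re-hits pass the uniqueness test, so no entry can be dirtied
  expect_true(all(idx$entries %in% c(0L, 1L)))
  km <- extract_kmers("ACGTACGT", 4, canonical = FALSE)$kmer
  expect_true(all(classify_kmers(idx, km) == 1L))
})

test_that("two identical genomes annihilate each other's signatures", {
  g <- bloomsig:::with_seed(4, bloomsig:::random_dna(500))
  gs <- genome_set(list(a = g, b = g))
  idx <- build_index(gs, m = 2^16, n = 2, k = 31, phases = 2, omega = 0)
  km <- extract_kmers(g, 31)$kmer
  expect_true(all(classify_kmers(idx, km) == -1L))
  st <- signature_stats(idx, gs)
  expect_equal(st$per_genome$signature_count, c(0, 0))
  expect_setequal(st$zero_signature_genomes, c("a", "b"))
})

test_that("process_genome collects signature positions only in phase 2", {
  fx <- small_index(seed = 2, G = 2, len = 400)
  r <- fx$genomes[[1]]
  p1 <- process_genome(fx$index, r, phase = 1)
  expect_null(p1$positions)
  p2 <- process_genome(fx$index, r, phase = 2)
  expect_true(is.list(p2$positions))
  expect_true(length(p2$positions[[1]]) > 0)
  # positions are ascending 0-based window starts
  expect_true(all(diff(p2$positions[[1]]) > 0))
  expect_gte(min(p2$positions[[1]]), 0)
  expect_error(process_genome(fx$index, list(gid = 99L, name = "x", sequences = "ACGT"), 1),
               "genome table")
})

test_that("a contig shorter than k contributes nothing, without error", {
  gs <- genome_set(list(a = c("ACGTACGTACGTACGTACGTACGTACGTACGTACG", "ACG")))
  idx <- build_index(gs, m = 2^10, n = 1, k = 31, phases = 2, omega = 5)
  expect_s3_class(idx, "signature_index")
  expect_length(idx$signatures[[1]][[2]], 0)  # short contig: empty, reduce skipped
})

test_that("signature thinning keeps omega-spaced positions and dirties the rest", {
  g <- bloomsig:::with_seed(9, bloomsig:::random_dna(60))
  gs <- genome_set(list(solo = g))
  idx <- build_index(gs, m = 2^16, n = 2, k = 31, phases = 2, omega = 0)
  all_pos <- idx$signatures[[1]][[1]]
  expect_equal(all_pos, 0:29)  # single genome: every window is a signature

  red <- reduce_signatures(idx, gs[[1]], positions = c(0L, 5L, 20L), omega = 10)
  expect_equal(red$selected, c(0L, 20L))
  kmer_at <- function(p) substr(g, p + 1, p + 31)
  expect_equal(classify_kmer(red$index, kmer_at(5)), -1L)
  expect_equal(classify_kmer(red$index, kmer_at(0)), 1L)
  expect_equal(classify_kmer(red$index, kmer_at(20)), 1L)

  # single position: kept, nothing dirtied
  red1 <- reduce_signatures(idx, gs[[1]], positions = 7L, omega = 100)
  expect_equal(red1$selected, 7L)
  expect_equal(classify_kmer(red1$index, kmer_at(3)), 1L)

  # omega = 0 with strictly increasing positions selects everything
  red0 <- reduce_signatures(idx, gs[[1]], positions = all_pos, omega = 0)
  expect_equal(red0$selected, all_pos)
  expect_identical(red0$index$entries, idx$entries)

  # empty positions: no-op
  red_e <- reduce_signatures(idx, gs[[1]], positions = integer(0), omega = 10)
  expect_equal(red_e$selected, integer(0))
})

test_that("with one hash function the index matches the brute-force oracle exactly", {
  for (seed in 1:3) {
    fx <- small_index(seed = seed, n = 1, m = 2^16)
    orc <- oracle_unique_kmers(fx$genomes, fx$index$family, 31)
    calls <- community_calls(fx$index, fx$genomes)
    for (i in seq_along(fx$genomes)) {
      uniq <- sort(unique(orc[[i]]$kmer))
      expect_equal(sort(names(calls[[i]])[calls[[i]] == i]), uniq)
      expect_true(all(calls[[i]][!names(calls[[i]]) %in% uniq] == -1L))
    }
  }
})

test_that("a k-mer marked with a genome id is always hash-unique to that genome", {
  # the one-sided guarantee of the two-phase build: marked => oracle-unique;
  # and a community k-mer never classifies to a genome it does not belong to
  for (seed in 4:5) {
    fx <- small_index(seed = seed, n = 2, m = 2^16)
    orc <- oracle_unique_kmers(fx$genomes, fx$index$family, 31)
    calls <- community_calls(fx$index, fx$genomes)
    for (i in seq_along(fx$genomes)) {
      expect_true(all(calls[[i]] %in% c(-1L, i)))
      marked <- names(calls[[i]])[calls[[i]] == i]
      expect_true(all(marked %in% orc[[i]]$kmer))
    }
  }
})

test_that("dirty entries never turn positive within a phase", {
  gs <- generate_community(4, 800, seed = 6)
  idx0 <- build_index(gs, m = 2^12, n = 2, k = 31, phases = 1, omega = 0)
  # replay phase 1 genome by genome and watch entry transitions
  idx <- idx0
  idx$entries <- integer(idx$m)
  prev <- idx$entries
  for (r in gs) {
    idx <- process_genome(idx, r, phase = 1)$index
    was_dirty <- prev == -1L
    expect_true(all(idx$entries[was_dirty] == -1L))
    prev <- idx$entries
  }
  expect_identical(idx$entries, idx0$entries)
})

test_that("degenerate builds are legal and duplicate names are not", {
  gs <- generate_community(3, 300, seed = 8)
  tiny <- build_index(gs, m = 4, n = 2, k = 31, phases = 2, omega = 0)
  expect_true(all(tiny$entries != 0))  # legal: index may be all dirty
  expect_error(genome_set(list(a = "ACGT", a = "ACGT")), "duplicate")
})

test_that("byte sizes convert to entry counts given the entry width", {
  expect_equal(index_entries_for_bytes("8GB", 4), 2^31)
  expect_equal(index_entries_for_bytes("8GB", 2), 2^32)
  expect_equal(index_entries_for_bytes(1024, 4), 256)
  expect_error(index_entries_for_bytes("eight GB"), "parse")
})
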