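test_that("per-k-mer calls follow the any-zero / unanimous / dirty rule", {
  fx <- small_index(seed = 7, G = 2, len = 300, m = 2^16, n = 2)
  idx <- fx$index
  key <- random_kmers(50, 31, seed = 20)
  # pick a key whose two hash positions are distinct and set its entries
  H <- bloomsig:::hash_kmers(idx$family, canonical_kmers(key))
  j <- which(H[1, ] != H[2, ])[1]
  pos <- H[, j] + 1
  key <- key[j]

  set_entries <- function(vals) {
    idx$entries[pos] <- vals
    idx
  }
  expect_equal(classify_kmer(set_entries(c(0L, 0L)), key), 0L)
  expect_equal(classify_kmer(set_entries(c(7L, 0L)), key), 0L)   # any zero: absent
  expect_equal(classify_kmer(set_entries(c(7L, 7L)), key), 7L)
  expect_equal(classify_kmer(set_entries(c(7L, -1L)), key), -1L)
  expect_equal(classify_kmer(set_entries(c(7L, 3L)), key), -1L)
  expect_equal(classify_kmer(set_entries(c(-1L, -1L)), key), -1L)
  expect_error(classify_kmer(idx, "ACGT"), "length")
})

test_that("the three strategies aggregate a call multiset as specified", {
  # the worked example: majority 3/4 positives -> G1, first positive -> G2,
  # two distinct positives -> discard
  V <- c(2L, 1L, 1L, 1L, -1L)
  expect_equal(assign_from_calls(V, "majority"), 1L)
  expect_equal(assign_from_calls(V, "first_hit"), 2L)
  expect_true(is.na(assign_from_calls(V, "one_or_nothing")))

  expect_true(is.na(assign_from_calls(c(1L, 2L), "majority")))      # exact tie
  expect_true(is.na(assign_from_calls(c(0L, -1L, 0L), "majority"))) # no positives
  expect_equal(assign_from_calls(c(1L, 1L, -1L, 0L), "one_or_nothing"), 1L)
  expect_true(is.na(assign_from_calls(c(2L, 1L, 1L), "one_or_nothing")))
  expect_equal(assign_from_calls(c(0L, 0L, 0L, 3L), "first_hit"), 3L)
  expect_true(is.na(assign_from_calls(c(0L, -1L), "first_hit")))
})

test_that("strategy algebra holds on random call multisets", {
  with_seed(31, {
    for (rep in 1:300) {
      V <- sample(c(-1L, 0L, 1L, 2L, 3L), sample(1:12, 1), replace = TRUE)
      m <- assign_from_calls(V, "majority")
      f <- assign_from_calls(V, "first_hit")
      o <- assign_from_calls(V, "one_or_nothing")
      if (!is.na(o)) expect_identical(m, o)  # one-or-nothing implies majority
      pos <- unique(V[V > 0])
      if (length(pos) == 1) {
        expect_identical(m, pos); expect_identical(f, pos); expect_identical(o, pos)
      }
      if (length(pos) == 0) {
        expect_true(is.na(m) && is.na(f) && is.na(o))
      }
    }
  })
})

test_that("reads shorter than k are discarded with a note", {
  fx <- small_index(seed = 8, G = 2, len = 300)
  r <- classify_read(fx$index, "ACGTACGT", "majority")
  expect_true(is.na(r$gid))
  expect_message(query_sample(fx$index, c(r1 = "ACGTAC")), "shorter than k")
})

test_that("error-free reads from a single-genome index always hit gid 1", {
  gs <- generate_community(1, 2000, seed = 14)
  idx <- build_index(gs, m = 2^18, n = 2, k = 31, omega = 0)
  sim <- simulate_reads(gs, 100, 2, 0, seed = 15)
  for (strat in c("majority", "first_hit", "one_or_nothing")) {
    asn <- query_sample(idx, sim$reads, strat)
    expect_true(all(asn$gid == 1L))
  }
})

test_that("the first-hit fast path agrees with a full scan", {
  fx <- small_index(seed = 9)
  sim <- simulate_reads(fx$genomes, 100, 1, 0.05, seed = 16)
  fast <- query_sample(fx$index, sim$reads, "first_hit")
  slow <- vapply(sim$reads, function(s) {
    calls <- bloomsig:::cpp_classify_sequence(
      fx$index$entries, s, fx$index$k, fx$index$family$seeds, fx$index$m,
      fx$index$canonical)
    assign_from_calls(calls, "first_hit")
  }, integer(1), USE.NAMES = FALSE)
  expect_identical(fast$gid, slow)
  expect_true(all(is.na(fast$n_positive)))  # counts unreported on the fast path
})

test_that("read sampling is a seeded Bernoulli and classification is order-free", {
  fx <- small_index(seed = 10)
  sim <- simulate_reads(fx$genomes, 100, 2, 0.01, seed = 17)
  a1 <- query_sample(fx$index, sim$reads, "majority", sample_fraction = 0.5, seed = 7)
  a2 <- query_sample(fx$index, sim$reads, "majority", sample_fraction = 0.5, seed = 7)
  expect_identical(a1, a2)
  expect_lt(nrow(a1), length(sim$reads))
  a3 <- query_sample(fx$index, sim$reads, "majority", sample_fraction = 0.5, seed = 8)
  expect_false(identical(a1$read_id, a3$read_id))

  serial <- query_sample(fx$index, sim$reads, "majority")
  threaded <- query_sample(fx$index, sim$reads, "majority", threads = 2)
  expect_identical(serial, threaded)

  expect_error(query_sample(fx$index, sim$reads, "best_guess"))
  expect_error(query_sample(fx$index, sim$reads, sample_fraction = 0), "sample_fraction")
})

test_that("canonical indexing is what rescues reverse-strand reads", {
  gs <- generate_community(1, 3000, seed = 18)
  sim <- simulate_reads(gs, 100, 2, 0, seed = 19)
  rev_reads <- sim$reads[sim$truth$strand == "-"]
  expect_gt(length(rev_reads), 10)

  idx_can <- build_index(gs, m = 2^20, n = 2, k = 31, omega = 0, canonical = TRUE)
  idx_raw <- build_index(gs, m = 2^20, n = 2, k = 31, omega = 0, canonical = FALSE)
  hit_can <- mean(!is.na(query_sample(idx_can, rev_reads, "first_hit")$gid))
  hit_raw <- mean(!is.na(query_sample(idx_raw, rev_reads, "first_hit")$gid))
  expect_equal(hit_can, 1)
  # residual raw-index hits can only come from chance hash coincidences
  expect_lt(hit_raw, 0.05)
})

test_that("assignments are written as TSV with '-' for discards", {
  fx <- small_index(seed = 11, G = 2, len = 300)
  asn <- data.frame(read_id = c("r1", "r2"), strategy = "majority",
                    gid = c(2L, NA), n_positive = c(5L, 0L), n_total = c(70L, 70L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_assignments(asn, f)
  got <- read.table(f, header = TRUE, sep = "\t", colClasses = "character")
  expect_equal(got$gid, c("2", "-"))
})
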