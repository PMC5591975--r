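test_that("genome simulation is seed-deterministic and alphabet-clean", {
  expect_identical(random_genome(100, 7), random_genome(100, 7))
  g <- random_genome(1e4, 1)
  expect_equal(nchar(g), 1e4)
  expect_false(grepl("[^ACGT]", g))
  expect_false(random_genome(500, 1) == random_genome(500, 2))
  # caller RNG state untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(random_genome(50, 3)); after <- runif(1)
  expect_identical(before, after)
})

test_that("error-free reads are genome substrings; parameters do what they say", {
  genome <- random_genome(2000, 11)
  reads <- sample_reads(genome, 50, 80, error_rate = 0, n_rate = 0, seed = 2)
  expect_true(all(vapply(reads, grepl, TRUE, x = genome, fixed = TRUE)))
  # and their k-mers are a subset of genome k-mers
  gk <- oracle_kmers(kmer_oracle(genome, 21))$kmer
  rk <- oracle_kmers(kmer_oracle(reads, 21))$kmer
  expect_true(all(rk %in% gk))

  expect_identical(sample_reads(genome, 20, 60, 0.02, 0.01, seed = 5),
                   sample_reads(genome, 20, 60, 0.02, 0.01, seed = 5))
  allN <- sample_reads(genome, 5, 50, 0, n_rate = 1, seed = 3)
  expect_true(all(allN == strrep("N", 50)))
  expect_equal(nrow(oracle_kmers(kmer_oracle(allN, 5))), 0L)
  # substitutions hit roughly the requested fraction of bases
  mut <- sample_reads(genome, 100, 100, error_rate = 0.1, n_rate = 0, seed = 8)
  ref <- sample_reads(genome, 100, 100, error_rate = 0, n_rate = 0, seed = 8)
  frac <- mean(mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, mut, ref)) / 100
  expect_gt(frac, 0.07); expect_lt(frac, 0.13)
})
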