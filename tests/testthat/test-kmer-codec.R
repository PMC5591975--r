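test_that("base and k-mer encoding follow the A=0,C=1,G=2,T=3 big-endian convention", {
  expect_identical(havec:::cpp_encode_bases(c("A", "C", "G", "T")), 0:3)
  expect_identical(havec:::cpp_encode_bases(c("a", "t")), c(0L, 3L))
  expect_error(havec:::cpp_encode_bases("N"), "ambiguous base")

  expect_identical(encode_kmers("AAAAA"), "0")
  expect_identical(encode_kmers("GGCAA"), "656")  # 2,2,1,0,0 in base 4
  expect_identical(encode_kmers("TTTTT"), as.character(4^5 - 1))
  expect_identical(decode_kmers("656", 5), "GGCAA")
  expect_error(encode_kmers(strrep("A", 33)), "k out of range")
  expect_error(encode_kmers("ACGTN"), "ambiguous base")
  expect_identical(encode_kmers("ggcaa"), "656")  # lowercase accepted
})

test_that("encode/decode round-trips across the full k range", {
  for (k in c(1, 5, 27, 32)) {
    kmers <- unique(random_kmers(500, k, seed = 100 + k))
    expect_identical(decode_kmers(encode_kmers(kmers), k), kmers)
  }
  # k = 32 exercises the full 64-bit code space beyond double precision
  expect_identical(encode_kmers(strrep("T", 32)), "18446744073709551615")
})

test_that("window extraction yields the documented k-mer walk of a read", {
  df <- extract_kmers("GGCAATTGTGTGTCG", 5)
  expect_identical(df$kmer,
                   c("GGCAA", "GCAAT", "CAATT", "AATTG", "ATTGT", "TTGTG",
                     "TGTGT", "GTGTG", "TGTGT", "GTGTC", "TGTCG"))
  expect_identical(df$next_base,
                   c("T", "T", "G", "T", "G", "T", "G", "T", "C", "G", NA))
  expect_identical(nrow(extract_kmers("ACGT", 5)), 0L)   # shorter than k
  expect_identical(extract_kmers("ACNGT", 2)$kmer, c("AC", "GT"))
})

test_that("window extraction agrees with an independent substring scan", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      k <- sample(c(2, 5, 11), 1)
      read <- paste(sample(c("A", "C", "G", "T", "N", "a", "g"),
                           sample(5:60, 1), replace = TRUE), collapse = "")
      got <- extract_kmers(read, k)
      want <- r_window_scan(read, k)
      expect_equal(got$kmer, want$kmer, info = read)
      expect_equal(got$next_base, want$next_base, info = read)
      expect_equal(got$pos, want$pos, info = read)
    }
  })
  # window count: clean read of length L gives L - k + 1 windows
  read <- random_genome(300, 9)
  expect_identical(nrow(extract_kmers(read, 21)), 280L)
})

test_that("successor generation drops the first base and appends in ACGT order", {
  expect_identical(kmer_successors("GGCAA", "T"), "GCAAT")
  expect_identical(kmer_successors("TGTGT", "GC"), c("GTGTC", "GTGTG"))
  expect_identical(kmer_successors("ACGTA", ""), character(0))
  # all four successors overlap the source by k-1
  for (km in random_kmers(20, 7, seed = 3)) {
    succ <- kmer_successors(km, "ACGT")
    expect_length(succ, 4)
    expect_true(all(substr(succ, 1, 6) == substr(km, 2, 7)))
  }
})
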