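test_that("hash families are deterministic in the master seed", {
  f1 <- hash_family(2, 42)
  f2 <- hash_family(2, 42)
  kms <- random_kmers(50, 9, seed = 1)
  expect_identical(hash_values(f1, 1, kms), hash_values(f2, 1, kms))
  expect_identical(hash_values(f1, 2, kms), hash_values(f2, 2, kms))
  # different seeds give different functions
  g1 <- hash_family(4, 1)
  g2 <- hash_family(4, 2)
  kms <- random_kmers(100, 9, seed = 2)
  expect_true(any(hash_values(g1, 1, kms) != hash_values(g2, 1, kms)))
  expect_error(hash_family(8, 0), "hash-function count unsupported")
  expect_error(hash_family(0, 0), "hash-function count unsupported")
})

test_that("each function is a bijection: exhaustive at k = 5, sampled at k = 32", {
  fam <- hash_family(4, 7)
  kms <- all_kmers(5)
  for (i in 1:4) {
    v <- hash_values(fam, i, kms)
    expect_false(anyDuplicated(v) > 0)            # injective on 4^5 codes
    expect_identical(hash_invert(fam, i, v, 5), kms)  # and invertible
  }
  for (k in c(1, 13, 27, 32)) {
    kms <- unique(random_kmers(1000, k, seed = k))
    v <- hash_values(fam, 2, kms)
    expect_identical(hash_invert(fam, 2, v, k), kms)
  }
})

test_that("hash values stay within 2k bits so the minimum-table-size bound is exact", {
  fam <- hash_family(3, 5)
  for (k in c(5, 16, 25)) {
    v <- as.numeric(hash_values(fam, 1, random_kmers(300, k, seed = k)))
    expect_true(all(v < 4^k))
  }
  # with M = 2^(2k-33) every quotient fits 33 bits (k = 32 boundary)
  v <- hash_values(fam, 1, random_kmers(500, 32, seed = 11))
  q <- split_hash(v, 2^31)$quotient
  expect_true(max(q) <= 2^33 - 1)
})

test_that("index/quotient decomposition reconstructs the hash value", {
  expect_equal(split_hash(57, 11), data.frame(index = 2, quotient = 5))
  expect_equal(split_hash(36, 11), data.frame(index = 3, quotient = 3))
  expect_equal(split_hash(0, 123), data.frame(index = 0, quotient = 0))
  expect_error(split_hash(57, 0), "invalid table size")
  # full-64-bit reconstruction check runs in native integers
  expect_true(havec:::cpp_index_quotient_roundtrip(10000L, 5))
  withr::with_seed(8, {
    v <- sample.int(.Machine$integer.max, 200)
    m <- sample.int(5000, 200)
    iq <- split_hash(v, 1)  # M = 1: index 0, quotient = value
    expect_true(all(iq$index == 0) && all(iq$quotient == v))
    for (j in 1:20) {
      iq <- split_hash(v, m[j])
      expect_equal(iq$quotient * m[j] + iq$index, v)
    }
  })
})

test_that("stipulated families look values up verbatim and reject unknown queries", {
  tab <- data.frame(fun = c(1, 1, 2), kmer = c("GGCAA", "CAATT", "CAATT"),
                    value = c(57, 24, 36))
  fam <- stipulated_hash_family(tab, h = 2)
  expect_identical(hash_values(fam, 1, "GGCAA"), "57")
  expect_identical(hash_values(fam, 2, "CAATT"), "36")
  expect_identical(hash_invert(fam, 1, 57, 5), "GGCAA")
  expect_error(hash_values(fam, 1, "AAAAA"), "unstipulated hash query")
  expect_error(hash_values(fam, 2, "GGCAA"), "unstipulated hash query")
  # a non-injective stipulation is rejected outright
  expect_error(stipulated_hash_family(
    data.frame(fun = c(1, 1), kmer = c("AA", "AC"), value = c(9, 9))),
    "not injective")
})
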