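test_that("records land in bucket ht_index %% V and share buckets by index", {
  av <- aux_vector(3)
  expect_true(aux_insert(av, ht_index = 5, quotient = 2, hf = 2, neighbours = "G"))
  df <- aux_records(av)
  expect_equal(df$bucket, 2)       # 5 %% 3
  expect_equal(df$ht_index, 5)
  expect_identical(df$neighbours, "G")
  # a second table index mapping to the same bucket gets its own sublist
  expect_true(aux_insert(av, ht_index = 8, quotient = 3, hf = 2))
  df <- aux_records(av)
  expect_equal(sort(df$ht_index[df$bucket == 2]), c(5, 8))
  # same (ht_index, quotient) twice: single record
  expect_false(aux_insert(av, ht_index = 5, quotient = 2, hf = 2))
  expect_equal(aux_stats(av)$records, 2)
})

test_that("lookups return exactly the inserted (ht_index, quotient) record", {
  av <- aux_vector(3)
  aux_insert(av, 5, 2, 2, "G")
  rec <- aux_lookup(av, 5, 2)
  expect_identical(rec$neighbours, "G")
  expect_equal(rec$hf, 2)
  expect_null(aux_lookup(av, 5, 99))
  expect_null(aux_lookup(aux_vector(4), 1, 1))
})

test_that("random insert/lookup agrees with a plain map", {
  withr::with_seed(31, {
    av <- aux_vector(7)
    truth <- new.env(parent = emptyenv())
    for (j in 1:2000) {
      ht <- sample(0:40, 1)
      q <- sample(0:15, 1)
      key <- paste(ht, q)
      if (runif(1) < 0.5) {
        created <- aux_insert(av, ht, q, hf = 3)
        expect_identical(created, !exists(key, envir = truth))
        assign(key, TRUE, envir = truth)
      } else {
        expect_identical(!is.null(aux_lookup(av, ht, q)),
                         exists(key, envir = truth))
      }
    }
    expect_equal(aux_stats(av)$records, length(ls(truth)))
    # every stored ht_index sits in its own bucket
    df <- aux_records(av)
    expect_true(all(df$bucket == df$ht_index %% 7))
  })
})

test_that("occupancy statistics count records, per-index and per-bucket maxima", {
  av <- aux_vector(4)
  s <- aux_stats(av)
  expect_equal(c(s$records, s$max_records_per_index, s$max_indices_per_bucket),
               c(0, 0, 0))
  aux_insert(av, 1, 1, 2)
  s <- aux_stats(av)
  expect_equal(c(s$records, s$max_records_per_index, s$max_indices_per_bucket),
               c(1, 1, 1))
  aux_insert(av, 1, 2, 2)   # second collided k-mer at the same table index
  aux_insert(av, 5, 1, 2)   # second table index in bucket 1
  s <- aux_stats(av)
  expect_equal(s$records, 3)
  expect_equal(s$max_records_per_index, 2)
  expect_equal(s$max_indices_per_bucket, 2)
})
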