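test_that("fresh tables are all-free and bit-exactly sized", {
  t5 <- packed_table(11, bytes = 5)
  expect_equal(table_info(t5)$nbytes, 55)   # 40 bits per entry
  t6 <- packed_table(1, bytes = 6)
  expect_equal(table_info(t6)$nbytes, 6)
  e <- table_read_slot(t5, 0)
  expect_equal(e$quotient, 0)
  expect_equal(e$hf, 0)
  expect_identical(e$neighbours, "")
  expect_error(packed_table(0), "table size")
})

test_that("pack/unpack is the identity on every representable entry", {
  # the free entry is the all-zero byte pattern
  expect_identical(pack_entry(0, 0, "", count = 0, bytes = 5), as.raw(rep(0, 5)))
  withr::with_seed(21, {
    for (j in 1:400) {
      q <- floor(runif(1) * 2^33)
      hf <- sample(0:7, 1)
      nb <- paste(sample(c("A", "C", "G", "T"), sample(0:4, 1)), collapse = "")
      ct <- sample(0:255, 1)
      for (bytes in 5:6) {
        raw <- pack_entry(q, hf, nb, ct, bytes)
        expect_length(raw, bytes)
        e <- unpack_entry(raw)
        expect_equal(e$quotient, q)
        expect_equal(e$hf, hf)
        expect_identical(e$neighbours, paste(sort(strsplit(nb, "")[[1]]), collapse = ""))
        if (bytes == 6) expect_equal(e$count, ct) else expect_true(is.na(e$count))
      }
    }
  })
  expect_equal(unpack_entry(pack_entry(2^33 - 1, 7, "ACGT", 255, 6))$quotient,
               2^33 - 1)
  expect_error(pack_entry(2^33, 1, ""), "quotient overflow")
})

test_that("slot writes are isolated and bounds-checked", {
  t <- packed_table(11)
  table_write_slot(t, 2, quotient = 5, hf = 1, neighbours = "T")
  e <- table_read_slot(t, 2)
  expect_equal(e$quotient, 5)
  expect_equal(e$hf, 1)
  expect_identical(e$neighbours, "T")
  expect_equal(table_read_slot(t, 3)$hf, 0)  # untouched neighbour slot
  expect_error(table_read_slot(t, 11), "out of range")
  expect_error(table_write_slot(t, 11, 0, 1), "out of range")
})

test_that("neighbour-bit updates are idempotent and refuse free slots", {
  t <- packed_table(4)
  table_write_slot(t, 1, quotient = 3, hf = 2, neighbours = "G")
  table_or_neighbour(t, 1, "C")
  expect_identical(table_read_slot(t, 1)$neighbours, "CG")
  table_or_neighbour(t, 1, "C")
  expect_identical(table_read_slot(t, 1)$neighbours, "CG")
  expect_error(table_or_neighbour(t, 0, "A"), "free entry")
})

test_that("the count byte saturates at 255 and needs 6-byte mode", {
  t <- packed_table(2, bytes = 6)
  table_write_slot(t, 0, quotient = 1, hf = 1, count = 254)
  table_bump_count(t, 0)
  expect_equal(table_read_slot(t, 0)$count, 255)
  table_bump_count(t, 0)
  expect_equal(table_read_slot(t, 0)$count, 255)  # saturated
  t5 <- packed_table(2, bytes = 5)
  table_write_slot(t5, 0, quotient = 1, hf = 1)
  expect_error(table_bump_count(t5, 0), "counts unavailable")
})
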