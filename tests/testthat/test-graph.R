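test_that("table-size validation enforces the 33-bit quotient floor", {
  expect_equal(min_table_size(32), 2^31)
  expect_equal(min_table_size(25), 2^17)
  expect_equal(min_table_size(16), 1)
  # creation is cheap even at the k = 32 floor: segments allocate on write
  expect_s3_class(havec(32, 2^31, h = 2), "havec")
  expect_error(havec(32, 2^31 - 1, h = 2), "table too small for 33-bit quotients")
  expect_s3_class(havec(25, 2^17, h = 2), "havec")
  expect_error(havec(25, 2^17 - 1, h = 2), "table too small")
  expect_error(havec(0, 10), "k out of range")
  expect_error(havec(5, 10, h = 8), "hash-function count")
  expect_equal(recommend_table_size(1000, 15), 1400)
  expect_equal(recommend_table_size(1000, 27), 2^21)  # floor dominates
})

test_that("the worked example builds to its documented table and vector state", {
  g <- build_wex()
  rep <- havec_build(havec(5, 11, 2, vector_size = 3,
                           family = worked_example()$family),
                     worked_example()$read)
  expect_equal(rep$observations, 11)
  expect_equal(rep$distinct_kmers, 10)

  t <- graph_table(g)
  slot <- function(i) table_read_slot(t, i)[c("quotient", "hf", "neighbours")]
  expect_equal(slot(0), list(quotient = 2, hf = 1, neighbours = "T"))
  expect_equal(slot(2), list(quotient = 5, hf = 1, neighbours = "T"))
  expect_equal(slot(3), list(quotient = 3, hf = 2, neighbours = "G"))
  expect_equal(slot(5), list(quotient = 2, hf = 1, neighbours = "T"))
  expect_equal(slot(8), list(quotient = 4, hf = 1, neighbours = "T"))
  # free slots stay free
  for (i in c(4, 6, 7, 9, 10)) expect_equal(table_read_slot(t, i)$hf, 0)
  # TGTGT lands at slot 1 (its first probe finds it free at insertion time)
  # with both observed neighbours; TGTCG then spills to the vector
  expect_equal(slot(1), list(quotient = 3, hf = 1, neighbours = "CG"))

  av <- aux_records(graph_aux(g))
  attgt <- av[av$ht_index == 5, ]
  expect_equal(attgt$bucket, 2)
  expect_equal(attgt[, c("quotient", "hf", "neighbours")],
               data.frame(quotient = 2, hf = 2, neighbours = "G"),
               ignore_attr = TRUE)
  s <- havec_stats(g)
  expect_equal(s$table_kmers + s$vector_kmers, 10)
})

test_that("locate reports the exact storage location or absence", {
  g <- build_wex()
  loc <- havec_locate(g, c("GCAAT", "ATTGT", "AAAAA"))
  expect_equal(loc$kind, c("table", "vector", "absent"))
  expect_equal(loc$index[1], 5)
  expect_equal(loc$bucket[2], 2)
  expect_equal(loc$ht_index[2], 5)
  expect_equal(loc$hf[1:2], c(1L, 2L))
})

test_that("membership is exact over the whole k = 5 universe", {
  g <- build_wex()
  inserted <- c("GGCAA", "GCAAT", "CAATT", "AATTG", "ATTGT", "TTGTG",
                "TGTGT", "GTGTG", "GTGTC", "TGTCG")
  expect_true(all(havec_contains(g, inserted)))
  # with a mixing family we can sweep all 1024 k-mers
  reads <- "GGCAATTGTGTGTCG"
  g2 <- havec(5, 11, h = 2, vector_size = 3, seed = 19)
  havec_build(g2, reads)
  universe <- all_kmers(5)
  expect_identical(havec_contains(g2, universe), universe %in% inserted)
})

test_that("successor and predecessor queries return exactly the observed edges", {
  g <- build_wex()
  expect_identical(havec_successors(g, "GGCAA"), "GCAAT")
  expect_identical(havec_successors(g, "TGTGT"), c("GTGTC", "GTGTG"))
  expect_identical(havec_successors(g, "TGTCG"), character(0))
  expect_identical(havec_predecessors(g, "GCAAT"), "GGCAA")
  expect_identical(havec_predecessors(g, "GGCAA"), character(0))
  expect_identical(havec_predecessors(g, "TGTGT"), c("GTGTG", "TTGTG"))
  expect_error(havec_successors(g, "AAAAA"), "not in graph")
  # closure: every successor is itself present
  for (km in c("GGCAA", "GCAAT", "CAATT", "TGTGT"))
    expect_true(all(havec_contains(g, havec_successors(g, km))))
})

test_that("repeat observations update neighbours in place, never duplicate", {
  ex <- worked_example()
  g <- havec(ex$k, ex$M, ex$h, vector_size = ex$V, family = ex$family)
  havec_build(g, ex$read)
  n1 <- havec_stats(g)$distinct_kmers
  havec_build(g, ex$read)  # same read again
  s <- havec_stats(g)
  expect_equal(s$distinct_kmers, n1)
  expect_equal(s$observations, 22)
  # single-observation path: a new following base ORs into the same entry
  loc1 <- havec_insert(g, "TGTCG", "A")
  expect_equal(loc1$kind, "vector")
  expect_identical(havec_successors(g, "TGTCG"), "GTCGA")
})

test_that("counting mode tracks multiplicities and drives cutoff queries", {
  g <- build_wex(counts = TRUE)
  km <- havec_kmers(g)
  expect_equal(km$count[km$kmer == "TGTGT"], 2L)
  expect_true(all(km$count[km$kmer != "TGTGT"] == 1L))
  # cutoff 2 keeps only the k-mer observed twice
  expect_identical(km$kmer[havec_contains(g, km$kmer, cutoff = 2)], "TGTGT")
  # and cutoff filtering is query-time only: nothing was dropped
  expect_true(all(havec_contains(g, km$kmer)))
  # suppressed successors are excluded so traversal stays closed
  expect_identical(havec_successors(g, "TGTGT", cutoff = 2), character(0))
  g5 <- build_wex(counts = FALSE)
  expect_error(havec_contains(g5, "TGTGT", cutoff = 2), "counts unavailable")
})

test_that("enumeration by hash inversion recovers every stored k-mer exactly once", {
  g <- build_wex()
  km <- havec_kmers(g)
  expect_equal(sort(km$kmer),
               sort(c("GGCAA", "GCAAT", "CAATT", "AATTG", "ATTGT", "TTGTG",
                      "TGTGT", "GTGTG", "GTGTC", "TGTCG")))
  expect_false(anyDuplicated(km$kmer) > 0)
  empty <- havec(5, 11, h = 2, vector_size = 3, seed = 1)
  expect_equal(nrow(havec_kmers(empty)), 0L)
  # synthetic genome at k = 27: enumeration equals the oracle key set
  case <- random_case(27, seed = 50, genome_len = 3000, n_reads = 150)
  expect_setequal(havec_kmers(case$graph)$kmer, oracle_kmers(case$oracle)$kmer)
})

test_that("graphs agree with the brute-force oracle on everything", {
  for (k in c(5, 15, 27)) {
    case <- random_case(k, seed = 60 + k)
    expect_equal(nrow(compare_graph(case$graph, case$oracle)), 0, info = k)
    s <- havec_stats(case$graph)
    expect_equal(s$table_kmers + s$vector_kmers, case$distinct, info = k)
  }
  # counting mode: counts equal oracle multiplicities (capped at 255)
  case <- random_case(11, seed = 77, counts = TRUE, n_reads = 400,
                      genome_len = 2000)
  expect_equal(nrow(compare_graph(case$graph, case$oracle)), 0)
  ok <- oracle_kmers(case$oracle)
  gk <- havec_kmers(case$graph)
  m <- match(gk$kmer, ok$kmer)
  expect_equal(gk$count, as.integer(pmin(ok$count[m], 255)))
})

test_that("k = 31 and k = 32 builds at the minimum table size stay exact", {
  reads <- sample_reads(random_genome(4000, 5), 150, 80, 0.01, 0, seed = 6)
  for (k in c(31, 32)) {
    o <- kmer_oracle(reads, k)
    g <- havec(k, min_table_size(k), h = 2, seed = 13)
    havec_build(g, reads)
    expect_equal(nrow(compare_graph(g, o)), 0, info = k)
    absent <- setdiff(random_kmers(2000, k, seed = 14), oracle_kmers(o)$kmer)
    expect_false(any(havec_contains(g, absent)))
    rm(g); gc()
  }
})

test_that("read order changes locations but never answers", {
  reads <- sample_reads(random_genome(2000, 23), 120, 60, 0.01, 0, seed = 24)
  k <- 13
  o <- kmer_oracle(reads, k)
  g1 <- havec(k, 4096, h = 3, seed = 9)
  havec_build(g1, reads)
  g2 <- havec(k, 4096, h = 3, seed = 9)
  havec_build(g2, rev(reads))
  expect_equal(nrow(compare_graph(g1, o)), 0)
  expect_equal(nrow(compare_graph(g2, o)), 0)
  k1 <- havec_kmers(g1); k2 <- havec_kmers(g2)
  expect_setequal(k1$kmer, k2$kmer)
  m <- match(k1$kmer, k2$kmer)
  expect_identical(k1$neighbours, k2$neighbours[m])
  probe <- k1$kmer[1:20]
  for (km in probe)
    expect_identical(havec_successors(g1, km), havec_successors(g2, km))
})

test_that("growing the table moves k-mers out of the vector, never into it", {
  reads <- sample_reads(random_genome(8000, 41), 300, 100, 0.01, 0, seed = 42)
  k <- 15
  n <- nrow(oracle_kmers(kmer_oracle(reads, k)))
  M0 <- ceiling(0.5 * n)
  spill <- vapply(0:5, function(step) {
    g <- havec(k, ceiling(M0 * 1.05^step), h = 2, seed = 3)
    havec_build(g, reads)
    havec_stats(g)$vector_kmers
  }, numeric(1))
  expect_true(all(diff(spill) <= 0))
  expect_gt(spill[1], 0)  # the starting table is genuinely undersized
})
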