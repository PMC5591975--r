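test_that("the oracle counts windows and successor sets by brute force", {
  o <- kmer_oracle("GGCAATTGTGTGTCG", 5)
  df <- oracle_kmers(o)
  expect_equal(nrow(df), 10)
  expect_equal(df$count[df$kmer == "TGTGT"], 2)
  expect_identical(df$neighbours[df$kmer == "TGTGT"], "CG")
  expect_identical(df$neighbours[df$kmer == "TGTCG"], "")
  expect_equal(nrow(oracle_kmers(kmer_oracle(character(0), 5))), 0L)
  one <- oracle_kmers(kmer_oracle("ACGTA", 5))
  expect_equal(nrow(one), 1L)
  expect_identical(one$neighbours, "")
})

test_that("oracle window semantics match an independent substring scan", {
  withr::with_seed(17, {
    for (rep in 1:10) {
      read <- paste(sample(c("A", "C", "G", "T", "N"), 40, replace = TRUE,
                           prob = c(.24, .24, .24, .24, .04)), collapse = "")
      df <- oracle_kmers(kmer_oracle(read, 4))
      want <- r_window_scan(read, 4)
      expect_setequal(df$kmer, unique(want$kmer))
      counts <- table(want$kmer)
      expect_equal(df$count, as.numeric(counts[df$kmer]), ignore_attr = TRUE)
    }
  })
})

test_that("comparison is empty for a correct build and pinpoints injected faults", {
  case <- random_case(9, seed = 33, genome_len = 1500, n_reads = 100)
  expect_equal(nrow(compare_graph(case$graph, case$oracle)), 0)
  # flip one neighbour bit through the shared table handle
  t <- graph_table(case$graph)
  loc <- havec_locate(case$graph, havec_kmers(case$graph)$kmer[1])
  stopifnot(loc$kind == "table")
  e <- table_read_slot(t, loc$index)
  flip <- setdiff(c("A", "C", "G", "T"), strsplit(e$neighbours, "")[[1]])[1]
  table_or_neighbour(t, loc$index, flip)
  bad <- compare_graph(case$graph, case$oracle)
  expect_equal(nrow(bad), 1)
  expect_equal(bad$field, "neighbours")
  expect_equal(bad$kmer, loc$kmer)
})

test_that("cutoff comparisons differ only in sub-cutoff k-mers", {
  g <- build_wex(counts = TRUE)
  o <- kmer_oracle(worked_example()$read, 5)
  expect_equal(nrow(compare_graph(g, o)), 0)
  expect_equal(nrow(compare_graph(g, o, cutoff = 2)), 0)
  # the filtered view really is smaller: only TGTGT survives cutoff 2
  expect_equal(sum(havec_contains(g, oracle_kmers(o)$kmer, cutoff = 2)), 1)
})
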