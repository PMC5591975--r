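# Shared fixtures, all generated in code.

# every k-mer of length k (4^k strings) — keep k tiny
all_kmers <- function(k) {
  grid <- expand.grid(rep(list(c("A", "C", "G", "T")), k),
                      stringsAsFactors = FALSE)
  apply(grid[, rev(seq_len(k)), drop = FALSE], 1, paste, collapse = "")
}

# independent base-R window scan: same contract as extract_kmers(), written
# against plain substring operations so the two cannot share a defect
r_window_scan <- function(read, k) {
  read <- toupper(read)
  L <- nchar(read)
  out <- list()
  if (L >= k) {
    for (p in seq_len(L - k + 1)) {
      w <- substr(read, p, p + k - 1)
      if (grepl("[^ACGT]", w)) next
      nb <- if (p + k <= L) substr(read, p + k, p + k) else NA_character_
      if (!is.na(nb) && !nb %in% c("A", "C", "G", "T")) nb <- NA_character_
      out[[length(out) + 1]] <- data.frame(pos = p, kmer = w, next_base = nb,
                                           stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(pos = numeric(), kmer = character(),
                      next_base = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# the worked-example graph, freshly built
build_wex <- function(counts = FALSE) {
  ex <- worked_example()
  g <- havec(ex$k, ex$M, ex$h, vector_size = ex$V, counts = counts,
             family = ex$family)
  havec_build(g, ex$read)
  g
}

# a reproducible synthetic build with its oracle
random_case <- function(k, seed, genome_len = 5000, n_reads = 250,
                        read_len = 100, error_rate = 0.01, n_rate = 0.002,
                        h = 4, factor = 1.4, counts = FALSE) {
  genome <- random_genome(genome_len, seed)
  reads <- sample_reads(genome, n_reads, read_len, error_rate, n_rate,
                        seed = seed + 1)
  o <- kmer_oracle(reads, k)
  n <- havec:::cpp_oracle_info(o$ptr)$distinct_kmers
  g <- havec(k, recommend_table_size(n, k, factor), h = h, counts = counts,
             seed = seed + 2)
  havec_build(g, reads)
  list(reads = reads, oracle = o, graph = g, distinct = n)
}

# uniformly random k-mer strings
random_kmers <- function(n, k, seed) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = ""),
      character(1))
  })
}
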