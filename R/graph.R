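#' Create an empty k-mer graph
#'
#' Allocates the packed table and auxiliary vector for a de Bruijn graph
#' over k-mers of length `k`. Insertion probes hash functions H_1..H_h in
#' order and stores each new k-mer in the first free slot; if all h probes
#' hit occupied slots the k-mer spills into the auxiliary vector under the
#' last function's slot index. Queries re-probe the same way and verify the
#' stored quotient and function index, which identifies exactly one k-mer —
#' answers are exact in both directions.
#'
#' `table_size` must be at least `2^(2k-33)` slots (see [min_table_size()])
#' so that every quotient fits in its 33-bit field; memory use is best near
#' 1.25--1.5 slots per expected distinct k-mer ([recommend_table_size()]).
#'
#' @param k k-mer length (1--32).
#' @param table_size number of table slots M.
#' @param h number of hash functions to cascade (1--7).
#' @param vector_size number of level-1 buckets V of the auxiliary vector;
#'   default `max(1024, ceiling(table_size / 1024))` keeps buckets tiny at
#'   the spill rates seen in practice (~1 spilled k-mer per 1000).
#' @param counts keep a saturating per-k-mer occurrence count (6 bytes per
#'   entry instead of 5)? Required for cutoff-filtered queries.
#' @param family a `havec_family`; default is `hash_family(h, seed)`.
#' @param seed master seed for the default family.
#' @return a `havec` graph handle (updated in place by build/insert).
#' @examples
#' g <- havec(k = 5, table_size = 64, h = 2, seed = 7)
#' havec_build(g, "GGCAATTGTGTGTCG")
#' havec_contains(g, c("GGCAA", "AAAAA"))
#' @export
havec <- function(k, table_size, h = 4, vector_size = NULL, counts = FALSE,
                  family = NULL, seed = 1) {
  if (is.null(vector_size)) vector_size <- max(1024, ceiling(table_size / 1024))
  if (is.null(family)) family <- hash_family(h, seed)
  stopifnot(inherits(family, "havec_family"))
  structure(
    list(ptr = cpp_graph_new(as.integer(k), as.numeric(table_size),
                             as.integer(h), as.numeric(vector_size),
                             isTRUE(counts), family$ptr)),
    class = "havec")
}

#' @export
print.havec <- function(x, ...) {
  p <- cpp_graph_params(x$ptr)
  cat(sprintf("<havec graph: k = %d, M = %.0f, h = %d, V = %.0f, %s%s>\n",
              p$k, p$M, p$h, p$V, p$mode,
              if (p$stipulated) ", stipulated hashes" else ""))
  cat(sprintf("  %.0f distinct k-mer(s): %.0f in table, %.0f in vector; %.0f read(s), %.0f observation(s)\n",
              p$table_kmers + p$vector_kmers, p$table_kmers, p$vector_kmers,
              p$reads, p$observations))
  invisible(x)
}

#' Graph parameters and counters
#' @param g a `havec` graph.
#' @return list with `k`, `h`, `M`, `V`, `mode`, counters.
#' @export
havec_params <- function(g) {
  stopifnot(inherits(g, "havec"))
  cpp_graph_params(g$ptr)
}

#' Build a graph from reads
#'
#' Streams each read through [extract_kmers()] and inserts every window
#' with its following base. The graph is updated in place; building twice
#' adds the second read set on top of the first.
#'
#' @param g a `havec` graph.
#' @param reads character vector of DNA reads.
#' @return invisibly, a list report: `reads`, `observations` (windows
#'   inserted), `skipped_windows` (ambiguous-base windows), and the
#'   resulting `distinct_kmers`, `table_kmers`, `vector_kmers`.
#' @export
havec_build <- function(g, reads) {
  stopifnot(inherits(g, "havec"))
  invisible(cpp_graph_build(g$ptr, as.character(reads)))
}

#' Insert a single k-mer observation
#'
#' The update path of one window: if the k-mer is already stored its
#' neighbour bit for `next_base` is OR-ed in (and its count bumped in
#' counting mode); otherwise it is placed in the first free probed slot, or
#' spilled to the auxiliary vector when all probes collide.
#'
#' @param g a `havec` graph.
#' @param kmer a single k-mer string of the graph's k.
#' @param next_base the observed following base, or `NA`/`""` for none (no
#'   neighbour bit is set).
#' @return invisibly, the final location (list: `kind`, `index`, `bucket`,
#'   `ht_index`, `pos`, `hf`; indices 0-based).
#' @export
havec_insert <- function(g, kmer, next_base = NA) {
  stopifnot(inherits(g, "havec"))
  if (is.na(next_base)) next_base <- ""
  invisible(cpp_graph_insert(g$ptr, kmer, next_base))
}

#' Locate k-mers in the graph
#'
#' Probes H_1..H_h and then the auxiliary vector, returning where each
#' k-mer lives — never the location of a different k-mer.
#'
#' @param g a `havec` graph.
#' @param kmers character vector of k-mers.
#' @return data.frame with columns `kmer`, `kind` (`"table"`, `"vector"` or
#'   `"absent"`), `index` (table slot), `bucket`/`ht_index`/`pos` (vector
#'   coordinates) and `hf`; all indices 0-based.
#' @export
havec_locate <- function(g, kmers) {
  stopifnot(inherits(g, "havec"))
  cpp_graph_locate(g$ptr, as.character(kmers))
}

#' Exact membership queries
#'
#' @param g a `havec` graph.
#' @param kmers character vector of k-mers.
#' @param cutoff minimum occurrence count for a k-mer to be reported
#'   present (2--255); requires a graph built with `counts = TRUE`.
#'   `NULL` (default) means no filtering. Cutoffs are applied at query time
#'   only, so one built graph serves any number of cutoffs.
#' @return logical vector: `TRUE` iff the k-mer was observed (and passes
#'   the cutoff). No false positives, no false negatives.
#' @export
havec_contains <- function(g, kmers, cutoff = NULL) {
  stopifnot(inherits(g, "havec"))
  cpp_graph_contains(g$ptr, as.character(kmers), normalize_cutoff(cutoff))
}

#' Observed successors / predecessors of a stored k-mer
#'
#' `havec_successors()` returns the k-mers reachable through the stored
#' neighbour bits, in A, C, G, T order; every one of them is itself stored.
#' `havec_predecessors()` checks the four candidate predecessors and
#' returns those that are stored with the matching neighbour bit set.
#' Under a cutoff, neighbours that fail the cutoff are excluded, so
#' traversal stays closed within the filtered graph.
#'
#' @param g a `havec` graph.
#' @param kmer a single stored k-mer (error if absent).
#' @inheritParams havec_contains
#' @return character vector of k-mers.
#' @export
havec_successors <- function(g, kmer, cutoff = NULL) {
  stopifnot(inherits(g, "havec"))
  cpp_graph_successors(g$ptr, kmer, normalize_cutoff(cutoff))
}

#' @rdname havec_successors
#' @export
havec_predecessors <- function(g, kmer, cutoff = NULL) {
  stopifnot(inherits(g, "havec"))
  cpp_graph_predecessors(g$ptr, kmer, normalize_cutoff(cutoff))
}

#' Enumerate every stored k-mer
#'
#' Recovers the k-mer behind each occupied table slot and vector record by
#' inverting the hash function that stored it (slot + quotient reconstruct
#' the hash value). Requires an invertible family; a stipulated family
#' without reverse entries is an error.
#'
#' @param g a `havec` graph.
#' @return data.frame with columns `kmer`, `neighbours` (bases string) and
#'   `count` (`NA` unless built with `counts = TRUE`), one row per distinct
#'   stored k-mer.
#' @export
havec_kmers <- function(g) {
  stopifnot(inherits(g, "havec"))
  cpp_graph_enumerate(g$ptr)
}

#' Graph occupancy and memory statistics
#'
#' @param g a `havec` graph.
#' @return list: `distinct_kmers`, `table_kmers`, `vector_kmers`,
#'   `load_factor` (table k-mers / M), `table_bytes` (M x entry width),
#'   `vector_bytes` (measured auxiliary payload), `max_records_per_index`,
#'   `max_indices_per_bucket`, `reads`, `observations`.
#' @export
havec_stats <- function(g) {
  stopifnot(inherits(g, "havec"))
  cpp_graph_stats(g$ptr)
}

normalize_cutoff <- function(cutoff) {
  if (is.null(cutoff) || is.na(cutoff)) return(1L)
  cutoff <- as.integer(cutoff)
  if (cutoff < 1 || cutoff > 255)
    stop("cutoff must be in 1..255, got ", cutoff)
  cutoff
}
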