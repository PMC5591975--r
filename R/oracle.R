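#' Brute-force exact reference for a read set
#'
#' Scans the reads with plain string windows (no hashing of any kind) and
#' records, for every observed k-mer, the set of bases seen immediately
#' after it and its total multiplicity. The window/skip semantics are the
#' single shared implementation also used by [extract_kmers()] and
#' [havec_build()], so the two sides cannot drift apart silently.
#'
#' @param reads character vector of DNA reads.
#' @param k k-mer length (1--32).
#' @return a `havec_oracle` handle.
#' @seealso [compare_graph()]
#' @export
kmer_oracle <- function(reads, k) {
  structure(list(ptr = cpp_oracle_build(as.character(reads), as.integer(k))),
            class = "havec_oracle")
}

#' @export
print.havec_oracle <- function(x, ...) {
  info <- cpp_oracle_info(x$ptr)
  cat(sprintf("<havec oracle: k = %d, %.0f distinct k-mer(s)>\n",
              info$k, info$distinct_kmers))
  invisible(x)
}

#' All k-mers known to an oracle
#'
#' @param o a `havec_oracle`.
#' @return data.frame with columns `kmer`, `neighbours`, `count`
#'   (uncapped multiplicity), in no particular order.
#' @export
oracle_kmers <- function(o) {
  stopifnot(inherits(o, "havec_oracle"))
  cpp_oracle_kmers(o$ptr)
}

#' Verify a graph against the brute-force oracle
#'
#' Checks, k-mer by k-mer, that membership, neighbour sets and (in counting
#' mode) capped counts agree with the oracle under the given cutoff, and
#' that the graph holds no k-mer the oracle does not. A correctly built
#' graph gives a zero-row report; each discrepancy is reported with the
#' offending k-mer.
#'
#' @param g a `havec` graph.
#' @param o a `havec_oracle` built with the same k from the same reads.
#' @param cutoff optional minimum multiplicity (see [havec_contains()]).
#' @return data.frame with columns `kmer`, `field`, `expected`, `observed`;
#'   zero rows means exact agreement.
#' @export
compare_graph <- function(g, o, cutoff = NULL) {
  stopifnot(inherits(g, "havec"), inherits(o, "havec_oracle"))
  cpp_compare(g$ptr, o$ptr, normalize_cutoff(cutoff))
}
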