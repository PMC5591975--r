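#' The bundled worked example
#'
#' A tiny, fully hand-checkable configuration: one read
#' `GGCAATTGTGTGTCG`, 5-mers, a table of 11 slots, 2 hash functions with
#' stipulated values, and a 3-bucket auxiliary vector. Replaying it
#' exercises every storage path — direct table insertion, second-probe
#' insertion, vector spill, and the in-place neighbour update when a k-mer
#' recurs (`TGTGT` appears twice, gaining neighbours G then C).
#'
#' The hash-value table covers every (function, k-mer) pair the replay and
#' its queries touch. Rows flagged `synthetic = TRUE` are values this
#' package chose for pairs the original illustration leaves open (e.g. the
#' second probe of `TGTCG`, and values for never-inserted k-mers that
#' negative queries must hash); the flagged values are arbitrary but fixed,
#' and chosen so the replay's documented final state is self-consistent.
#'
#' @return list with elements `read`, `k`, `M`, `h`, `V`, `hashes` (the
#'   stipulation data.frame with columns `fun`, `kmer`, `value`,
#'   `synthetic`), and `family` (ready-made stipulated family).
#' @examples
#' ex <- worked_example()
#' g <- havec(ex$k, ex$M, ex$h, vector_size = ex$V, family = ex$family)
#' havec_build(g, ex$read)
#' havec_locate(g, c("GGCAA", "ATTGT"))
#' @export
worked_example <- function() {
  path <- system.file("extdata", "worked_example_hashes.csv",
                      package = "havec", mustWork = TRUE)
  hashes <- utils::read.csv(path, stringsAsFactors = FALSE)
  list(read = "GGCAATTGTGTGTCG", k = 5L, M = 11, h = 2L, V = 3,
       hashes = hashes, family = stipulated_hash_family(hashes, h = 2L))
}
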