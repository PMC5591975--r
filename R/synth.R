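#' Simulate a random genome
#'
#' Uniform i.i.d. bases; the same seed always gives the same genome, and
#' the caller's RNG state is left untouched.
#'
#' @param length genome length in bases (>= 1).
#' @param seed integer seed.
#' @return a single DNA string.
#' @export
random_genome <- function(length, seed) {
  stopifnot(length >= 1)
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = ""))
}

#' Sample error-bearing reads from a genome
#'
#' Reads start at uniform positions on the forward strand. Each base is
#' substituted with probability `error_rate` (to one of the three other
#' bases) and replaced by `N` with probability `n_rate`, which exercises
#' the ambiguous-window skip policy downstream. Substitution-only errors
#' (no indels) are enough to inflate the distinct k-mer count, which is
#' what stresses table occupancy and vector spill.
#'
#' @param genome a DNA string.
#' @param n number of reads.
#' @param read_length read length (<= nchar(genome)).
#' @param error_rate per-base substitution probability.
#' @param n_rate per-base probability of an ambiguous `N`.
#' @param seed integer seed; fixed seed gives a byte-identical read set.
#' @return character vector of `n` reads.
#' @export
sample_reads <- function(genome, n, read_length = 100, error_rate = 0,
                         n_rate = 0, seed = 1) {
  L <- nchar(genome)
  stopifnot(read_length <= L, n >= 0, error_rate >= 0, error_rate <= 1,
            n_rate >= 0, n_rate <= 1)
  if (n == 0) return(character(0))
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    starts <- sample.int(L - read_length + 1L, n, replace = TRUE)
    reads <- substring(genome, starts, starts + read_length - 1L)
    if (error_rate > 0 || n_rate > 0) {
      mat <- matrix(unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE),
                    nrow = read_length)
      if (error_rate > 0) {
        hit <- which(matrix(stats::runif(length(mat)) < error_rate,
                            nrow = read_length))
        if (length(hit)) {
          # substitute with a base different from the original
          shift <- sample.int(3L, length(hit), replace = TRUE)
          orig <- match(mat[hit], bases)
          mat[hit] <- bases[((orig - 1L + shift) %% 4L) + 1L]
        }
      }
      if (n_rate > 0) {
        hit <- which(matrix(stats::runif(length(mat)) < n_rate,
                            nrow = read_length))
        if (length(hit)) mat[hit] <- "N"
      }
      reads <- apply(mat, 2, paste, collapse = "")
    }
    reads
  })
}
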