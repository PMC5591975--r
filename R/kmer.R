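#' Encode k-mers as 2k-bit integer codes
#'
#' Each base maps to 2 bits (A=0, C=1, G=2, T=3) and the first base occupies
#' the most significant position, i.e. big-endian base-4 packing. Codes for
#' k > 26 exceed the exact integer range of a double, so codes are returned
#' (and accepted) as decimal strings; they are exact for every k up to 32.
#'
#' @param kmers character vector of DNA strings (1--32 bases, ACGT only;
#'   lowercase is accepted and upper-cased).
#' @return character vector of decimal integer codes in `[0, 4^k)`.
#' @examples
#' encode_kmers("GGCAA")   # "656"
#' decode_kmers("656", 5)  # "GGCAA"
#' @seealso [decode_kmers()], [extract_kmers()]
#' @export
encode_kmers <- function(kmers) {
  cpp_encode_kmers(as.character(kmers))
}

#' Decode 2k-bit integer codes back to k-mer strings
#'
#' @param codes character or numeric vector of codes (see [encode_kmers()]).
#' @param k k-mer length in bases (1--32).
#' @return character vector of DNA strings.
#' @export
decode_kmers <- function(codes, k) {
  cpp_decode_kmers(as.character(codes), as.integer(k))
}

#' Extract successive k-mers (and their following base) from a read
#'
#' Slides a k-wide window along the read. Any window containing a non-ACGT
#' symbol is skipped entirely, and windows resume after the offending base;
#' this is the same skip policy the graph builder and the verification
#' oracle use. The base immediately following a window is reported so that
#' the caller can record the outgoing-neighbour edge; it is `NA` for the
#' last window of a read or when the following base is ambiguous.
#'
#' @param read a single DNA string.
#' @param k window length (1--32).
#' @return a data.frame with columns `pos` (1-based start), `kmer`, and
#'   `next_base` (single base or `NA`). Reads shorter than `k` give zero
#'   rows.
#' @examples
#' extract_kmers("GGCAATTGTGTGTCG", 5)
#' @export
extract_kmers <- function(read, k) {
  stopifnot(is.character(read), length(read) == 1L)
  cpp_extract_kmers(read, as.integer(k))
}

#' Successor k-mers reachable through a set of neighbour bases
#'
#' Drops the first base of `kmer` and appends each base in `bases`,
#' returning the successors in A, C, G, T order. This is the edge rule of
#' the de Bruijn graph: an appended base reaches the k-mer that overlaps
#' the current one by k-1 symbols.
#'
#' @param kmer a single k-mer string.
#' @param bases bases to append, e.g. `"CG"`; `""` gives no successors.
#' @return character vector of successor k-mers.
#' @examples
#' kmer_successors("TGTGT", "CG")  # GTGTC, GTGTG
#' @export
kmer_successors <- function(kmer, bases) {
  stopifnot(is.character(kmer), length(kmer) == 1L)
  cpp_successor_kmers(kmer, paste(bases, collapse = ""))
}
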