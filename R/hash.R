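#' Create a family of invertible hash functions
#'
#' Builds `h` deterministic mixing permutations of the 2k-bit k-mer code
#' space (multiply-by-odd-constant and xor-shift rounds, every step
#' invertible). Bijectivity is what makes the stored (slot, quotient,
#' function index) triple a perfect fingerprint of one k-mer — the basis of
#' the structure's no-false-positive guarantee — and it allows the full
#' k-mer set to be recovered from a built graph by inversion
#' ([havec_kmers()]).
#'
#' Function indices are 1-based; index 0 is reserved as the free-slot
#' sentinel in table entries, so at most 7 of the 8 representable indices
#' name usable functions.
#'
#' @param h number of hash functions (1--7).
#' @param seed integer master seed; all per-function constants derive from
#'   it, so equal seeds give identical families across sessions.
#' @return a `havec_family` object.
#' @examples
#' fam <- hash_family(2, seed = 42)
#' hash_values(fam, 1, "GGCAA")
#' @export
hash_family <- function(h, seed = 1) {
  structure(
    list(ptr = cpp_hash_family(as.integer(h), as.numeric(seed)),
         h = as.integer(h), stipulated = FALSE, seed = as.numeric(seed)),
    class = "havec_family")
}

#' Create a hash family from an explicit value table
#'
#' A closed-world family for controlled experiments: every hash value is
#' looked up verbatim in `table`, and querying a (function, k-mer) pair the
#' table does not cover is an error ("unstipulated hash query"). Inversion
#' works by reverse lookup, so each function's values must be distinct.
#'
#' @param table a data.frame with columns `fun` (1-based function index),
#'   `kmer`, and `value` (hash value, numeric or decimal string).
#' @param h number of functions; defaults to `max(table$fun)`.
#' @return a `havec_family` object.
#' @seealso [worked_example()] for the bundled demonstration table.
#' @export
stipulated_hash_family <- function(table, h = max(table$fun)) {
  stopifnot(is.data.frame(table),
            all(c("fun", "kmer", "value") %in% names(table)))
  structure(
    list(ptr = cpp_stipulated_family(as.integer(h), as.integer(table$fun),
                                     as.character(table$kmer),
                                     as.character(table$value)),
         h = as.integer(h), stipulated = TRUE, seed = NA_real_),
    class = "havec_family")
}

#' @export
print.havec_family <- function(x, ...) {
  info <- cpp_family_info(x$ptr)
  cat(sprintf("<havec hash family: h = %d, %s>\n", info$h,
              if (info$stipulated) "stipulated value table"
              else sprintf("mixing permutations, seed %.0f", info$seed)))
  invisible(x)
}

#' Hash k-mers with one function of a family
#'
#' @param family a `havec_family`.
#' @param i 1-based function index.
#' @param kmers character vector of k-mers (all the same length).
#' @return character vector of decimal hash values (exact 64-bit).
#' @export
hash_values <- function(family, i, kmers) {
  stopifnot(inherits(family, "havec_family"))
  cpp_hash_values(family$ptr, as.integer(i), as.character(kmers))
}

#' Invert one function of a family
#'
#' Recovers the k-mer whose hash value is `values` under function `i`; for
#' a mixing family this applies the inverse permutation, for a stipulated
#' family a reverse lookup.
#'
#' @inheritParams hash_values
#' @param values hash values (numeric or decimal strings).
#' @param k k-mer length.
#' @return character vector of k-mer strings.
#' @export
hash_invert <- function(family, i, values, k) {
  stopifnot(inherits(family, "havec_family"))
  cpp_hash_invert(family$ptr, as.integer(i), as.character(values),
                  as.integer(k))
}

#' Split hash values into table index and quotient
#'
#' The table slot is `value %% M` and the quotient `value %/% M`, so
#' `quotient * M + index` reconstructs the hash value exactly. The quotient
#' is the stored fingerprint: two k-mers whose values share a slot must
#' differ in quotient.
#'
#' @param values hash values (numeric or decimal strings).
#' @param M table size (>= 1).
#' @return data.frame with columns `index` and `quotient`.
#' @examples
#' split_hash(57, 11)  # index 2, quotient 5
#' @export
split_hash <- function(values, M) {
  cpp_index_quotient(as.character(values), as.numeric(M))
}

#' Minimum table size for a given k
#'
#' Quotients are stored in 33 bits. Hash values occupy 2k bits, so the
#' table must have at least `2^(2k-33)` slots for every quotient to fit;
#' smaller k (2k <= 33) is unconstrained. For k = 32 this floor is `2^31`
#' slots, for k = 25 it is `2^17`.
#'
#' @param k k-mer length (1--32).
#' @return minimum number of table slots (numeric).
#' @export
min_table_size <- function(k) {
  cpp_min_table_size(as.integer(k))
}

#' Recommended table size for an expected number of distinct k-mers
#'
#' Memory use is smallest when the table holds roughly 1.25--1.5 slots per
#' distinct k-mer; the default factor 1.4 sits in the middle of that band.
#' The result never falls below [min_table_size()].
#'
#' @param n_distinct expected number of distinct k-mers.
#' @param k k-mer length.
#' @param factor slots per distinct k-mer.
#' @return a table size (numeric).
#' @export
recommend_table_size <- function(n_distinct, k, factor = 1.4) {
  stopifnot(n_distinct >= 0, factor > 0)
  max(ceiling(factor * n_distinct), min_table_size(k), 1)
}
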