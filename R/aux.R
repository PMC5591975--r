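#' Three-level auxiliary vector for collided k-mers
#'
#' Holds the k-mers for which every table probe failed. Level 1 is a fixed
#' array of `V` buckets addressed by `ht_index %% V`, where `ht_index` is
#' the table slot produced by the last hash function. Level 2 is the list
#' of distinct `ht_index` values that landed in a bucket; level 3 holds,
#' per `ht_index`, the records of collided k-mers. A record stores the
#' quotient, the hash-function index (always the last function), the
#' neighbour bits, and in counting mode an occurrence count. Within one
#' `ht_index` quotients are unique, so a (ht_index, quotient) pair
#' identifies exactly one k-mer.
#'
#' @param V number of level-1 buckets (>= 1).
#' @return a `havec_aux` handle.
#' @export
aux_vector <- function(V) {
  structure(list(ptr = cpp_aux_new(as.numeric(V))), class = "havec_aux")
}

#' @export
print.havec_aux <- function(x, ...) {
  s <- cpp_aux_stats(x$ptr)
  cat(sprintf("<havec auxiliary vector: V = %.0f, %.0f record(s)>\n",
              s$V, s$records))
  invisible(x)
}

#' Insert a collided k-mer record
#'
#' Files the record under bucket `ht_index %% V`, creating the `ht_index`
#' sublist if needed. If a record with the same quotient already exists
#' under that `ht_index` nothing is inserted (the existing record is the
#' same k-mer and the caller updates it instead).
#'
#' @param av a `havec_aux` handle.
#' @param ht_index hash table index from the last hash function.
#' @param quotient 33-bit quotient.
#' @param hf hash function index stored with the record.
#' @param neighbours neighbour bases string.
#' @param count initial count.
#' @return `TRUE` if a new record was appended, `FALSE` if one existed.
#' @export
aux_insert <- function(av, ht_index, quotient, hf, neighbours = "",
                       count = 1) {
  stopifnot(inherits(av, "havec_aux"))
  cpp_aux_insert(av$ptr, as.numeric(ht_index), as.numeric(quotient),
                 as.integer(hf), neighbours, as.integer(count))
}

#' Look up a collided k-mer record
#'
#' @inheritParams aux_insert
#' @return the matching record as a list, or `NULL`; never a record with a
#'   different quotient.
#' @export
aux_lookup <- function(av, ht_index, quotient) {
  stopifnot(inherits(av, "havec_aux"))
  cpp_aux_lookup(av$ptr, as.numeric(ht_index), as.numeric(quotient))
}

#' Occupancy statistics of an auxiliary vector
#'
#' @param av a `havec_aux` handle.
#' @return list with `V`, `records` (total), `max_records_per_index`, and
#'   `max_indices_per_bucket` — the n and m that bound the cost of any
#'   single lookup.
#' @export
aux_stats <- function(av) {
  stopifnot(inherits(av, "havec_aux"))
  cpp_aux_stats(av$ptr)
}

#' All records of an auxiliary vector as a data.frame
#'
#' @param av a `havec_aux` handle.
#' @return data.frame with columns `bucket`, `ht_index`, `pos`, `quotient`,
#'   `hf`, `neighbours`, `count` (indices 0-based).
#' @export
aux_records <- function(av) {
  stopifnot(inherits(av, "havec_aux"))
  cpp_aux_dump(av$ptr)
}

#' Access the auxiliary vector of a graph
#'
#' The returned handle shares storage with the graph.
#'
#' @param g a `havec` graph.
#' @return a `havec_aux` handle.
#' @export
graph_aux <- function(g) {
  stopifnot(inherits(g, "havec"))
  structure(list(ptr = cpp_aux_from_graph(g$ptr)), class = "havec_aux")
}
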