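#' Packed k-mer hash table
#'
#' The table backing a graph: M entries of 5 bytes (40 bits) each, or 6
#' bytes when a saturating occurrence count is kept. The 40-bit word packs,
#' most significant first, 4 neighbour bits (A, C, G, T), the 3-bit index
#' of the hash function that stored the entry (0 marks a free slot), and
#' the 33-bit quotient. Words are laid out little-endian in the backing
#' bytes. A fresh table is all zeros, i.e. every entry free.
#'
#' Storage is allocated in zero-filled segments on first write, so a large
#' table costs memory only for the regions actually touched.
#'
#' @param M number of entries (>= 1).
#' @param bytes entry width: 5, or 6 to keep counts.
#' @return a `havec_table` handle.
#' @examples
#' t <- packed_table(11)
#' table_read_slot(t, 0)   # free: quotient 0, hf 0
#' @export
packed_table <- function(M, bytes = 5) {
  structure(list(ptr = cpp_packed_table(as.numeric(M), as.integer(bytes))),
            class = "havec_table")
}

#' @export
print.havec_table <- function(x, ...) {
  info <- cpp_table_info(x$ptr)
  cat(sprintf("<havec packed table: %.0f entries x %d bytes = %.0f bytes>\n",
              info$M, info$bytes_per_entry, info$nbytes))
  invisible(x)
}

#' Table geometry
#' @param x a `havec_table`.
#' @return list with `M`, `bytes_per_entry`, `nbytes`.
#' @export
table_info <- function(x) {
  stopifnot(inherits(x, "havec_table"))
  cpp_table_info(x$ptr)
}

#' Read or write one table slot
#'
#' Slot indices are 0-based throughout, matching the convention of the
#' structure's printed-table notation. Writing a slot affects only that
#' entry; reading after writing returns the identical entry.
#'
#' @param x a `havec_table` (standalone or from [graph_table()]).
#' @param index slot index in `[0, M)`.
#' @return `table_read_slot()`: a list with `quotient`, `hf`, `neighbours`
#'   (bases string) and `count` (`NA` in 5-byte mode).
#' @export
table_read_slot <- function(x, index) {
  stopifnot(inherits(x, "havec_table"))
  cpp_table_read(x$ptr, as.numeric(index))
}

#' @rdname table_read_slot
#' @param quotient 33-bit quotient value.
#' @param hf hash function index (0 = free, 1..7).
#' @param neighbours neighbour bases as a string, e.g. `"CG"`.
#' @param count occurrence count (6-byte tables only; ignored otherwise).
#' @export
table_write_slot <- function(x, index, quotient, hf, neighbours = "",
                             count = 1) {
  stopifnot(inherits(x, "havec_table"))
  cpp_table_write(x$ptr, as.numeric(index), as.numeric(quotient),
                  as.integer(hf), neighbours, as.integer(count))
  invisible(x)
}

#' Set one neighbour bit of an occupied slot
#'
#' Idempotent: adding a base that is already recorded changes nothing.
#' Updating a free slot is an error.
#'
#' @inheritParams table_read_slot
#' @param base single base `"A"`, `"C"`, `"G"` or `"T"`.
#' @export
table_or_neighbour <- function(x, index, base) {
  stopifnot(inherits(x, "havec_table"))
  cpp_table_or(x$ptr, as.numeric(index), base)
  invisible(x)
}

#' Increment the count byte of an occupied slot (6-byte tables)
#'
#' Saturates at 255. Calling this on a 5-byte table is an error.
#'
#' @inheritParams table_read_slot
#' @export
table_bump_count <- function(x, index) {
  stopifnot(inherits(x, "havec_table"))
  cpp_table_bump(x$ptr, as.numeric(index))
  invisible(x)
}

#' Pack or unpack a single table entry
#'
#' Pure bit-layout functions; `unpack_entry(pack_entry(...))` is the
#' identity on every representable field combination. A quotient needing
#' more than 33 bits is an error.
#'
#' @inheritParams table_write_slot
#' @param bytes entry width, 5 or 6.
#' @return `pack_entry()`: a raw vector of `bytes` bytes.
#' @examples
#' pack_entry(quotient = 5, hf = 1, neighbours = "T")
#' @export
pack_entry <- function(quotient, hf, neighbours = "", count = 1, bytes = 5) {
  cpp_pack_entry(as.numeric(quotient), as.integer(hf), neighbours,
                 as.integer(count), as.integer(bytes))
}

#' @rdname pack_entry
#' @param raw raw vector as produced by `pack_entry()`.
#' @export
unpack_entry <- function(raw, bytes = length(raw)) {
  cpp_unpack_entry(raw, as.integer(bytes))
}

#' Access the packed table of a graph
#'
#' Returns a `havec_table` handle sharing storage with the graph (writes
#' through it are visible to graph queries — useful for fault-injection
#' experiments with [compare_graph()]).
#'
#' @param g a `havec` graph.
#' @return a `havec_table` handle.
#' @export
graph_table <- function(g) {
  stopifnot(inherits(g, "havec"))
  structure(list(ptr = cpp_table_from_graph(g$ptr)), class = "havec_table")
}
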