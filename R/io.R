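#' Read sequences from FASTA or FASTQ
#'
#' The format is auto-detected from the first non-empty character ('>' for
#' FASTA, '@' for FASTQ) and gzip compression from the file itself.
#' Multi-line FASTA records are concatenated; FASTQ quality lines are
#' ignored. Parsing is done by Biostrings.
#'
#' @param path path to a (optionally gzip-compressed) FASTA/FASTQ file.
#' @return character vector of sequences in file order (upper-case).
#'   An empty file gives `character(0)`.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- peek_first_char(path)
  if (is.na(first)) return(character(0))
  format <- switch(first, ">" = "fasta", "@" = "fastq",
                   stop("malformed record at line 1 of ", path,
                        ": expected '>' (FASTA) or '@' (FASTQ), saw '",
                        first, "'"))
  if (format == "fastq") check_fastq_lines(path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = format),
    error = function(e) stop("malformed ", toupper(format), " in ", path,
                             ": ", conditionMessage(e), call. = FALSE))
  toupper(as.character(seqs, use.names = FALSE))
}

# a FASTQ record is exactly 4 lines; a dangling partial record is an error
check_fastq_lines <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ in ", path, ": truncated record near line ",
         length(lines), call. = FALSE)
}

peek_first_char <- function(path) {
  con <- gzfile(path, "rt")  # transparently handles plain files too
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) return(NA_character_)
    line <- sub("^\\s+", "", line)
    if (nzchar(line)) return(substr(line, 1L, 1L))
  }
}

#' Write sequences to a FASTA file
#'
#' @param seqs character vector of sequences.
#' @param path output path (`.gz` suffix gives gzip compression).
#' @param names record names; default `read1`, `read2`, ...
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, names = NULL) {
  if (is.null(names)) names <- paste0("read", seq_along(seqs))
  x <- Biostrings::DNAStringSet(seqs)
  base::names(x) <- names
  Biostrings::writeXStringSet(x, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Save / load a graph as a binary container
#'
#' The container stores a little-endian header (format version, k, h, entry
#' width, M, V, hash master seed, counters), the M x width table bytes, the
#' auxiliary-vector payload, and a trailing whole-file checksum. The header
#' alone reconstructs the hash family, so a loaded graph answers every
#' query identically to the saved one. Graphs using a stipulated hash
#' family cannot be saved (their hash values are not derivable from a
#' seed).
#'
#' @param g a `havec` graph.
#' @param path file path (conventionally `.havec`).
#' @return `save_havec()`: `path` invisibly. `load_havec()`: a `havec`
#'   graph.
#' @export
save_havec <- function(g, path) {
  stopifnot(inherits(g, "havec"))
  writeBin(cpp_graph_serialize(g$ptr), path)
  invisible(path)
}

#' @rdname save_havec
#' @export
load_havec <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  buf <- readBin(path, "raw", n = file.size(path))
  structure(list(ptr = cpp_graph_deserialize(buf)), class = "havec")
}
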