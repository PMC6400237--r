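#' Read a FASTA file
#'
#' Reads nucleotide or protein FASTA into a named character vector, one
#' element per record, uppercased, in file order. Reading is
#' gzip-transparent. Record ids are the first whitespace-delimited token of
#' each header line and must be unique within the file.
#'
#' @param path Path to a FASTA file (optionally gzip-compressed).
#' @param type `"DNA"` (sequences restricted to A/C/G/T/N after
#'   uppercasing) or `"AA"` (protein; `*` permitted).
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  .check_fasta_headers(path)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(seqs) <- ids
  if (type == "DNA") {
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad)) {
      stop("non-ACGTN character in nucleotide record(s): ",
           paste(ids[bad], collapse = ", "))
    }
  } else {
    bad <- grepl("[^A-Z*-]", seqs)
    if (any(bad)) {
      stop("invalid character in protein record(s): ",
           paste(ids[bad], collapse = ", "))
    }
  }
  seqs
}

# First non-empty line must be a header; every header line must carry an id.
.check_fasta_headers <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) return(invisible(NULL))
  if (!startsWith(lines[nonempty[1]], ">")) {
    stop("malformed FASTA: line ", nonempty[1], " is not a header")
  }
  hdr <- which(startsWith(lines, ">"))
  empty_id <- hdr[!nzchar(sub("\\s.*$", "", sub("^>", "", lines[hdr])))]
  if (length(empty_id)) {
    stop("malformed FASTA: empty header id at line ", empty_id[1])
  }
  invisible(NULL)
}

#' Write sequences to FASTA
#'
#' Writes a named character vector of sequences as FASTA, wrapped at 60
#' columns. `write_fasta()` followed by [read_fasta()] round-trips exactly.
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param type `"DNA"`, `"AA"`, or `"auto"` (DNA iff all characters are
#'   A/C/G/T/N).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("auto", "DNA", "AA")) {
  type <- match.arg(type)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named")
  }
  if (type == "auto") {
    type <- if (all(!grepl("[^ACGTN]", seqs))) "DNA" else "AA"
  }
  set <- if (type == "DNA") Biostrings::DNAStringSet(seqs) else
    Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}
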