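#' Translate DNA to protein
#'
#' Translates a nucleotide string with the standard genetic code
#' (Biostrings' `GENETIC_CODE`, NCBI table 1). Any codon containing `N`
#' translates to `X`, stop codons to `*`, and a trailing partial codon is
#' dropped.
#'
#' @param na DNA string over A/C/G/T/N.
#' @param offset Reading-frame offset: 0, 1 or 2 nucleotides skipped.
#' @return Protein string (possibly empty).
#' @export
translate_dna <- function(na, offset = 0L) {
  stopifnot(length(na) == 1L, offset %in% 0:2)
  if (grepl("[^ACGTN]", na)) stop("invalid nucleotide character in input")
  n <- nchar(na) - offset
  n_codon <- n %/% 3L
  if (n_codon <= 0L) return("")
  starts <- offset + seq(1L, by = 3L, length.out = n_codon)
  codons <- substring(na, starts, starts + 2L)
  aa <- unname(GENETIC_CODE_TABLE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Standard genetic code as a plain lookup vector (from Biostrings).
GENETIC_CODE_TABLE <- NULL  # populated in .onLoad

.onLoad <- function(libname, pkgname) {
  tbl <- Biostrings::GENETIC_CODE
  utils::assignInMyNamespace("GENETIC_CODE_TABLE", structure(as.character(tbl), names = names(tbl)))
}

#' Reverse complement
#'
#' @param na DNA string over A/C/G/T/N.
#' @return The reverse complement string.
#' @export
reverse_complement <- function(na) {
  if (grepl("[^ACGTN]", na)) stop("invalid nucleotide character in input")
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", na))))
}

#' Find open reading frames in all six frames
#'
#' Reports every Met-to-stop ORF (one per start methionine, including nested
#' starts) in the three forward and three reverse frames of a contig. ORFs
#' that run off the contig end without a stop codon are reported with
#' `has_stop = FALSE`; transcriptome assemblies routinely truncate 3' ends,
#' so such ORFs remain eligible candidates downstream. Reverse-strand ORFs
#' are reported in forward-strand coordinates (0-based, half-open, stop
#' codon excluded).
#'
#' @param seq Nucleotide string over A/C/G/T/N.
#' @param min_aa Minimum protein length in residues (>= 1).
#' @param contig_id Id recorded in the output (defaults to `"contig"`).
#' @return A data.frame with columns `contig_id`, `frame` (one of
#'   1, 2, 3, -1, -2, -3), `start_nt`, `end_nt`, `aa`, `has_stop`, sorted by
#'   decreasing protein length, ties broken by frame (in the order
#'   +1,+2,+3,-1,-2,-3) then `start_nt`.
#' @export
find_orfs <- function(seq, min_aa = 1L, contig_id = "contig") {
  stopifnot(length(seq) == 1L, min_aa >= 1L)
  L <- nchar(seq)
  rc <- reverse_complement(seq)
  out <- vector("list", 6L)
  k <- 0L
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) seq else rc
    for (offset in 0:2) {
      k <- k + 1L
      out[[k]] <- .orfs_in_frame(s, offset, L, strand, min_aa)
    }
  }
  res <- do.call(rbind, out)
  res$contig_id <- rep(contig_id, nrow(res))
  res <- res[, c("contig_id", "frame", "start_nt", "end_nt", "aa", "has_stop")]
  len <- nchar(res$aa)
  frame_rank <- match(res$frame, c(1L, 2L, 3L, -1L, -2L, -3L))
  res <- res[order(-len, frame_rank, res$start_nt), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.orfs_in_frame <- function(s, offset, L, strand, min_aa) {
  prot <- translate_dna(s, offset)
  empty <- data.frame(frame = integer(), start_nt = integer(),
                      end_nt = integer(), aa = character(),
                      has_stop = logical())
  if (!nzchar(prot)) return(empty)
  ch <- strsplit(prot, "")[[1]]
  ms <- which(ch == "M")
  if (!length(ms)) return(empty)
  stops <- which(ch == "*")
  # first stop strictly after each M (an M position is never a stop position)
  stop_pos <- rep(NA_integer_, length(ms))
  if (length(stops)) {
    nxt <- findInterval(ms, stops) + 1L
    ok <- nxt <= length(stops)
    stop_pos[ok] <- stops[nxt[ok]]
  }
  has_stop <- !is.na(stop_pos)
  aa_end <- ifelse(has_stop, stop_pos - 1L, length(ch))
  len <- aa_end - ms + 1L
  keep <- len >= min_aa
  if (!any(keep)) return(empty)
  ms <- ms[keep]; aa_end <- aa_end[keep]; has_stop <- has_stop[keep]
  aa <- substring(prot, ms, aa_end)
  start_f <- offset + 3L * (ms - 1L)         # 0-based on the frame strand
  end_f <- offset + 3L * aa_end
  if (strand == 1L) {
    start_nt <- start_f; end_nt <- end_f
  } else {
    start_nt <- L - end_f; end_nt <- L - start_f
  }
  data.frame(frame = strand * (offset + 1L), start_nt = start_nt,
             end_nt = end_nt, aa = aa, has_stop = has_stop)
}
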