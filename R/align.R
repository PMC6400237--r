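#' Global pairwise alignment with affine gap penalties
#'
#' Needleman–Wunsch/Gotoh global alignment of two protein sequences. A gap
#' of length k costs `gap_open + k * gap_extend`. Traceback ties are broken
#' deterministically: match/mismatch is preferred over a gap in `a`, which
#' is preferred over a gap in `b`.
#'
#' @param a,b Non-empty protein strings.
#' @param matrix Substitution matrix with residue dimnames; defaults to
#'   [blosum62()].
#' @param gap_open,gap_extend Gap penalties (sign is ignored; magnitudes are
#'   used as costs). Defaults 10 and 1.
#' @return An object of class `pairwise_alignment`: list with `aligned_a`,
#'   `aligned_b` (equal-length gapped strings), `score`, and `identity`
#'   (fraction of columns with residues in both rows that are identical).
#' @export
nw_align <- function(a, b, matrix = blosum62(), gap_open = 10, gap_extend = 1) {
  stopifnot(length(a) == 1L, length(b) == 1L)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  go <- abs(gap_open); ge <- abs(gap_extend)
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  unknown <- setdiff(unique(c(ca, cb)), rownames(matrix))
  if (length(unknown)) {
    stop("residue(s) absent from substitution matrix: ",
         paste(unknown, collapse = ", "))
  }
  cell <- matrix[ca, cb, drop = FALSE]
  dp <- .affine_dp(cell, go, ge)
  al <- .apply_path(dp$path, ca, cb)
  same <- al$a_chars != "-" & al$b_chars != "-"
  identity <- if (any(same)) mean(al$a_chars[same] == al$b_chars[same]) else 0
  structure(list(aligned_a = paste(al$a_chars, collapse = ""),
                 aligned_b = paste(al$b_chars, collapse = ""),
                 score = dp$score, identity = identity),
            class = "pairwise_alignment")
}

# Expand two character vectors along a DP move path (0 diag, 1 gap in a,
# 2 gap in b).
.apply_path <- function(path, ca, cb) {
  n <- length(path)
  a_out <- character(n); b_out <- character(n)
  i <- 0L; j <- 0L
  for (k in seq_len(n)) {
    mv <- path[k]
    if (mv == 0L) {
      i <- i + 1L; j <- j + 1L
      a_out[k] <- ca[i]; b_out[k] <- cb[j]
    } else if (mv == 1L) {
      j <- j + 1L
      a_out[k] <- "-"; b_out[k] <- cb[j]
    } else {
      i <- i + 1L
      a_out[k] <- ca[i]; b_out[k] <- "-"
    }
  }
  list(a_chars = a_out, b_chars = b_out)
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Pairwise global alignment (score ", format(x$score),
      ", identity ", sprintf("%.3f", x$identity), ")\n", sep = "")
  cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Multiple protein alignment container
#'
#' A thin container for an aligned set of proteins: a named character
#' vector of equal-length gapped rows.
#'
#' @param rows Named character vector; all elements the same length, names
#'   unique and non-empty.
#' @return Object of class `hblhb_msa`.
#' @export
new_msa <- function(rows) {
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    stop("all MSA rows must be named")
  }
  if (anyDuplicated(names(rows))) stop("duplicate MSA row ids")
  if (length(unique(nchar(rows))) > 1L) stop("MSA rows differ in length")
  structure(rows, class = "hblhb_msa")
}

#' @export
print.hblhb_msa <- function(x, ...) {
  cat("Multiple alignment: ", length(x), " sequences x ",
      if (length(x)) nchar(x[[1]]) else 0L, " columns\n", sep = "")
  invisible(x)
}

# n x L character matrix of an MSA.
.msa_matrix <- function(msa) {
  do.call(rbind, strsplit(unclass(msa), ""))
}

.msa_from_matrix <- function(chmat, ids) {
  new_msa(structure(apply(chmat, 1L, paste, collapse = ""), names = ids))
}

#' Remove gaps from MSA rows
#'
#' @param msa An [new_msa()] object.
#' @return Named character vector of ungapped sequences.
#' @export
degap <- function(msa) {
  structure(gsub("-", "", unclass(msa)), names = names(msa))
}

# Shared-k-mer distance between ungapped sequences, used for the guide tree.
.kmer_distance <- function(seqs, k = 3L) {
  if (min(nchar(seqs)) < k) k <- 1L
  sets <- lapply(seqs, function(s) {
    unique(substring(s, seq_len(nchar(s) - k + 1L),
                     seq_len(nchar(s) - k + 1L) + k - 1L))
  })
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- length(intersect(sets[[i]], sets[[j]]))
      d[i, j] <- d[j, i] <-
        1 - shared / min(length(sets[[i]]), length(sets[[j]]))
    }
  }
  d
}

# Residue-count profile of a set of gapped rows (letters x columns); gaps
# contribute nothing.
.profile_counts <- function(rows, letters) {
  chmat <- do.call(rbind, strsplit(rows, ""))
  out <- matrix(0, length(letters), ncol(chmat))
  for (l in seq_along(letters)) out[l, ] <- colSums(chmat == letters[l])
  out
}

# Align two profiles (lists of gapped rows) and return the merged rows.
.merge_profiles <- function(rows1, rows2, S, go, ge) {
  letters <- rownames(S)
  C1 <- .profile_counts(rows1, letters)
  C2 <- .profile_counts(rows2, letters)
  cell <- crossprod(C1, S %*% C2) / (length(rows1) * length(rows2))
  path <- .affine_dp(cell, go, ge)$path
  n_col <- length(path)
  take1 <- integer(n_col); take2 <- integer(n_col)
  i <- 0L; j <- 0L
  for (k in seq_len(n_col)) {
    mv <- path[k]
    if (mv != 1L) i <- i + 1L
    if (mv != 2L) j <- j + 1L
    take1[k] <- if (mv == 1L) NA_integer_ else i
    take2[k] <- if (mv == 2L) NA_integer_ else j
  }
  expand <- function(row, take) {
    ch <- strsplit(row, "")[[1]]
    out <- rep("-", length(take))
    out[!is.na(take)] <- ch[take[!is.na(take)]]
    paste(out, collapse = "")
  }
  c(vapply(rows1, expand, "", take = take1),
    vapply(rows2, expand, "", take = take2))
}

#' Progressive multiple sequence alignment
#'
#' Aligns proteins progressively along a guide tree: pairwise k-mer
#' distances, a neighbor-joining guide tree (midpoint-rooted), and
#' profile-profile merges with the same affine-gap kernel used by
#' [nw_align()]. Deterministic for a given input.
#'
#' @param seqs Named character vector of >= 2 ungapped protein sequences
#'   with unique ids.
#' @inheritParams nw_align
#' @return An `hblhb_msa` whose de-gapped rows reproduce the inputs, in
#'   input order.
#' @export
progressive_msa <- function(seqs, matrix = blosum62(), gap_open = 10,
                            gap_extend = 1) {
  if (length(seqs) < 2L) stop("need at least two sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must have unique ids")
  }
  go <- abs(gap_open); ge <- abs(gap_extend)
  S <- matrix
  if (length(seqs) == 2L) {
    al <- nw_align(seqs[[1]], seqs[[2]], matrix = S, gap_open = go,
                   gap_extend = ge)
    rows <- structure(c(al$aligned_a, al$aligned_b), names = names(seqs))
    return(new_msa(rows))
  }
  guide <- midpoint_root(nj_tree(.kmer_distance(seqs)))
  ntip <- length(guide$tip.label)
  align_node <- function(node) {
    if (node <= ntip) {
      return(structure(seqs[guide$tip.label[node]],
                       names = guide$tip.label[node]))
    }
    children <- guide$edge[guide$edge[, 1] == node, 2]
    profs <- lapply(children, align_node)
    Reduce(function(p1, p2) .merge_profiles(p1, p2, S, go, ge), profs)
  }
  rows <- align_node(ntip + 1L)
  new_msa(rows[names(seqs)])
}

#' Gap-threshold column trimming
#'
#' Removes gap-rich alignment columns: a column is kept iff the fraction of
#' rows holding a residue (non-gap) in it is at least `gt`. This is the
#' trimAl `-gt` convention; the screening pipeline uses 0.5 for linker and
#' 0.75 for extracellular-globin alignments.
#'
#' @param msa An `hblhb_msa`.
#' @param gt Gap threshold in `[0, 1]`.
#' @return Trimmed `hblhb_msa` with attribute `kept_columns` (indices of
#'   retained columns in the input).
#' @export
trim_columns <- function(msa, gt) {
  stopifnot(inherits(msa, "hblhb_msa"), gt >= 0, gt <= 1)
  chmat <- .msa_matrix(msa)
  frac <- colMeans(chmat != "-")
  keep <- which(frac >= gt)
  out <- .msa_from_matrix(chmat[, keep, drop = FALSE], names(msa))
  attr(out, "kept_columns") <- keep
  out
}

#' Trim alignment columns 5' of the majority start methionine
#'
#' Locates, for every row containing a methionine, the alignment column of
#' its first `M`; the start column is the leftmost column by which at least
#' half of those rows have seen their first `M` (their median start). All
#' columns left of it are removed. Rows without any methionine do not vote
#' but are trimmed with the block.
#'
#' @param msa An `hblhb_msa`.
#' @return Trimmed `hblhb_msa` with attribute `kept_columns`.
#' @export
trim_to_start <- function(msa) {
  stopifnot(inherits(msa, "hblhb_msa"))
  first_m <- regexpr("M", unclass(msa), fixed = TRUE)
  voters <- first_m[first_m > 0L]
  if (!length(voters)) {
    warning("no row contains a methionine; alignment left untouched")
    attr(msa, "kept_columns") <- seq_len(nchar(msa[[1]]))
    return(msa)
  }
  start_col <- sort(voters)[ceiling(length(voters) / 2)]
  chmat <- .msa_matrix(msa)
  keep <- seq(start_col, ncol(chmat))
  out <- .msa_from_matrix(chmat[, keep, drop = FALSE], names(msa))
  attr(out, "kept_columns") <- keep
  out
}

#' Read/write aligned FASTA
#'
#' @param path FASTA file of equal-length gapped protein rows.
#' @return `read_msa()`: an `hblhb_msa`; `write_msa()`: `path` invisibly.
#' @export
read_msa <- function(path) {
  new_msa(read_fasta(path, type = "AA"))
}

#' @rdname read_msa
#' @param msa An `hblhb_msa`.
#' @export
write_msa <- function(msa, path) {
  write_fasta(unclass(msa), path, type = "AA")
}
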