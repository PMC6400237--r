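# Independent brute-force oracles and random-input builders used across the
# suite. These deliberately re-derive results by the most literal method
# available and share no code path with the implementation they check.

AA20_ <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(n, alphabet = AA20_) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# ---- LDL-A motif: naive character-by-character backtracking matcher -------
# Returns an integer vector of length nchar(aa): the minimal match span
# anchored at each start position, NA where no match exists.
oracle_ldla_spans <- function(aa, pattern = ldla_pattern()) {
  ch <- strsplit(aa, "")[[1]]
  n <- length(ch)
  n_el <- nrow(pattern)
  match_from <- function(pos, el) {
    if (el > n_el) return(0L)
    res <- pattern$residue[el]
    if (!is.na(res)) {
      if (pos > n || ch[pos] != res) return(NA_integer_)
      rest <- match_from(pos + 1L, el + 1L)
      if (is.na(rest)) return(NA_integer_)
      return(1L + rest)
    }
    best <- NA_integer_
    for (len in pattern$min_len[el]:pattern$max_len[el]) {
      if (pos + len > n + 1L) break
      rest <- match_from(pos + len, el + 1L)
      if (!is.na(rest)) {
        cand <- len + rest
        if (is.na(best) || cand < best) best <- cand
      }
    }
    best
  }
  vapply(seq_len(n), function(s) match_from(s, 1L), integer(1))
}

# Plant one motif instance (random spacer lengths) into a random background
# at a random feasible start; background may contain cysteines.
plant_motif <- function(n_bg = 100L, pattern = ldla_pattern()) {
  lens <- pattern$min_len
  var_gap <- which(is.na(pattern$residue) & pattern$max_len > pattern$min_len)
  for (i in var_gap) lens[i] <- sample(pattern$min_len[i]:pattern$max_len[i], 1L)
  span <- sum(lens)
  offs <- c(0L, cumsum(lens)[-length(lens)])
  fixed <- which(!is.na(pattern$residue))
  motif <- sample(AA20_, span, replace = TRUE)
  motif[offs[fixed] + 1L] <- pattern$residue[fixed]
  bg <- sample(AA20_, n_bg, replace = TRUE)
  start <- sample(seq_len(n_bg - span + 1L), 1L)
  bg[start:(start + span - 1L)] <- motif
  paste(bg, collapse = "")
}

# ---- affine-gap global alignment: exhaustive path enumeration -------------
oracle_affine_score <- function(a, b, S = blosum62(), go = 10, ge = 1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na_ <- length(ca); nb_ <- length(cb)
  best <- -Inf
  rec <- function(i, j, state, sc) {
    if (i > na_ && j > nb_) {
      if (sc > best) best <<- sc
      return(invisible(NULL))
    }
    if (i <= na_ && j <= nb_) rec(i + 1L, j + 1L, 0L, sc + S[ca[i], cb[j]])
    if (j <= nb_) rec(i, j + 1L, 1L, sc - if (state == 1L) ge else go + ge)
    if (i <= na_) rec(i + 1L, j, 2L, sc - if (state == 2L) ge else go + ge)
  }
  rec(1L, 1L, 0L, 0)
  best
}

# ---- ORFs: scan every ATG occurrence on both strands ----------------------
oracle_orfs <- function(seq, min_aa) {
  code <- Biostrings::GENETIC_CODE
  translate_codon <- function(cdn) {
    out <- code[cdn]
    if (is.na(out)) "X" else unname(out)
  }
  out <- list()
  L <- nchar(seq)
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) seq else
      intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", seq))))
    for (q in seq_len(L - 2L)) {            # 1-based ATG position on strand
      if (substr(s, q, q + 2L) != "ATG") next
      aa <- character(0)
      p <- q
      hit_stop <- FALSE
      while (p + 2L <= L) {
        r <- translate_codon(substr(s, p, p + 2L))
        if (r == "*") { hit_stop <- TRUE; break }
        aa <- c(aa, r)
        p <- p + 3L
      }
      if (length(aa) < min_aa) next
      offset <- (q - 1L) %% 3L
      start_f <- q - 1L
      end_f <- start_f + 3L * length(aa)
      out[[length(out) + 1L]] <- data.frame(
        frame = strand * (offset + 1L),
        start_nt = if (strand == 1L) start_f else L - end_f,
        end_nt = if (strand == 1L) end_f else L - start_f,
        aa = paste(aa, collapse = ""),
        has_stop = hit_stop)
    }
  }
  if (!length(out)) {
    return(data.frame(frame = integer(), start_nt = integer(),
                      end_nt = integer(), aa = character(),
                      has_stop = logical()))
  }
  do.call(rbind, out)
}

# ---- midpoint: exhaustive minimax search over all edge points -------------
# Minimal achievable maximum point-to-leaf distance over every point of the
# tree; exact because the per-edge objective is piecewise linear with
# breakpoints only at pairwise line crossings.
oracle_minmax_depth <- function(tree) {
  ntip <- length(tree$tip.label)
  D <- ape::dist.nodes(tree)
  best <- Inf
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    Len <- tree$edge.length[e]
    A <- D[u, seq_len(ntip)]   # via u at offset x
    B <- D[v, seq_len(ntip)]   # via v at offset Len - x
    f <- function(x) max(pmin(A + x, B + (Len - x)))
    xs <- c(0, Len, outer(B + Len, A, "-") / 2)
    xs <- unique(pmin(pmax(xs, 0), Len))
    best <- min(best, min(vapply(xs, f, numeric(1))))
  }
  best
}

# ---- random gapped MSAs for trimming tests --------------------------------
random_msa <- function(n_rows = sample(3:8, 1), n_cols = sample(10:40, 1),
                       gap_prob = 0.3) {
  rows <- vapply(seq_len(n_rows), function(i) {
    ch <- sample(AA20_, n_cols, replace = TRUE)
    ch[runif(n_cols) < gap_prob] <- "-"
    paste(ch, collapse = "")
  }, "")
  names(rows) <- paste0("r", seq_len(n_rows))
  new_msa(rows)
}
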