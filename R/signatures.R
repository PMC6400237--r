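#' The LDL-A cysteine-rich linker signature
#'
#' The linker chains of HBL-Hb carry a cysteine-rich module homologous to
#' the low-density-lipoprotein receptor class A (LDL-A) domain. The default
#' pattern encodes its fixed-residue/spacer structure:
#' Cys-X(5-7)-Cys-X(5-6)-Cys-X(6)-Cys-Asp-X(3)-Asp-Cys-X(4)-Asp-Glu-X(2-4)-Cys,
#' i.e. six cysteines, three aspartates and one glutamate with bounded
#' spacer runs; any match spans 35-40 residues.
#'
#' @param residues Character vector: a residue letter for fixed elements,
#'   `NA` for a spacer run.
#' @param min_len,max_len Integer vectors of per-element length bounds
#'   (fixed elements must have both equal to 1).
#' @return A data.frame of class `ldla_pattern` with columns `residue`,
#'   `min_len`, `max_len`.
#' @export
ldla_pattern <- function(residues = c("C", NA, "C", NA, "C", NA, "C", "D",
                                      NA, "D", "C", NA, "D", "E", NA, "C"),
                         min_len = c(1L, 5L, 1L, 5L, 1L, 6L, 1L, 1L,
                                     3L, 1L, 1L, 4L, 1L, 1L, 2L, 1L),
                         max_len = c(1L, 7L, 1L, 6L, 1L, 6L, 1L, 1L,
                                     3L, 1L, 1L, 4L, 1L, 1L, 4L, 1L)) {
  p <- data.frame(residue = residues, min_len = as.integer(min_len),
                  max_len = as.integer(max_len))
  .validate_ldla(p)
  class(p) <- c("ldla_pattern", "data.frame")
  p
}

.validate_ldla <- function(p) {
  if (any(p$max_len < p$min_len)) {
    stop("pattern configuration error: max_len < min_len")
  }
  if (any(p$min_len < 1L)) stop("pattern element lengths must be >= 1")
  fixed <- !is.na(p$residue)
  if (any(p$min_len[fixed] != 1L | p$max_len[fixed] != 1L)) {
    stop("fixed pattern elements must have min_len = max_len = 1")
  }
  invisible(p)
}

# All spacer-length combinations of a pattern, ordered by total span then by
# enumeration order (so the first hit per start is a shortest match).
.ldla_combos <- function(p) {
  gap_idx <- which(is.na(p$residue))
  grid <- expand.grid(lapply(gap_idx, function(i) p$min_len[i]:p$max_len[i]),
                      KEEP.OUT.ATTRS = FALSE)
  fixed_idx <- which(!is.na(p$residue))
  combos <- lapply(seq_len(nrow(grid)), function(r) {
    lens <- p$min_len
    lens[gap_idx] <- as.integer(grid[r, ])
    offs <- c(0L, cumsum(lens)[-length(lens)])  # 0-based element offsets
    list(span = sum(lens), fixed_off = offs[fixed_idx],
         fixed_res = p$residue[fixed_idx])
  })
  combos[order(vapply(combos, `[[`, 0L, "span"))]
}

#' Match the LDL-A signature in a protein
#'
#' Finds every start position at which the pattern matches, collapsing all
#' valid spacer-length combinations at one start to a single match with the
#' shortest span. Fixed elements must match their residue letter exactly,
#' so `X` never satisfies a fixed element; spacer positions accept any
#' residue. Deterministic.
#'
#' @param aa Protein string (20-letter alphabet plus `X`).
#' @param pattern An [ldla_pattern()].
#' @return A list of matches, each a list with `start`, `end` (0-based,
#'   half-open span on `aa`) and `anchors` (0-based positions of the fixed
#'   elements, named by their residue letters).
#' @export
match_ldla <- function(aa, pattern = ldla_pattern()) {
  .validate_ldla(pattern)
  n <- nchar(aa)
  if (n == 0L) return(list())
  ch <- strsplit(aa, "")[[1]]
  combos <- .ldla_combos(pattern)
  best_span <- rep(NA_integer_, n)
  best_anchor <- vector("list", n)
  for (cmb in combos) {
    max_start <- n - cmb$span + 1L
    if (max_start < 1L) next
    s <- seq_len(max_start)
    s <- s[is.na(best_span[s])]  # earlier (shorter) combos already won
    if (!length(s)) next
    ok <- rep(TRUE, length(s))
    for (f in seq_along(cmb$fixed_off)) {
      ok <- ok & ch[s + cmb$fixed_off[f]] == cmb$fixed_res[f]
    }
    hit <- s[ok]
    if (length(hit)) {
      best_span[hit] <- cmb$span
      for (h in hit) {
        best_anchor[[h]] <- structure(h - 1L + cmb$fixed_off,
                                      names = cmb$fixed_res)
      }
    }
  }
  starts <- which(!is.na(best_span))
  lapply(starts, function(s) {
    list(start = s - 1L, end = s - 1L + best_span[s],
         anchors = best_anchor[[s]])
  })
}

#' The extracellular-globin invariant-residue set
#'
#' Extracellular globins of HBL-Hb share 12 invariant residues in classical
#' alignment numbering on a reference chain: Cys-19, Trp-31, Phe-63,
#' Val-66, Phe-76, His-79, Arg-82, His-106, Gln-110, His-111, Trp-144 and
#' Cys-147. Cys-19, which enables the disulfide-bonded globin trimers, is
#' the feature separating extracellular from intracellular globins and can
#' never be waived.
#'
#' @param positions 1-based positions on the reference, strictly increasing.
#' @param residues Residue letters at those positions.
#' @param required_positions Positions that must always be present
#'   (default: 19, i.e. Cys-19).
#' @param reference_id Optional label of the reference the numbering is on.
#' @return A data.frame of class `invariant_set` with columns `position`,
#'   `residue` and attributes `required_positions`, `reference_id`.
#' @export
invariant_residue_set <- function(positions = c(19L, 31L, 63L, 66L, 76L, 79L,
                                                82L, 106L, 110L, 111L, 144L,
                                                147L),
                                  residues = c("C", "W", "F", "V", "F", "H",
                                               "R", "H", "Q", "H", "W", "C"),
                                  required_positions = 19L,
                                  reference_id = "reference_globin") {
  stopifnot(length(positions) == length(residues))
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("invariant positions must be strictly increasing")
  }
  if (!all(required_positions %in% positions)) {
    stop("required_positions must be a subset of positions")
  }
  s <- data.frame(position = as.integer(positions), residue = residues)
  attr(s, "required_positions") <- as.integer(required_positions)
  attr(s, "reference_id") <- reference_id
  class(s) <- c("invariant_set", "data.frame")
  s
}

#' Check invariant residues through a reference alignment
#'
#' Globally aligns a candidate to the reference carrying the invariant
#' numbering, then reads, for each invariant site, the candidate residue in
#' the column aligned to that reference position. A site aligned to a gap
#' counts as missing; `X` never satisfies a site.
#'
#' @param candidate Non-empty protein string.
#' @param reference Reference protein; must be at least as long as the
#'   largest site position.
#' @param sites An [invariant_residue_set()].
#' @param ... Passed to [nw_align()].
#' @return List with `invariant_hits` (count), `missing_sites` (labels such
#'   as `"C19"`), and `missing_positions`.
#' @export
check_invariants <- function(candidate, reference,
                             sites = invariant_residue_set(), ...) {
  stopifnot(nchar(candidate) >= 1L)
  if (max(sites$position) > nchar(reference)) {
    stop("configuration error: invariant site position ",
         max(sites$position), " beyond reference length ", nchar(reference))
  }
  al <- nw_align(candidate, reference, ...)
  a_ch <- strsplit(al$aligned_a, "")[[1]]
  b_ch <- strsplit(al$aligned_b, "")[[1]]
  ref_cols <- which(b_ch != "-")           # alignment column of ref position p
  cand_at_site <- a_ch[ref_cols[sites$position]]
  hit <- cand_at_site == sites$residue
  list(invariant_hits = sum(hit),
       missing_sites = paste0(sites$residue, sites$position)[!hit],
       missing_positions = sites$position[!hit])
}

#' Class-specific minimum-length filter
#'
#' Linker and extracellular-globin candidates must exceed 200 and 130
#' residues respectively (strict inequality).
#'
#' @param aa Protein string.
#' @param cls `"LINKER"` or `"EX_GLOBIN"`.
#' @param thresholds Named positive thresholds per class.
#' @return `TRUE` iff `nchar(aa) > thresholds[cls]`.
#' @export
length_filter <- function(aa, cls,
                          thresholds = c(LINKER = 200L, EX_GLOBIN = 130L)) {
  if (any(thresholds <= 0)) stop("length thresholds must be positive")
  if (!cls %in% names(thresholds)) stop("unknown class: ", cls)
  nchar(aa) > thresholds[[cls]]
}

#' Similarity prescreen against reference proteins
#'
#' Global-alignment percent identity of a candidate against each reference;
#' returns the best hit if it reaches `min_identity`. This stands in for
#' the annotation-database prescreen of the original cascade: its job is to
#' cheaply shortlist candidates, while the decisive filters are the
#' signature checks. Ties are broken by reference order; deterministic.
#'
#' @param aa Protein string.
#' @param refs Non-empty named character vector of reference proteins.
#' @param min_identity Minimum identity fraction (default 0.35).
#' @return List with `reference_id` and `identity`, or `NULL` if no
#'   reference reaches `min_identity`.
#' @export
prescreen_similarity <- function(aa, refs, min_identity = 0.35) {
  if (!length(refs)) stop("reference set must be non-empty")
  if (is.null(names(refs))) stop("references must be named")
  ids <- vapply(refs, function(r) nw_align(aa, r)$identity, numeric(1))
  best <- which.max(ids)
  if (ids[best] >= min_identity) {
    list(reference_id = names(refs)[best], identity = unname(ids[best]))
  } else {
    NULL
  }
}
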