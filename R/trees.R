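#' Pairwise distances from a protein alignment
#'
#' p-distance (mismatches over compared columns, where a compared column
#' has a residue in both rows) or its Poisson correction `-ln(1 - p)`.
#' `X` is compared literally like any residue.
#'
#' @param msa An [new_msa()] object with >= 2 rows.
#' @param model `"p"` or `"poisson"`.
#' @return Symmetric numeric matrix with zero diagonal and row ids as
#'   dimnames.
#' @export
distance_matrix <- function(msa, model = c("p", "poisson")) {
  model <- match.arg(model)
  stopifnot(inherits(msa, "hblhb_msa"), length(msa) >= 2L)
  chmat <- .msa_matrix(msa)
  n <- nrow(chmat)
  ids <- names(msa)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- chmat[i, ] != "-" & chmat[j, ] != "-"
      if (!any(ok)) {
        stop("no overlapping columns for pair ", ids[i], ", ", ids[j])
      }
      p <- mean(chmat[i, ok] != chmat[j, ok])
      if (model == "poisson") {
        if (p >= 1) {
          stop("saturated p-distance (p = 1) for pair ", ids[i], ", ",
               ids[j], "; Poisson correction undefined")
        }
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou–Nei neighbor joining on a symmetric distance matrix.
#' Deterministic: among tied minimal Q values the lowest-index pair is
#' joined. Negative branch lengths are clamped to zero with the deficit
#' moved to the sister edge (their sum is preserved).
#'
#' @param d Symmetric non-negative matrix with zero diagonal and unique
#'   row/column ids (>= 3 taxa).
#' @return An unrooted `phylo` object (ape).
#' @export
nj_tree <- function(d) {
  ids <- rownames(d)
  n <- length(ids)
  if (is.null(ids) || n < 3L) stop("need a labelled matrix with >= 3 taxa")
  if (!isTRUE(all.equal(d, t(d)))) stop("distance matrix must be symmetric")
  if (any(grepl("[(),:;\\s]", ids, perl = TRUE))) {
    stop("taxon ids must not contain newick metacharacters or whitespace")
  }
  fmt <- function(x) sprintf("%.12g", x)
  D <- d
  frag <- ids
  while (length(frag) > 3L) {
    m <- length(frag)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    hit <- which(Q == min(Q), arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- D[i, j]; li <- 0 }
    if (lj < 0) { li <- D[i, j]; lj <- 0 }
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    dnew <- pmax((D[i, ] + D[j, ] - D[i, j]) / 2, 0)[-c(i, j)]
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, dnew), c(dnew, 0))
    frag <- c(frag[-c(i, j)], newfrag)
  }
  lx <- max((D[1, 2] + D[1, 3] - D[2, 3]) / 2, 0)
  ly <- max((D[1, 2] + D[2, 3] - D[1, 3]) / 2, 0)
  lz <- max((D[1, 3] + D[2, 3] - D[1, 2]) / 2, 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], fmt(lx),
                 frag[2], fmt(ly), frag[3], fmt(lz))
  ape::read.tree(text = nwk)
}

#' Midpoint rooting
#'
#' Roots a tree at the midpoint of its longest leaf-to-leaf path (so the
#' maximum root-to-leaf distance equals half the tree diameter). If all
#' branch lengths are zero the tree is rooted, with a warning, at a
#' deterministic arbitrary position (the first tip's edge).
#'
#' @param tree A `phylo` object.
#' @return A rooted `phylo` object.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || all(tree$edge.length == 0)) {
    warning("all branch lengths are zero; rooting at an arbitrary node")
    return(ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE))
  }
  phangorn::midpoint(tree)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds
#' the NJ tree per replicate, and records for each internal edge of the
#' (midpoint-rooted) original tree the percentage of replicates containing
#' its bipartition. Reproducible for a given `seed`.
#'
#' @inheritParams distance_matrix
#' @param n_reps Number of bootstrap replicates (default 100).
#' @param seed Optional integer seed.
#' @return A rooted `phylo` with `node.label` holding supports in
#'   `[0, 100]` (the root label is empty).
#' @export
bootstrap_support <- function(msa, n_reps = 100L, model = c("p", "poisson"),
                              seed = NULL) {
  model <- match.arg(model)
  stopifnot(n_reps >= 1L)
  if (!is.null(seed)) set.seed(seed)
  chmat <- .msa_matrix(msa)
  L <- ncol(chmat)
  base <- midpoint_root(nj_tree(distance_matrix(msa, model)))
  reps <- vector("list", n_reps)
  for (k in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    m2 <- .msa_from_matrix(chmat[, cols, drop = FALSE], names(msa))
    reps[[k]] <- nj_tree(distance_matrix(m2, model))
  }
  cnt <- ape::prop.clades(base, reps, rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  support <- round(100 * cnt / n_reps, 1)
  support[1] <- NA  # root bipartition is trivial
  base$node.label <- ifelse(is.na(support), "", as.character(support))
  attr(base, "n_reps") <- n_reps
  base
}

#' Test a leaf set for monophyly
#'
#' A leaf set is monophyletic in a rooted tree iff it is exactly the leaf
#' set of some clade.
#'
#' @param tree A rooted `phylo` object (node labels, if any, are treated as
#'   supports).
#' @param leaves Character vector of tip labels (subset of the tree's
#'   tips).
#' @return List with `monophyletic` (logical), `clade` (tips of the
#'   smallest clade containing `leaves`), and `support` (that clade's node
#'   label, `NA` if absent).
#' @export
is_monophyletic <- function(tree, leaves) {
  stopifnot(inherits(tree, "phylo"))
  unknown <- setdiff(leaves, tree$tip.label)
  if (length(unknown)) {
    stop("unknown leaf label(s): ", paste(unknown, collapse = ", "))
  }
  if (length(leaves) == 1L) {
    return(list(monophyletic = TRUE, clade = leaves, support = NA_character_))
  }
  if (setequal(leaves, tree$tip.label)) {
    return(list(monophyletic = TRUE, clade = tree$tip.label,
                support = NA_character_))
  }
  mrca <- ape::getMRCA(tree, leaves)
  clade <- ape::extract.clade(tree, mrca)$tip.label
  support <- NA_character_
  if (!is.null(tree$node.label)) {
    support <- tree$node.label[mrca - length(tree$tip.label)]
  }
  list(monophyletic = setequal(clade, leaves), clade = clade,
       support = support)
}

#' Assign a chain type by nearest reference
#'
#' Labels a protein with the chain type (globin chains A/B with subtypes
#' A1/A2/B1/B2, linker chains L1/L2/L3) of its nearest reference by
#' global-alignment identity. Ties prefer the coarse classes A and B over
#' subtypes, then reference order.
#'
#' @param aa Protein string.
#' @param refs Named character vector of reference proteins; names must be
#'   chain types among A, B, A1, A2, B1, B2, L1, L2, L3.
#' @return List with `type` and `identity`.
#' @export
assign_chain_type <- function(aa, refs) {
  if (!length(refs)) stop("reference set must be non-empty")
  valid <- c("A", "B", "A1", "A2", "B1", "B2", "L1", "L2", "L3")
  if (!all(names(refs) %in% valid)) {
    stop("chain types must be among: ", paste(valid, collapse = ", "))
  }
  ids <- vapply(refs, function(r) nw_align(aa, r)$identity, numeric(1))
  rank <- ifelse(names(refs) %in% c("A", "B"), 1L, 2L)
  ord <- order(-ids, rank, seq_along(refs))
  best <- ord[1]
  list(type = names(refs)[best], identity = unname(ids[best]))
}
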