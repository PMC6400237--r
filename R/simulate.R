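#' Reference extracellular globin (synthetic)
#'
#' Builds a 158-residue synthetic reference globin: methionine at position
#' 1, the 12 invariant residues (Cys-19 ... Cys-147) at their canonical
#' positions, and all remaining sites drawn uniformly from the 19 non-Cys
#' residues -- extracellular globins characteristically carry exactly the
#' two invariant cysteines (which form the inter-chain disulfide), and
#' keeping the background Cys-free makes the Cys-19 check discriminate
#' exactly as intended (no chance cysteine can stand in for a knocked-out
#' Cys-19 through a shifted alignment). 158 residues matches the maximum
#' extracellular-globin alignment length observed across metazoans.
#'
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @param sites An [invariant_residue_set()].
#' @return Protein string with attribute `signature_sites` (the protected
#'   1-based positions: the start Met plus the invariant sites).
#' @export
make_reference_globin <- function(seed = NULL,
                                  sites = invariant_residue_set()) {
  if (!is.null(seed)) set.seed(seed)
  s <- sample(setdiff(AA20, "C"), 158L, replace = TRUE)
  s[1] <- "M"
  s[sites$position] <- sites$residue
  structure(paste(s, collapse = ""),
            signature_sites = c(1L, sites$position))
}

#' Reference linker chain (synthetic)
#'
#' Builds a 236-residue synthetic reference linker: methionine at position
#' 1 and exactly one embedded LDL-A motif instance with spacer lengths
#' drawn within the pattern bounds. All cysteines of the sequence belong to
#' the motif (non-motif positions are drawn from the 19 non-Cys residues),
#' which guarantees the motif match is unique. The motif is placed within
#' the first 140 residues so that truncation decoys retain it. 236
#' residues matches the maximum linker alignment length observed.
#'
#' @inheritParams make_reference_globin
#' @param pattern An [ldla_pattern()].
#' @return Protein string with attributes `signature_sites` (start Met plus
#'   motif anchor positions, 1-based), `motif_start`, `motif_end` (1-based,
#'   inclusive).
#' @export
make_reference_linker <- function(seed = NULL, pattern = ldla_pattern()) {
  if (!is.null(seed)) set.seed(seed)
  aa_no_c <- setdiff(AA20, "C")
  s <- sample(aa_no_c, 236L, replace = TRUE)
  s[1] <- "M"
  lens <- pattern$min_len
  var_gap <- which(is.na(pattern$residue) & pattern$max_len > pattern$min_len)
  for (i in var_gap) lens[i] <- sample(pattern$min_len[i]:pattern$max_len[i], 1L)
  span <- sum(lens)
  start <- sample(40:(140L - span), 1L)
  offs <- c(0L, cumsum(lens)[-length(lens)])
  motif <- sample(aa_no_c, span, replace = TRUE)
  fixed <- which(!is.na(pattern$residue))
  motif[offs[fixed] + 1L] <- pattern$residue[fixed]
  s[start:(start + span - 1L)] <- motif
  anchors <- start + offs[fixed]
  structure(paste(s, collapse = ""),
            signature_sites = c(1L, anchors),
            motif_start = start, motif_end = start + span - 1L)
}

#' Evolve a protein by random point substitution
#'
#' Each unprotected site is substituted, independently with probability
#' `rate`, by a uniformly drawn *different* residue; protected sites are
#' untouched. Deterministic for a given seed.
#'
#' @param protein Protein string.
#' @param rate Per-site substitution probability in `[0, 1]`.
#' @param protected_sites Integer vector of 1-based positions to protect.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @param alphabet Residues substitutions are drawn from (default: the 20
#'   standard amino acids). The transcriptome generator evolves linker-
#'   and globin-derived sequences over the 19 non-Cys residues so that a
#'   synthetic sequence's cysteine content is exactly its planted
#'   signature.
#' @return Mutant protein string with attribute `mutated_sites`.
#' @export
evolve_protein <- function(protein, rate, protected_sites = integer(),
                           seed = NULL, alphabet = AA20) {
  stopifnot(rate >= 0, rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  ch <- strsplit(protein, "")[[1]]
  hit <- runif(length(ch)) < rate
  hit[protected_sites] <- FALSE
  idx <- which(hit)
  for (i in idx) ch[i] <- sample(setdiff(alphabet, ch[i]), 1L)
  structure(paste(ch, collapse = ""), mutated_sites = idx)
}

# codon lists per amino acid, from the standard code
.codon_choices <- function() {
  if (is.null(.hblhb$codons)) {
    tbl <- GENETIC_CODE_TABLE
    .hblhb$codons <- split(names(tbl), unname(tbl))
  }
  .hblhb$codons
}

#' Back-translate a protein to a coding sequence
#'
#' Chooses uniformly among the synonymous codons of each residue (no
#' codon-usage model) and optionally appends a uniformly chosen stop
#' codon. Translating the result reproduces the protein exactly.
#'
#' @param protein Protein string over the 20 standard residues.
#' @param include_stop Append a stop codon (default `TRUE`).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Nucleotide string.
#' @export
back_translate <- function(protein, include_stop = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  choices <- .codon_choices()
  ch <- strsplit(protein, "")[[1]]
  if (any(!ch %in% AA20)) stop("protein contains non-standard residues")
  codons <- vapply(ch, function(a) {
    opts <- choices[[a]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, "")
  if (include_stop) codons <- c(codons, sample(choices[["*"]], 1L))
  paste(codons, collapse = "")
}

#' Synthetic-transcriptome configuration
#'
#' Study conditions for the planted-gene simulator: 10 species; per species
#' and class, a gene count drawn uniformly from 1 to 12 (matching the
#' observed per-species range of expressed genes) unless fixed counts are
#' given; per-site substitution rate 0.1 with signature sites protected;
#' three decoys per decoy class; UTR flanks of 30-150 nt.
#'
#' @param n_species Number of species.
#' @param genes_per_species `NULL` (draw 1-12 per class per species) or a
#'   named integer vector with entries `EX_GLOBIN`, `LINKER`.
#' @param substitution_rate Per-site substitution probability.
#' @param protect_signature_sites Protect invariant/motif sites (and the
#'   start Met) from mutation.
#' @param decoy_counts Named counts per decoy class
#'   (`DECOY_INTRACELLULAR_GLOBIN`, `DECOY_TRUNCATED_LINKER`,
#'   `DECOY_BROKEN_MOTIF`, `DECOY_RANDOM`).
#' @param utr_len_range Length range (min, max) of the random UTR flanks.
#' @param seed Integer seed; the whole output is reproducible given it.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_species = 10L,
                             genes_per_species = NULL,
                             substitution_rate = 0.1,
                             protect_signature_sites = TRUE,
                             decoy_counts = c(DECOY_INTRACELLULAR_GLOBIN = 3L,
                                              DECOY_TRUNCATED_LINKER = 3L,
                                              DECOY_BROKEN_MOTIF = 3L,
                                              DECOY_RANDOM = 3L),
                             utr_len_range = c(30L, 150L),
                             seed = 1L) {
  if (substitution_rate < 0 || substitution_rate > 1) {
    stop("substitution_rate must be in [0, 1]")
  }
  if (n_species < 1L) stop("need at least one species")
  if (any(decoy_counts < 0)) stop("decoy counts must be >= 0")
  if (length(utr_len_range) != 2L || utr_len_range[1] > utr_len_range[2] ||
      utr_len_range[1] < 0) {
    stop("impossible utr_len_range")
  }
  if (!is.null(genes_per_species)) {
    if (!all(c("EX_GLOBIN", "LINKER") %in% names(genes_per_species)) ||
        any(genes_per_species < 0)) {
      stop("genes_per_species needs non-negative EX_GLOBIN and LINKER counts")
    }
  }
  structure(list(n_species = as.integer(n_species),
                 genes_per_species = genes_per_species,
                 substitution_rate = substitution_rate,
                 protect_signature_sites = protect_signature_sites,
                 decoy_counts = decoy_counts,
                 utr_len_range = as.integer(utr_len_range),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

.random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")

# Wrap a protein into a Trinity-like contig: 5' UTR + CDS + stop + 3' UTR.
# The last codon-aligned triplet of the 5' UTR is forced to a stop so the
# planted CDS is never extended by a chance upstream in-frame start (real
# 5' UTRs essentially always carry in-frame stops).
.contigify <- function(protein, utr_range) {
  u5 <- sample(utr_range[1]:utr_range[2], 1L)
  u3 <- sample(utr_range[1]:utr_range[2], 1L)
  utr5 <- .random_dna(u5)
  if (u5 >= 3L) substr(utr5, u5 - 2L, u5) <- "TAA"
  paste0(utr5, back_translate(protein, include_stop = TRUE),
         .random_dna(u3))
}

#' Generate synthetic transcriptomes with planted genes and decoys
#'
#' Emulates Trinity-like assemblies: every planted extracellular globin or
#' linker is an evolved copy of the synthetic reference, back-translated
#' and wrapped in random UTR flanks; decoy contigs carry (i) intracellular
#' globin mimics (evolved globins with Cys-19 substituted), (ii) linkers
#' truncated to <= 200 aa, (iii) linkers with one motif anchor broken, and
#' (iv) random nucleotide contigs. A truth table labels every contig.
#'
#' @param cfg A [synthetic_config()].
#' @return Object of class `synthetic_transcriptome`: list with
#'   `sequences` (named list species -> named contig vector), `truth`
#'   (data.frame: `species`, `contig_id`, `label`, `protein`,
#'   `n_mutations`), `references` (list `EX_GLOBIN`, `LINKER`), `config`.
#' @export
build_transcriptome <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  ref_g <- make_reference_globin()
  ref_l <- make_reference_linker()
  prot_g <- if (cfg$protect_signature_sites)
    attr(ref_g, "signature_sites") else 1L
  prot_l <- if (cfg$protect_signature_sites)
    attr(ref_l, "signature_sites") else 1L
  anchors_l <- setdiff(attr(ref_l, "signature_sites"), 1L)
  rate <- cfg$substitution_rate
  aa_no_c <- setdiff(AA20, "C")

  seq_list <- vector("list", cfg$n_species)
  truth <- list()
  for (i in seq_len(cfg$n_species)) {
    sp <- sprintf("species_%02d", i)
    contigs <- character(0)
    add <- function(label, protein, n_mut) {
      cid <- sprintf("%s_c%03d", sp, length(contigs) + 1L)
      contigs[[cid]] <<- if (label == "DECOY_RANDOM") {
        .random_dna(sample(300:1200, 1L))
      } else {
        .contigify(protein, cfg$utr_len_range)
      }
      truth[[length(truth) + 1L]] <<- data.frame(
        species = sp, contig_id = cid, label = label,
        protein = if (is.null(protein)) NA_character_ else protein,
        n_mutations = n_mut)
    }
    n_g <- if (is.null(cfg$genes_per_species)) sample(1:12, 1L) else
      cfg$genes_per_species[["EX_GLOBIN"]]
    n_l <- if (is.null(cfg$genes_per_species)) sample(1:12, 1L) else
      cfg$genes_per_species[["LINKER"]]
    for (k in seq_len(n_g)) {
      p <- evolve_protein(ref_g, rate, prot_g, alphabet = aa_no_c)
      add("EX_GLOBIN", p, length(attr(p, "mutated_sites")))
    }
    for (k in seq_len(n_l)) {
      p <- evolve_protein(ref_l, rate, prot_l, alphabet = aa_no_c)
      add("LINKER", p, length(attr(p, "mutated_sites")))
    }
    dc <- cfg$decoy_counts
    for (k in seq_len(dc[["DECOY_INTRACELLULAR_GLOBIN"]])) {
      p <- evolve_protein(ref_g, rate, prot_g, alphabet = aa_no_c)
      ch <- strsplit(unclass(p), "")[[1]]
      ch[19] <- sample(setdiff(AA20, "C"), 1L)   # knock out Cys-19
      add("DECOY_INTRACELLULAR_GLOBIN", paste(ch, collapse = ""),
          length(attr(p, "mutated_sites")) + 1L)
    }
    for (k in seq_len(dc[["DECOY_TRUNCATED_LINKER"]])) {
      p <- evolve_protein(ref_l, rate, prot_l, alphabet = aa_no_c)
      cut <- sample(150:200, 1L)
      add("DECOY_TRUNCATED_LINKER", substr(unclass(p), 1L, cut),
          length(attr(p, "mutated_sites")))
    }
    for (k in seq_len(dc[["DECOY_BROKEN_MOTIF"]])) {
      p <- evolve_protein(ref_l, rate, prot_l, alphabet = aa_no_c)
      ch <- strsplit(unclass(p), "")[[1]]
      a <- sample(anchors_l, 1L)
      ch[a] <- sample(setdiff(aa_no_c, ch[a]), 1L)  # never introduce a Cys
      add("DECOY_BROKEN_MOTIF", paste(ch, collapse = ""),
          length(attr(p, "mutated_sites")) + 1L)
    }
    for (k in seq_len(dc[["DECOY_RANDOM"]])) {
      add("DECOY_RANDOM", NULL, 0L)
    }
    seq_list[[i]] <- contigs
    names(seq_list)[i] <- sp
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  structure(list(sequences = seq_list, truth = truth,
                 references = list(EX_GLOBIN = unclass(ref_g)[[1]],
                                   LINKER = unclass(ref_l)[[1]]),
                 config = cfg),
            class = "synthetic_transcriptome")
}

#' Write a synthetic transcriptome to disk
#'
#' One nucleotide FASTA per species plus a `truth.tsv` table.
#'
#' @param sim A [build_transcriptome()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector species -> FASTA path, with attribute
#'   `truth_path`.
#' @export
write_transcriptomes <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_transcriptome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(sim$sequences), function(sp) {
    p <- file.path(dir, paste0(sp, ".fasta"))
    write_fasta(sim$sequences[[sp]], p, type = "DNA")
    p
  }, "")
  truth_path <- file.path(dir, "truth.tsv")
  write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  structure(paths, truth_path = truth_path)
}

#' Pipeline configuration matching a synthetic transcriptome
#'
#' Convenience constructor: a [pipeline_config()] whose reference sets are
#' the simulator's own reference globin and linker.
#'
#' @param sim A [build_transcriptome()] result.
#' @param ... Overrides passed to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
default_pipeline_config <- function(sim, ...) {
  pipeline_config(linker_refs = c(linker_ref = sim$references$LINKER),
                  globin_refs = c(globin_ref = sim$references$EX_GLOBIN),
                  ...)
}

#' Simulate diverged chain families
#'
#' Generates tip proteins for `n_clades` chain families descending from a
#' common ancestor: clade ancestors diverge from it at `between`
#' substitutions per site, tips within each clade at `within`. With
#' `between >> within` the clades are deep, strongly supported splits
#' (the globin A/B situation); with `between` comparable to `within` the
#' families interleave (the metazoan-level linker situation). Sequences
#' are substitution-only (equal length), so the tips form an alignment
#' directly.
#'
#' @param ancestor Ancestral protein (default: a synthetic reference
#'   globin).
#' @param labels Clade labels (one clade per label).
#' @param n_per_clade Tips per clade.
#' @param between,within Substitution rates.
#' @param seed Optional integer seed.
#' @return An `hblhb_msa` of tips named `<label>_<k>`, with attribute
#'   `clades` (named list label -> tip ids).
#' @export
simulate_chain_families <- function(ancestor = NULL, labels = c("A", "B"),
                                    n_per_clade = 4L, between = 0.5,
                                    within = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ancestor)) ancestor <- unclass(make_reference_globin())[[1]]
  rows <- character(0)
  clades <- list()
  for (li in seq_along(labels)) {
    anc <- if (li == 1L) ancestor else
      unclass(evolve_protein(ancestor, between))[[1]]
    ids <- sprintf("%s_%d", labels[li], seq_len(n_per_clade))
    for (id in ids) {
      rows[[id]] <- unclass(evolve_protein(anc, within))[[1]]
    }
    clades[[labels[li]]] <- ids
  }
  out <- new_msa(rows)
  attr(out, "clades") <- clades
  out
}
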