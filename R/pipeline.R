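#' Screening-pipeline configuration
#'
#' Bundles the cut-offs and reference sets of the HBL-Hb component screen:
#' minimum ORF length, similarity-prescreen identity, the class length
#' thresholds (linkers > 200 aa, extracellular globins > 130 aa), the LDL-A
#' pattern and invariant-residue set, the number of invariant mismatches
#' tolerated (default 0; Cys-19 can never be waived), the identity above
#' which a linker lacking a start methionine is still retained (default
#' 0.5, mirroring the retention of highly similar Met-less linkers), and
#' the per-species gene de-duplication identity (default 0.98).
#'
#' @param linker_refs,globin_refs Non-empty named character vectors of
#'   reference proteins per class.
#' @param invariant_reference Reference protein carrying the invariant-site
#'   numbering (defaults to the first globin reference).
#' @param min_orf_aa Minimum ORF length fed to the screen (default 50).
#' @param prescreen_min_identity Identity for the similarity prescreen.
#' @param allowed_mismatches Invariant sites that may be missing.
#' @param metless_linker_min_identity See description.
#' @param dedup_identity Two accepted candidates in one species at or above
#'   this identity collapse to one gene (longest kept).
#' @param length_thresholds Named class length thresholds.
#' @param gap_thresholds Trimming gap thresholds per class (0.5 linkers,
#'   0.75 globins), used downstream of the screen.
#' @param pattern An [ldla_pattern()].
#' @param invariants An [invariant_residue_set()].
#' @param seed Optional integer seed recorded in the config.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(linker_refs, globin_refs,
                            invariant_reference = globin_refs[[1]],
                            min_orf_aa = 50L,
                            prescreen_min_identity = 0.35,
                            allowed_mismatches = 0L,
                            metless_linker_min_identity = 0.5,
                            dedup_identity = 0.98,
                            length_thresholds = c(LINKER = 200L,
                                                  EX_GLOBIN = 130L),
                            gap_thresholds = c(LINKER = 0.5,
                                               EX_GLOBIN = 0.75),
                            pattern = ldla_pattern(),
                            invariants = invariant_residue_set(),
                            seed = NULL) {
  if (!length(linker_refs) || !length(globin_refs)) {
    stop("config error: reference sets must be non-empty for both classes")
  }
  if (is.null(names(linker_refs))) names(linker_refs) <-
      paste0("linker_ref", seq_along(linker_refs))
  if (is.null(names(globin_refs))) names(globin_refs) <-
      paste0("globin_ref", seq_along(globin_refs))
  if (any(length_thresholds <= 0) || min_orf_aa < 1L) {
    stop("config error: thresholds must be positive")
  }
  if (prescreen_min_identity < 0 || prescreen_min_identity > 1 ||
      dedup_identity < 0 || dedup_identity > 1) {
    stop("config error: identities must be in [0, 1]")
  }
  .validate_ldla(pattern)
  if (max(invariants$position) > nchar(invariant_reference)) {
    stop("config error: invariant positions exceed the invariant reference")
  }
  structure(list(linker_refs = linker_refs, globin_refs = globin_refs,
                 invariant_reference = invariant_reference,
                 min_orf_aa = as.integer(min_orf_aa),
                 prescreen_min_identity = prescreen_min_identity,
                 allowed_mismatches = as.integer(allowed_mismatches),
                 metless_linker_min_identity = metless_linker_min_identity,
                 dedup_identity = dedup_identity,
                 length_thresholds = length_thresholds,
                 gap_thresholds = gap_thresholds,
                 pattern = pattern, invariants = invariants, seed = seed),
            class = "pipeline_config")
}

#' Classify one candidate protein
#'
#' Applies the validation cascade to a candidate, for both classes
#' independently: similarity prescreen, class signature (LDL-A motif for
#' linkers; invariant residues read through a reference alignment for
#' globins), strict length filter, and the start-methionine rule (globins
#' require a leading Met; linkers without one are retained only at
#' prescreen identity >= `metless_linker_min_identity`). A candidate
#' passing both cascades is assigned to the class with the higher prescreen
#' identity (ties go to `EX_GLOBIN`).
#'
#' @param aa Non-empty candidate protein string.
#' @param cfg A [pipeline_config()].
#' @param id Candidate id recorded in the report.
#' @return Object of class `signature_report`: list with `candidate_id`,
#'   `prescreen` (per class), `motif_matches`, `invariant_hits`,
#'   `missing_sites`, `length_ok` (per class), `start_met_ok`,
#'   `failed_stage` (per class, `NA` if passed) and `assigned_class`
#'   (`"LINKER"`, `"EX_GLOBIN"` or `"NONE"`).
#' @export
classify_candidate <- function(aa, cfg, id = "candidate") {
  stopifnot(inherits(cfg, "pipeline_config"), nzchar(aa))
  start_met <- startsWith(aa, "M")
  length_ok <- c(LINKER = length_filter(aa, "LINKER", cfg$length_thresholds),
                 EX_GLOBIN = length_filter(aa, "EX_GLOBIN",
                                           cfg$length_thresholds))

  pre_l <- prescreen_similarity(aa, cfg$linker_refs,
                                cfg$prescreen_min_identity)
  motif <- list()
  stage_l <- NA_character_
  if (is.null(pre_l)) {
    stage_l <- "prescreen"
  } else {
    motif <- match_ldla(aa, cfg$pattern)
    if (!length(motif)) {
      stage_l <- "motif"
    } else if (!length_ok[["LINKER"]]) {
      stage_l <- "length"
    } else if (!start_met &&
               pre_l$identity < cfg$metless_linker_min_identity) {
      stage_l <- "start"
    }
  }

  pre_g <- prescreen_similarity(aa, cfg$globin_refs,
                                cfg$prescreen_min_identity)
  inv <- list(invariant_hits = NA_integer_, missing_sites = character(),
              missing_positions = integer())
  stage_g <- NA_character_
  if (is.null(pre_g)) {
    stage_g <- "prescreen"
  } else {
    inv <- check_invariants(aa, cfg$invariant_reference, cfg$invariants)
    required <- attr(cfg$invariants, "required_positions")
    sig_ok <- inv$invariant_hits >=
      nrow(cfg$invariants) - cfg$allowed_mismatches &&
      !any(required %in% inv$missing_positions)
    if (!sig_ok) {
      stage_g <- "invariants"
    } else if (!length_ok[["EX_GLOBIN"]]) {
      stage_g <- "length"
    } else if (!start_met) {
      stage_g <- "start"
    }
  }

  pass_l <- is.na(stage_l)
  pass_g <- is.na(stage_g)
  assigned <- if (pass_l && pass_g) {
    if (pre_l$identity > pre_g$identity) "LINKER" else "EX_GLOBIN"
  } else if (pass_l) "LINKER" else if (pass_g) "EX_GLOBIN" else "NONE"

  structure(list(candidate_id = id,
                 prescreen = list(LINKER = pre_l, EX_GLOBIN = pre_g),
                 motif_matches = motif,
                 invariant_hits = inv$invariant_hits,
                 missing_sites = inv$missing_sites,
                 length_ok = length_ok,
                 start_met_ok = start_met,
                 failed_stage = c(LINKER = stage_l, EX_GLOBIN = stage_g),
                 assigned_class = assigned),
            class = "signature_report")
}

# Greedy per-species de-duplication: keep the longest representative of
# every >= dedup_identity cluster.
.dedup_genes <- function(proteins, dedup_identity) {
  if (length(proteins) <= 1L) return(proteins)
  ord <- order(-nchar(proteins), names(proteins))
  kept <- character(0)
  for (id in names(proteins)[ord]) {
    dup <- any(vapply(kept, function(k) {
      nw_align(proteins[[id]], proteins[[k]])$identity >= dedup_identity
    }, logical(1)))
    if (!dup) kept <- c(kept, id)
  }
  proteins[sort(kept)]
}

#' Dual independent search over transcriptomes
#'
#' Runs the linker search and the extracellular-globin search independently
#' over all six-frame ORFs of every contig of every species. A contig
#' contributes at most one candidate per class (its best-scoring ORF, by
#' prescreen identity then length), and accepted candidates within a
#' species are de-duplicated at `cfg$dedup_identity` (longest kept) to
#' count genes rather than assembly isoforms. Unreadable inputs are
#' recorded per species without stopping the remaining species.
#'
#' @param transcriptomes Named character vector: species -> nucleotide
#'   FASTA path.
#' @param cfg A [pipeline_config()].
#' @return A data.frame of class `species_summary` with one row per
#'   species: `species`, `n_contigs`, `n_linker_genes`, `linker_ids`
#'   (list column of contig ids), `n_globin_genes`, `globin_ids`, `error`.
#'   Attributes: `proteins` (accepted gene proteins per class) and
#'   `reports` (all candidate [classify_candidate()] reports).
#' @export
run_dual_search <- function(transcriptomes, cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!length(transcriptomes) || is.null(names(transcriptomes))) {
    stop("transcriptomes must be a non-empty named vector of paths")
  }
  species <- sort(names(transcriptomes))
  rows <- vector("list", length(species))
  proteins <- list(LINKER = list(), EX_GLOBIN = list())
  reports <- list()
  for (si in seq_along(species)) {
    sp <- species[si]
    contigs <- tryCatch(read_fasta(transcriptomes[[sp]], type = "DNA"),
                        error = function(e) e)
    if (inherits(contigs, "error")) {
      rows[[si]] <- data.frame(species = sp, n_contigs = NA_integer_,
                               n_linker_genes = 0L, n_globin_genes = 0L,
                               error = conditionMessage(contigs))
      rows[[si]]$linker_ids <- list(character(0))
      rows[[si]]$globin_ids <- list(character(0))
      next
    }
    accepted <- list(LINKER = character(0), EX_GLOBIN = character(0))
    for (cid in names(contigs)) {
      orfs <- find_orfs(contigs[[cid]], min_aa = cfg$min_orf_aa,
                        contig_id = cid)
      if (!nrow(orfs)) next
      best <- list(LINKER = NULL, EX_GLOBIN = NULL)
      for (oi in seq_len(nrow(orfs))) {
        orf_id <- sprintf("%s|f%+d|%d", cid, orfs$frame[oi],
                          orfs$start_nt[oi])
        rep_ <- classify_candidate(orfs$aa[oi], cfg, id = orf_id)
        reports[[length(reports) + 1L]] <- c(list(species = sp), rep_)
        cls <- rep_$assigned_class
        if (cls == "NONE") next
        score <- c(rep_$prescreen[[cls]]$identity, nchar(orfs$aa[oi]))
        if (is.null(best[[cls]]) ||
            score[1] > best[[cls]]$score[1] ||
            (score[1] == best[[cls]]$score[1] &&
             score[2] > best[[cls]]$score[2])) {
          best[[cls]] <- list(aa = orfs$aa[oi], score = score)
        }
      }
      for (cls in names(best)) {
        if (!is.null(best[[cls]])) {
          accepted[[cls]][cid] <- best[[cls]]$aa
        }
      }
    }
    genes <- lapply(names(accepted), function(cls) {
      .dedup_genes(accepted[[cls]], cfg$dedup_identity)
    })
    names(genes) <- names(accepted)
    proteins$LINKER[[sp]] <- genes$LINKER
    proteins$EX_GLOBIN[[sp]] <- genes$EX_GLOBIN
    row <- data.frame(species = sp, n_contigs = length(contigs),
                      n_linker_genes = length(genes$LINKER),
                      n_globin_genes = length(genes$EX_GLOBIN),
                      error = NA_character_)
    row$linker_ids <- list(names(genes$LINKER))
    row$globin_ids <- list(names(genes$EX_GLOBIN))
    rows[[si]] <- row
  }
  out <- do.call(rbind, rows)
  out <- out[, c("species", "n_contigs", "n_linker_genes", "linker_ids",
                 "n_globin_genes", "globin_ids", "error")]
  rownames(out) <- NULL
  class(out) <- c("species_summary", "data.frame")
  attr(out, "proteins") <- proteins
  attr(out, "reports") <- reports
  out
}

#' Cross-validate the two independent searches
#'
#' The screen's two component classes corroborate each other: a species in
#' which both linkers and extracellular globins are found is a
#' cross-validated detection; species with a single class are flagged as
#' lower confidence.
#'
#' @param summaries A [run_dual_search()] result.
#' @param taxonomy Optional named vector species -> taxonomic group.
#' @return Data.frame with `species`, `category` (`both`, `linker_only`,
#'   `globin_only`, `neither`), `flagged`; attribute `counts` is the
#'   category table (per group when `taxonomy` is given).
#' @export
cross_validate <- function(summaries, taxonomy = NULL) {
  has_l <- summaries$n_linker_genes > 0
  has_g <- summaries$n_globin_genes > 0
  category <- ifelse(has_l & has_g, "both",
                     ifelse(has_l, "linker_only",
                            ifelse(has_g, "globin_only", "neither")))
  out <- data.frame(species = summaries$species, category = category,
                    flagged = category %in% c("linker_only", "globin_only"))
  if (!is.null(taxonomy)) {
    out$group <- unname(taxonomy[out$species])
    attr(out, "counts") <- table(out$group, out$category)
  } else {
    attr(out, "counts") <- table(out$category)
  }
  out
}

#' Write / read the species summary table
#'
#' Serializes a [run_dual_search()] summary as TSV, one row per species
#' with at least one detection (species empty in both classes are
#' omitted), id lists comma-joined, ordered by taxonomic group (if given)
#' then species name.
#'
#' @param summaries A `species_summary` data.frame.
#' @param path Output TSV path.
#' @param taxonomy Optional named vector species -> group.
#' @return `summary_table()`: the written data.frame, invisibly;
#'   `read_summary_table()`: a `species_summary` data.frame.
#' @export
summary_table <- function(summaries, path, taxonomy = NULL) {
  keep <- (summaries$n_linker_genes > 0 | summaries$n_globin_genes > 0) &
    is.na(summaries$error)
  s <- summaries[keep, , drop = FALSE]
  df <- data.frame(species = s$species, n_contigs = s$n_contigs,
                   n_linker_genes = s$n_linker_genes,
                   linker_ids = vapply(s$linker_ids, paste, "",
                                       collapse = ","),
                   n_globin_genes = s$n_globin_genes,
                   globin_ids = vapply(s$globin_ids, paste, "",
                                       collapse = ","))
  if (!is.null(taxonomy)) {
    df <- df[order(unname(taxonomy[df$species]), df$species), , drop = FALSE]
  } else {
    df <- df[order(df$species), , drop = FALSE]
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' @rdname summary_table
#' @export
read_summary_table <- function(path) {
  df <- read.delim(path, colClasses = "character")
  out <- data.frame(species = df$species,
                    n_contigs = as.integer(df$n_contigs),
                    n_linker_genes = as.integer(df$n_linker_genes),
                    n_globin_genes = as.integer(df$n_globin_genes),
                    error = rep(NA_character_, nrow(df)))
  split_ids <- function(x) {
    lapply(x, function(s) if (nzchar(s)) strsplit(s, ",")[[1]] else
      character(0))
  }
  out$linker_ids <- split_ids(df$linker_ids)
  out$globin_ids <- split_ids(df$globin_ids)
  out <- out[, c("species", "n_contigs", "n_linker_genes", "linker_ids",
                 "n_globin_genes", "globin_ids", "error")]
  class(out) <- c("species_summary", "data.frame")
  out
}

#' HBL-Hb stoichiometry model
#'
#' The earthworm-type complex assembles 12 globin dodecamers around a
#' central core of 12 linker trimers: 144 globin chains + 36 linker chains
#' = 180 polypeptide chains.
#'
#' @param n_dodecamers,globins_per_dodecamer,n_trimers,linkers_per_trimer
#'   Positive integers (defaults 12, 12, 12, 3).
#' @return Object of class `stoichiometry_model`.
#' @export
stoichiometry_model <- function(n_dodecamers = 12L,
                                globins_per_dodecamer = 12L,
                                n_trimers = 12L, linkers_per_trimer = 3L) {
  vals <- c(n_dodecamers, globins_per_dodecamer, n_trimers,
            linkers_per_trimer)
  if (any(vals <= 0) || any(vals != as.integer(vals))) {
    stop("stoichiometry fields must be positive integers")
  }
  structure(list(n_dodecamers = as.integer(n_dodecamers),
                 globins_per_dodecamer = as.integer(globins_per_dodecamer),
                 n_trimers = as.integer(n_trimers),
                 linkers_per_trimer = as.integer(linkers_per_trimer)),
            class = "stoichiometry_model")
}

#' Chain counts of the HBL-Hb complex
#'
#' @param m A [stoichiometry_model()].
#' @return Named integer vector `n_globin_chains`, `n_linker_chains`,
#'   `n_total_chains` (default model: 144, 36, 180).
#' @export
complex_stoichiometry <- function(m = stoichiometry_model()) {
  stopifnot(inherits(m, "stoichiometry_model"))
  g <- m$n_dodecamers * m$globins_per_dodecamer
  l <- m$n_trimers * m$linkers_per_trimer
  c(n_globin_chains = g, n_linker_chains = l, n_total_chains = g + l)
}
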