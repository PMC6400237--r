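# Small shared fixture: one synthetic transcriptome and its matching config.
small_sim <- function(seed = 7, ...) {
  build_transcriptome(synthetic_config(
    n_species = 2L,
    genes_per_species = c(EX_GLOBIN = 2L, LINKER = 2L),
    decoy_counts = c(DECOY_INTRACELLULAR_GLOBIN = 1L,
                     DECOY_TRUNCATED_LINKER = 1L,
                     DECOY_BROKEN_MOTIF = 1L, DECOY_RANDOM = 2L),
    seed = seed, ...))
}

test_that("the validation cascade assigns planted genes and rejects decoys", {
  sim <- small_sim()
  cfg <- default_pipeline_config(sim)
  truth <- sim$truth

  planted_linker <- truth$protein[truth$label == "LINKER"][1]
  expect_identical(classify_candidate(planted_linker, cfg)$assigned_class,
                   "LINKER")
  planted_globin <- truth$protein[truth$label == "EX_GLOBIN"][1]
  expect_identical(classify_candidate(planted_globin, cfg)$assigned_class,
                   "EX_GLOBIN")

  # intracellular-globin decoy: everything intact except Cys-19
  ig <- truth$protein[truth$label == "DECOY_INTRACELLULAR_GLOBIN"][1]
  r_ig <- classify_candidate(ig, cfg)
  expect_identical(r_ig$assigned_class, "NONE")
  expect_identical(unname(r_ig$failed_stage["EX_GLOBIN"]), "invariants")
  expect_true("C19" %in% r_ig$missing_sites)

  # truncated linker: motif intact but too short
  tl <- truth$protein[truth$label == "DECOY_TRUNCATED_LINKER"][1]
  r_tl <- classify_candidate(tl, cfg)
  expect_identical(r_tl$assigned_class, "NONE")
  expect_identical(unname(r_tl$failed_stage["LINKER"]), "length")

  # broken motif: full length but no signature
  bm <- truth$protein[truth$label == "DECOY_BROKEN_MOTIF"][1]
  r_bm <- classify_candidate(bm, cfg)
  expect_identical(r_bm$assigned_class, "NONE")
  expect_identical(unname(r_bm$failed_stage["LINKER"]), "motif")

  # a 180-aa truncation of a linker fails on length
  short <- substr(planted_linker, 1, 180)
  expect_identical(
    unname(classify_candidate(short, cfg)$failed_stage["LINKER"]), "length")
})

test_that("Met-less linkers are retained only at high prescreen identity", {
  sim <- small_sim()
  cfg <- default_pipeline_config(sim)
  linker <- sim$truth$protein[sim$truth$label == "LINKER"][1]
  metless <- substr(linker, 2, nchar(linker))  # drop the start Met
  r <- classify_candidate(metless, cfg)
  expect_identical(r$assigned_class, "LINKER")  # identity ~0.9 >= 0.5
  expect_false(r$start_met_ok)

  # a Met-less globin is never retained
  globin <- sim$truth$protein[sim$truth$label == "EX_GLOBIN"][1]
  metless_g <- paste0("A", substr(globin, 2, nchar(globin)))
  r_g <- classify_candidate(metless_g, cfg)
  expect_identical(unname(r_g$failed_stage["EX_GLOBIN"]), "start")
})

test_that("the dual search recovers the planted truth table end to end", {
  sim <- small_sim()
  dir <- tempfile()
  paths <- write_transcriptomes(sim, dir)
  res <- run_dual_search(paths, default_pipeline_config(sim))
  expect_s3_class(res, "species_summary")
  expect_identical(res$n_linker_genes, c(2L, 2L))
  expect_identical(res$n_globin_genes, c(2L, 2L))
  truth <- sim$truth
  for (i in seq_len(nrow(res))) {
    sp <- res$species[i]
    expect_setequal(res$linker_ids[[i]],
                    truth$contig_id[truth$species == sp &
                                      truth$label == "LINKER"])
    expect_setequal(res$globin_ids[[i]],
                    truth$contig_id[truth$species == sp &
                                      truth$label == "EX_GLOBIN"])
  }
  # counts equal id-list lengths
  expect_identical(res$n_linker_genes, lengths(res$linker_ids))

  # unreadable input is recorded without failing other species
  paths_bad <- c(paths, broken = file.path(dir, "absent.fasta"))
  res_bad <- run_dual_search(paths_bad, default_pipeline_config(sim))
  expect_identical(sum(!is.na(res_bad$error)), 1L)
  expect_identical(res_bad$n_linker_genes[is.na(res_bad$error)], c(2L, 2L))
})

test_that("the dual search is invariant to contig and species order", {
  sim <- small_sim(seed = 19)
  dir1 <- tempfile(); dir2 <- tempfile()
  paths1 <- write_transcriptomes(sim, dir1)
  # rewrite with contigs reversed and species order scrambled
  dir.create(dir2)
  paths2 <- vapply(names(sim$sequences), function(sp) {
    p <- file.path(dir2, paste0(sp, ".fasta"))
    write_fasta(rev(sim$sequences[[sp]]), p, type = "DNA")
    p
  }, "")
  paths2 <- rev(paths2)
  cfg <- default_pipeline_config(sim)
  r1 <- run_dual_search(paths1, cfg)
  r2 <- run_dual_search(paths2, cfg)
  expect_identical(r1$species, r2$species)
  expect_identical(r1$n_linker_genes, r2$n_linker_genes)
  expect_identical(r1$n_globin_genes, r2$n_globin_genes)
  expect_identical(lapply(r1$linker_ids, sort), lapply(r2$linker_ids, sort))
})

test_that("near-identical isoforms deduplicate to one gene per species", {
  sim <- small_sim(seed = 23)
  linker <- sim$truth$protein[sim$truth$label == "LINKER"][1]
  iso <- linker  # one substitution outside the motif: identity >> 0.98
  substr(iso, 200, 200) <- if (substr(iso, 200, 200) == "A") "G" else "A"
  cfg <- default_pipeline_config(sim)
  sp_dir <- tempfile(); dir.create(sp_dir)
  set.seed(1)
  contigs <- c(iso1 = paste0("TAA", back_translate(linker)),
               iso2 = paste0("TAA", back_translate(iso)))
  f <- file.path(sp_dir, "sp.fasta")
  write_fasta(contigs, f, type = "DNA")
  res <- run_dual_search(c(sp = f), cfg)
  expect_identical(res$n_linker_genes, 1L)
})

test_that("cross-validation partitions species by which searches fired", {
  s <- data.frame(species = c("s1", "s2", "s3", "s4"),
                  n_linker_genes = c(1L, 2L, 0L, 0L),
                  n_globin_genes = c(1L, 0L, 3L, 0L))
  cv <- cross_validate(s)
  expect_identical(cv$category,
                   c("both", "linker_only", "globin_only", "neither"))
  expect_identical(cv$flagged, c(FALSE, TRUE, TRUE, FALSE))
  tax <- c(s1 = "Annelida", s2 = "Annelida", s3 = "Mollusca",
           s4 = "Mollusca")
  cv2 <- cross_validate(s, taxonomy = tax)
  expect_identical(unname(attr(cv2, "counts")["Annelida", "linker_only"]), 1L)
})

test_that("the summary table omits empty species and round-trips through TSV", {
  sim <- small_sim(seed = 29)
  dir <- tempfile()
  res <- run_dual_search(write_transcriptomes(sim, dir),
                         default_pipeline_config(sim))
  empty <- res[1, ]
  empty$species <- "zz_empty"
  empty$n_linker_genes <- 0L; empty$n_globin_genes <- 0L
  empty$linker_ids <- list(character(0)); empty$globin_ids <- list(character(0))
  res2 <- rbind(res, empty)
  f <- tempfile(fileext = ".tsv")
  written <- summary_table(res2, f)
  expect_false("zz_empty" %in% written$species)
  back <- read_summary_table(f)
  expect_identical(back$species, res$species)
  expect_identical(back$n_linker_genes, res$n_linker_genes)
  expect_identical(back$linker_ids, res$linker_ids)
  expect_identical(back$globin_ids, res$globin_ids)

  # header-only table for empty summaries
  f2 <- tempfile(fileext = ".tsv")
  summary_table(res2[0, ], f2)
  expect_identical(nrow(read_summary_table(f2)), 0L)
})

test_that("stoichiometry multiplies out the complex architecture", {
  expect_identical(complex_stoichiometry(),
                   c(n_globin_chains = 144L, n_linker_chains = 36L,
                     n_total_chains = 180L))
  expect_identical(complex_stoichiometry(stoichiometry_model(1, 1, 1, 1)),
                   c(n_globin_chains = 1L, n_linker_chains = 1L,
                     n_total_chains = 2L))
  m <- stoichiometry_model(2, 12, 2, 3)
  got <- complex_stoichiometry(m)
  expect_identical(got, c(n_globin_chains = 24L, n_linker_chains = 6L,
                          n_total_chains = 30L))
  expect_identical(unname(got["n_total_chains"]),
                   unname(got["n_globin_chains"] + got["n_linker_chains"]))
  expect_error(stoichiometry_model(0, 12, 12, 3), "positive")
})
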