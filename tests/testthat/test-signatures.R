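# Minimal witness: the pattern's fixed residues joined by minimum-length
# runs of alanine -- a 35-residue string with exactly one match.
minimal_witness <- function(pattern = ldla_pattern()) {
  parts <- vapply(seq_len(nrow(pattern)), function(i) {
    if (is.na(pattern$residue[i])) {
      strrep("A", pattern$min_len[i])
    } else {
      pattern$residue[i]
    }
  }, "")
  paste(parts, collapse = "")
}

test_that("LDL-A pattern default has the documented shape", {
  p <- ldla_pattern()
  fixed <- p$residue[!is.na(p$residue)]
  expect_identical(sum(fixed == "C"), 6L)
  expect_identical(sum(fixed == "D"), 3L)
  expect_identical(sum(fixed == "E"), 1L)
  expect_identical(sum(p$min_len), 35L)
  expect_identical(sum(p$max_len), 40L)
  expect_error(ldla_pattern(min_len = c(1, 8, rep(1, 14)),
                            max_len = c(1, 7, rep(1, 14))),
               "max_len < min_len")
})

test_that("motif matching finds the minimal witness and dies on any knockout", {
  w <- minimal_witness()
  expect_identical(nchar(w), 35L)
  m <- match_ldla(w)
  expect_length(m, 1L)
  expect_identical(m[[1]]$start, 0L)
  expect_identical(m[[1]]$end, 35L)
  expect_length(match_ldla(""), 0L)

  # first Asp -> Asn destroys the match
  broken <- sub("D", "N", w)
  expect_length(match_ldla(broken), 0L)
  # removing any fixed residue (knock to 'A') destroys the single match
  for (a in m[[1]]$anchors) {
    kn <- w
    substr(kn, a + 1L, a + 1L) <- "A"
    expect_length(match_ldla(kn), 0L)
  }
  # X never satisfies a fixed element
  xed <- w
  substr(xed, 1L, 1L) <- "X"
  expect_length(match_ldla(xed), 0L)
})

test_that("motif matching agrees with the backtracking oracle on random and planted input", {
  set.seed(10)
  for (i in 1:150) {
    aa <- if (i %% 2 == 0) random_protein(100) else plant_motif(100)
    got <- match_ldla(aa)
    spans <- oracle_ldla_spans(aa)
    expect_identical(vapply(got, function(m) m$start + 1L, 0L),
                     which(!is.na(spans)))
    expect_identical(vapply(got, function(m) m$end - m$start, 0L),
                     unname(spans[!is.na(spans)]))
    for (m in got) {
      expect_true(m$end - m$start >= 35 && m$end - m$start <= 40)
      ch <- strsplit(aa, "")[[1]]
      expect_identical(ch[m$anchors + 1L], unname(names(m$anchors)))
    }
  }
})

test_that("invariant checking reads sites through the reference alignment", {
  ref <- make_reference_globin(seed = 1)
  sites <- invariant_residue_set()
  self <- check_invariants(ref, ref, sites)
  expect_identical(self$invariant_hits, 12L)
  expect_length(self$missing_sites, 0L)

  mut <- ref
  substr(mut, 19, 19) <- "S"
  ko <- check_invariants(mut, ref, sites)
  expect_identical(ko$invariant_hits, 11L)
  expect_identical(ko$missing_sites, "C19")

  # 5-residue insertion upstream shifts absolute positions but the
  # alignment recovers all 12 sites
  ins <- paste0(substr(ref, 1, 9), "AAAAA", substr(ref, 10, nchar(ref)))
  shifted <- check_invariants(ins, ref, sites)
  expect_identical(shifted$invariant_hits, 12L)

  # hits are non-increasing under additional site knockouts
  hits <- 12L
  mut2 <- ref
  for (p in sites$position) {
    substr(mut2, p, p) <- "G"
    h <- check_invariants(mut2, ref, sites)$invariant_hits
    expect_lte(h, hits)
    hits <- h
  }
  expect_error(check_invariants("MA", "SHORT", sites), "configuration error")
})

test_that("length filter enforces strict class thresholds and monotonicity", {
  expect_true(length_filter(strrep("A", 201), "LINKER"))
  expect_false(length_filter(strrep("A", 200), "LINKER"))
  expect_true(length_filter(strrep("A", 131), "EX_GLOBIN"))
  expect_false(length_filter(strrep("A", 130), "EX_GLOBIN"))
  expect_error(length_filter("AAA", "GLOBIN"), "unknown class")
  lens <- vapply(c(100, 200, 201, 300),
                 function(n) length_filter(strrep("A", n), "LINKER"),
                 logical(1))
  expect_identical(lens, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("similarity prescreen scores identity against the best reference", {
  set.seed(11)
  refs <- c(g1 = random_protein(158), g2 = random_protein(158))
  hit <- prescreen_similarity(refs[["g1"]], refs)
  expect_identical(hit$reference_id, "g1")
  expect_equal(hit$identity, 1.0)

  # ~10% mutated copy still hits the right reference above 0.85
  mut <- unclass(evolve_protein(refs[["g2"]], 0.1, seed = 3))[[1]]
  hit2 <- prescreen_similarity(mut, refs)
  expect_identical(hit2$reference_id, "g2")
  expect_gte(hit2$identity, 0.85)

  # random sequences do not reach 0.4 identity against these references
  n_pass <- sum(vapply(1:25, function(i) {
    !is.null(prescreen_similarity(random_protein(200), refs,
                                  min_identity = 0.4))
  }, logical(1)))
  expect_identical(n_pass, 0L)
})
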