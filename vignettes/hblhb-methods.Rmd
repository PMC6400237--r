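---
title: "Methods: signature-based discovery of HBL-Hb components and their gene genealogies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature-based discovery of HBL-Hb components and their gene genealogies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hblhb)
```

## The problem

Hexagonal-bilayer hemoglobin (HBL-Hb) is a giant extracellular
oxygen-transport complex best known from annelids: 12 globin dodecamers
(144 heme-binding chains) assembled around a core of 12 linker trimers
(36 heme-free chains), 180 polypeptides in all
(`complex_stoichiometry()`). Because the complex has two obligate protein
classes, a transcriptome either expresses both (strong evidence for the
complex) or only one (weak evidence, possibly mis-annotation). This
package implements the discovery side of that argument: screen assembled
transcriptomes for each class *independently*, validate candidates by
their sequence signatures, and cross-validate the two searches per
species, then reconstruct gene genealogies of the validated genes.

## The validation cascade

Candidates are all six-frame Met-to-stop ORFs of every contig
(`find_orfs`). ORF calling is exhaustive rather than model-based: the
cascade below, not an ORF score, decides retention. ORFs running off the
contig 3' end are kept (flagged) because assemblies truncate transcripts.
Each candidate then passes, per class:

1. **Similarity prescreen** (`prescreen_similarity`): global-alignment
   identity ≥ 0.35 against a reference set of the class. This stands in
   for the database-annotation prescreen of annotation pipelines; it is a
   cheap shortlist, deliberately permissive — the decisive filters are
   the signatures. 0.35 sits well above the identity of unrelated protein
   pairs under global alignment (~0.2 in our tests) and well below the
   ~0.65+ of genuinely homologous candidates.
2. **Class signature**. Linkers: at least one match of the LDL-A pattern
   `C-x(5,7)-C-x(5,6)-C-x(6)-C-D-x(3)-D-C-x(4)-D-E-x(2,4)-C`
   (`match_ldla`; every match necessarily spans 35–40 residues, all
   spacer-length combinations at one start are collapsed to the shortest).
   Globins: the 12 invariant residues Cys-19 … Cys-147 read through a
   global alignment to the reference carrying the numbering
   (`check_invariants`); a site aligned to a gap is missing, `X` never
   counts. By default all 12 are required, and Cys-19 — the residue that
   separates extracellular from intracellular globins — can never be
   waived regardless of `allowed_mismatches`.
3. **Length**: strictly more than 200 aa (linkers) or 130 aa (globins).
4. **Start methionine**: required for globins. Linkers lacking a leading
   Met are retained only when prescreen identity ≥ 0.5 — a deterministic
   proxy for the practice of keeping clearly homologous but 5'-truncated
   linker transcripts.

A candidate passing both cascades is assigned to the class with higher
prescreen identity (ties to the globin class, which has the stricter
signature). Per species, each contig contributes at most its
best-scoring candidate per class, and accepted candidates at ≥ 0.98
identity collapse to one gene (longest kept) so that assembly isoforms
are not counted as paralogs; 0.98 is configurable
(`pipeline_config(dedup_identity = )`). `cross_validate` then partitions
species into both / linker-only / globin-only / neither, flagging
single-class species as lower confidence.

## Alignment, trimming, genealogy

Pairwise alignment is global Needleman–Wunsch/Gotoh with BLOSUM62 and
affine gaps costing `gap_open + k·gap_extend` (defaults 10 and 1 — the
common defaults for protein-level global alignment); traceback ties are
fixed (match > gap in the first sequence > gap in the second) so results
are deterministic. The multiple aligner is progressive: 3-mer distances,
a neighbor-joining guide tree, midpoint-rooted, and profile–profile
merges through the same affine DP kernel with expected-BLOSUM column
scores. It makes no claim to consistency-based accuracy; it exists so
the pipeline is self-contained and deterministic, and its contract
(de-gapping reproduces the inputs; an isolated insertion becomes gap
columns elsewhere) is tested property-style.

Column trimming follows the trimAl `-gt` convention: keep a column iff
the fraction of rows with a residue is ≥ `gt`, with the class settings
0.5 (linkers) and 0.75 (globins). `trim_to_start` replaces manual
alignment curation with a deterministic rule: each Met-containing row
votes with the column of its first Met, and everything left of the
leftmost column by which half the voters have started (their median
start column) is removed. We read the "leftmost column in which at least
50% of rows have their first Met" cumulatively because an exact-column
reading is undefined when starts are spread; the two readings agree
whenever starts align, which is the intended use.

Distances are p-distances over pairwise non-gap columns (optionally
Poisson-corrected, `−ln(1−p)`); `X` is compared literally. Trees are
Saitou–Nei neighbor joining with two contractual details made explicit
because standard implementations hide them: ties in the Q matrix join
the lowest-index pair, and a negative branch-length estimate is clamped
to zero with the deficit moved to its sister edge (preserving their
sum). NJ is provably consistent on additive matrices, which the tests
exploit (exact recovery of 100 random 4–8-taxon additive trees).
Bootstrap support resamples alignment columns with replacement, rebuilds
the NJ tree per replicate, and reports the percentage of replicates
containing each bipartition of the midpoint-rooted original tree; 100
replicates is the package default. Midpoint rooting places the root so
the maximum root-to-leaf distance equals half the tree diameter; an
all-zero-length tree is rooted arbitrarily but deterministically, with a
warning. Bayesian and maximum-likelihood inference are deliberately out
of scope: distance NJ with bootstrap is sufficient to pose and test the
monophyly questions (A/B globin chains; L1–L3 linkers,
`is_monophyletic`, `assign_chain_type`) on desk-scale data.

## What the synthetic generator emulates — and what it does not

`build_transcriptome` produces Trinity-like contigs: a planted protein is
back-translated with uniform synonymous codon choice (no codon-usage
model — the pipeline analyses proteins, so codon bias is irrelevant
here), given a stop codon and random UTR flanks of 30–150 nt. The last
in-frame triplet of the 5' UTR is forced to a stop codon, as real 5'
UTRs essentially always contain one; without it, chance upstream
in-frame starts occasionally extended truncated decoys past the length
threshold, which would misrepresent the planted truth.

Study conditions (the generator defaults): 10 species; per species and
class a gene count drawn uniformly from 1–12, matching the observed
range of expressed genes per species; per-site substitution rate 0.1
from the class reference, with signature sites (invariants, motif
anchors, the start Met) protected; three decoys per class per species.
The references themselves are synthetic: a 158-residue globin and a
236-residue linker (the maximum alignment lengths of the two classes),
carrying their signatures by construction. Both classes are generated
and mutated over the 19 non-Cys residues, so a synthetic sequence's
cysteine content is exactly its planted signature: a broken-motif decoy
can never re-anchor the LDL-A pattern on a chance cysteine, and a
Cys-19 knockout can never be rescued by a shifted alignment onto a
background cysteine. For globins this matches biology (the two invariant
cysteines are the extracellular hallmark); for linkers it understates
real background cysteine content.

The four decoy classes operationalize the cascade's failure modes:
intracellular-globin mimics (evolved globins with Cys-19 substituted —
real intracellular globins differ far more broadly; Cys-19 loss is the
single discriminating feature we model), linkers truncated to ≤ 200 aa,
linkers with one motif anchor substituted, and random nucleotide
contigs. What passing tests show is therefore *internal* validity: the
cascade implements its stated rules exactly, recovers every planted gene
whose signature sites are intact, and rejects every decoy. They do not
show field performance on real assemblies, where divergence is not
i.i.d., isoforms and chimeras are messier than our truncation decoys,
and intracellular globins differ from extracellular ones at many sites.

`simulate_chain_families` provides the genealogy-side synthetic truth:
clade ancestors at divergence `between` (0.5 for a deep A/B-type split),
tips at `within` (0.02); with `between = 0` the labels carry no
phylogenetic signal, reproducing the situation where chain types are not
recoverable as clades.

## Numerical and scale choices

All randomness flows through explicit seeds; every generator function
accepts `seed = NULL` to use the ambient RNG stream so that one seed at
the top reproduces a whole cohort. Alignment scores are exact integers
under BLOSUM62 and integer gap costs, so score comparisons in tests are
exact; tree-length comparisons use 1e-8 tolerances. Problem sizes in the
test-suite and acceptance script — 10-species cohorts, 100-residue motif
test sequences, 4–10-taxon trees, 100 bootstrap replicates — are chosen
so the full synthetic study runs on a laptop in minutes while still
exercising every code path; the pipeline itself has no hard-coded size
limits.

## Known limitations

* The prescreen requires a reference set; sensitivity to HBL-Hb
  components highly diverged from all references is untested (and, with
  identity 0.35, limited by construction).
* The progressive aligner has no iterative refinement or
  consistency objective; deep alignments should be rebuilt with a
  dedicated MSA tool when accuracy matters more than self-containment.
* Invariant-site numbering is reference-relative; a user-supplied
  reference must carry the classical numbering (e.g. an earthworm chain)
  or supply adjusted positions via `invariant_residue_set`.
* Distance NJ does not estimate among-site rate variation; supports on
  real, saturated data will differ from likelihood-based analyses.
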