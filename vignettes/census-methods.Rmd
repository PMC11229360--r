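---
title: "Methods: censusing type III CRISPR-Cas loci and their effectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: censusing type III CRISPR-Cas loci and their effectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Type III CRISPR-Cas systems defend prokaryotes through the Cas10 subunit,
which can carry two enzymatic modules: an N-terminal HD nuclease domain and
a PALM cyclase domain that synthesizes cyclic oligoadenylate (cA3, cA4,
cA6) or SAM-AMP second messengers. These messengers activate ancillary
effector proteins — Csx1, Csm6, Can1-2, Cami1, CalpL, SAVED-CHAT, NucC,
Cam1, Csx23 and CorA — encoded in or near the locus. A census of such loci
asks, per locus: does Cas10 have an intact cyclase and/or HD domain, which
effector families are present, which second messengers do they answer to,
and do effector-lacking loci co-occur with other type III loci in the same
genome (inter-locus signalling)?

`cas10census` implements that census as a deterministic, testable pipeline:
annotated proteins in, per-locus calls and statistics out.

## Pipeline model and assumptions

The unit of input is a genome's protein set plus a locus annotation table
(one row per gene: coordinates, locus membership, operon boundaries, an
annotation label and E-value, and a subtype call). Operon boundaries are
taken verbatim from the table; computing them is the job of the upstream
locus caller, and a thin adapter converts such output into the documented
TSV dialect. Coordinates are 0-based half-open nucleotide intervals
throughout; strand is metadata only, since protein sequences are already
translated.

Stages, in order:

1. **Profiles.** Every protein family is modelled as a position-specific
   scoring matrix (PSSM) in bits, built from an aligned seed with
   `log2((count + pc*bg) / (n + pc) / bg)` per column (pseudocount `pc = 1`,
   uniform background over the 20 standard residues, `X` scores 0, columns
   with more than 50% gaps dropped). Significance comes from an empirical
   Gumbel calibration: the best-window scores of 200 random background
   sequences of length 400 are fitted by the method of moments
   (`lambda = pi/(sd*sqrt(6))`, `mu = mean - gamma/lambda`), and
   `E = db * (1 - exp(-exp(-lambda*(s - mu))))` with `db` the number of
   proteins in the current search set. Ungapped PSSM windows are a
   deliberate simplification of profile HMMs: they keep the E-value
   threshold semantics that all downstream rules rely on, at desk scale and
   with no external binaries, and real profile scanners can be swapped in
   without changing any downstream contract.
2. **Cas10 census.** Proteins of at least 500 residues are scanned against
   the Cas10 library; hits at `E <= 1e-20` are Cas10s. They are
   dereplicated by greedy identity clustering (identity 0.9, word size 5;
   longest-first, first-fit against representatives, ties broken by
   lexicographic id), which removes assembly redundancy; downstream counts
   use representatives' loci only.
3. **Domain calls.** The cyclase call is a conjunction: a hit against
   profiles built from windows spanning 50 residues N-terminal and 100
   C-terminal of the motif at `E <= 1e-3`, *and* a literal occurrence of
   one of the ten motif variants (GGDD, AGDD, GGED, GGDE, SGDD, DGDD,
   AGDE, EGDD, KGDD, GEDD). Either alone is insufficient — the literal
   check removes profile false positives, the profile removes chance
   4-mers. All literal occurrences qualify, and the first in N-to-C order
   is recorded. The HD call requires the dipeptide `HD` to start within
   the first 50 residues (the whole dipeptide inside residues 1-50) and
   residues 10-40 (1-based inclusive, 31 residues) to hit the HD profile
   at the relaxed `E <= 1e-1`; "residues 10-40" is read 1-based because
   that matches the biological phrasing, and both conventions are plain
   config values.
4. **Locus filtering.** Loci with two or more detected Cas10s (ambiguous
   hybrids) are removed; surviving III/non-III hybrids are renamed to
   their type III subtype; loci without a type III component are dropped.
5. **Effector typing.** All proteins intersecting the operon boundaries
   ±4 kb (half-open intersection: a gene touching the window at zero
   overlap is out) are scanned against every family library. Families at
   `E <= 1e-3` are collected per protein; a unique family wins outright,
   multiple families resolve by best bitscore with exact ties going to the
   lexicographically smaller name, and the Cam1/Csx1 cross-hit (shared
   CARF sensory domains) is resolved by transmembrane content: Kyte–
   Doolittle hydropathy averaged over 19-residue windows, counting maximal
   non-overlapping windows with mean ≥ 1.6; at least one TM segment means
   Cam1, none means Csx1. The effector E-value cutoff is not a published
   constant; 1e-3 (the cyclase magnitude) is the package default and is
   configurable. Cross-hits are reported for QC; a Cam1 call without TM
   support is kept but flagged.
6. **Candidate discovery.** In loci with no known effector, genes
   annotated `Unknown` or with annotation E-value worse than 1e-7 are
   flagged, clustered permissively (identity 0.4, word size 2), and each
   representative is screened against all locus proteomes by global
   identity (≥ 0.3, the in-package replacement for an external BLAST
   step). Recurrent co-localized uncharacterized genes in the matched loci
   (labels `Unknown`/`CasR`, recurring in ≥ 2 matched loci — the weakest
   recurrence that is not a singleton) are added as guilt-by-association
   candidates. An explicit exclusion-list file replaces manual curation.
7. **CorA analysis.** CorA-containing loci are screened for the SAM-AMP
   degrading ancillary families (NrN, DEDD, SAM-lyase) by the same
   identity screen; a neighbour-joining tree of CorA proteins is exported
   with a per-leaf metadata table. Fusions (e.g. CorA with a C-terminal
   Csm6-2, or NucC fused to Cas10) are called when two families hit one
   protein with non-overlapping best windows, reported in N-to-C order;
   overlapping windows are ambiguous cross-hits, not fusions.
8. **Statistics.** Per-family locus counts (a locus contributes once per
   distinct family), the symmetric co-occurrence matrix with per-family
   co-occurrence proportions, UpSet-style exact-configuration counts, and
   activator fractions via the family-to-activator map. Inter-locus
   signalling is a binomial GLM: response = locus carries ≥ 1 known
   effector, covariate = genome carries ≥ 2 type III loci, fitted by IRLS
   with a Wald z test; for this binary-binary design the fitted odds
   ratio equals the 2×2 cross-product ratio, which the tests exploit as a
   closed-form oracle. The model treats loci as independent observations
   (the published analysis does the same); the output carries a note
   flagging the within-genome non-independence. Candidate families do not
   count as effector presence by default. Reported percentages round
   half-up to integers.

Trees use `1 - global identity` distances (Needleman-Wunsch, match +1,
mismatch 0, linear gap -1, identity = matches / alignment length, ties in
the DP broken diagonal-first for determinism) with neighbour joining,
negative branch lengths clamped to zero, and midpoint rooting — the
rooting convention is a display choice, made explicit here because no
single convention is canonical.

## The synthetic benchmark

`generate_dataset()` emits genomes with planted ground truth so that every
rule above has a measurable right answer. Its defaults are the study
conditions under which the package's claims are tested:

* 200 genomes, one contig each; 20% of genomes carry 2-3 type III loci.
* Cas10s of 520-600 residues carry the cyclase context (motif slot at
  offset 50) with probability 0.92 and the HD block at residues 10-40
  with probability 0.39 — the fractions reported for real loci; the GGDD
  variant dominates the motif-weight table at 0.82.
* Effector presence per locus follows a logistic model with intercept 2.5
  and a planted log odds-ratio of `-log(2.57)` against the multi-locus
  indicator, mirroring the published inter-locus signalling effect (and
  its direction); present loci draw 1-2 families with weights
  proportional to the published family counts. Effector genes sit inside
  the ±4 kb neighbourhood on both sides of the operon, with 200-2000 nt
  intergenic gaps so the boundary rule is exercised.
* Effector-less loci carry a candidate-family gene (annotated `Unknown`)
  with probability 0.4; the first candidate family co-occurs with a
  recurrent `CasR`-annotated partner gene that only guilt-by-association
  can find. CorA loci carry each ancillary family with probability 0.8.
* Rare constructs (4% single-Cas10 hybrids, 4% non-III loci, 2%
  two-Cas10 hybrids) exercise the locus filters.
* Substitution noise defaults to 0 (the planted-signal acceptance
  condition is noiseless recovery); seed alignments diverge at 5% per
  residue, which is what separates profile scores from background.

Family signatures are synthetic 30-60 residue blocks unique per family
(pairwise identity < 40%), not real family sequences: the benchmark tests
the pipeline's logic, not biology. Real seed alignments are a drop-in
replacement via the same aligned-FASTA interface. What passing tests on
this benchmark shows is that the rules, thresholds and statistics behave
exactly as specified on data satisfying their assumptions; it does not
show that the shipped synthetic seed profiles detect real Cas10s or real
effectors — that depends entirely on the seed alignments supplied.

## Numerical choices and degenerate inputs

* Profile columns with no positively scoring residue are a construction
  error; calibration with zero score variance is an error; sequences
  shorter than a profile scan to `NULL` by contract.
* `E = db * -expm1(-exp(-lambda (s - mu)))` is computed with `expm1` so
  the deep tail (the 1e-20 Cas10 cutoff) does not cancel to zero.
* Greedy clustering is deterministic: input order is fixed by descending
  length then lexicographic id, and the word prefilter (≥ 1 shared
  word) only ever skips pairs that share no k-mer.
* The GLM refuses perfect separation (an empty 2×2 cell), naming the
  degenerate margin, rather than returning a divergent estimate.
* Ambiguous residues other than `X` map to `X` with a warning, keeping
  the 21-letter alphabet closed.
* Problem sizes in the tests — 200 genomes for planted-signal recovery,
  2000 loci × 200 replicates for GLM recovery, 1000 replicates for the
  Wald size check, 40 genomes for the determinism check — were chosen as
  the smallest sets at which the binomial/simulation error bands in the
  assertions are comfortably narrow.

## Known limitations

* Ungapped PSSM windows cannot model indel-rich families the way profile
  HMMs with insert/delete states can; the profile interface isolates this
  choice.
* Global-identity screens penalize length mismatch, so reference sets for
  the candidate and ancillary screens should be full-length homologs.
* The hydropathy TM counter is a coarse stand-in for dedicated TM
  predictors and is only used to break Cam1/Csx1 ties.
* The GLM ignores genome-level clustering of loci; its p-values are
  anti-conservative when genomes contribute many correlated loci.
* Manual curation steps of real-data workflows are replaced by explicit,
  reproducible inputs (exclusion list, annotation table), which shifts
  curation upstream rather than eliminating it.
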