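# cas10census

Census analytics for **type III CRISPR-Cas loci**. Type III systems defend
bacteria and archaea through the Cas10 subunit, whose PALM cyclase domain
(hallmark motif GGDD and nine observed variants) synthesizes cyclic
oligoadenylate (cA3/cA4/cA6) or SAM-AMP second messengers, and whose
N-terminal HD domain is a nuclease. The messengers activate ancillary
effector proteins encoded in or near the locus — Csx1, Csm6, Can1-2, Cami1,
CalpL, SAVED-CHAT, NucC, Cam1, Csx23 and CorA. This package turns per-genome
protein sets and a locus annotation table into a reproducible census of
those loci, for bioinformaticians studying CRISPR-associated signalling:

* **Cas10 identification** — proteins ≥ 500 aa scanned against Cas10
  profiles at E ≤ 1e-20, dereplicated by greedy identity clustering
  (0.9 identity, word size 5),
* **domain calls** — cyclase: profile hit at E ≤ 1e-3 **and** a literal
  motif variant (GGDD, AGDD, GGED, GGDE, SGDD, DGDD, AGDE, EGDD, KGDD,
  GEDD); HD: the dipeptide `HD` within the first 50 residues **and** a
  profile hit on residues 10–40 at E ≤ 1e-1,
* **effector typing** in the operon ± 4 kb neighbourhood, best-bitscore
  resolution, and the Cam1/Csx1 transmembrane rule (TM segment ⇒ Cam1),
* **candidate discovery** — `Unknown`/poor-E-value (> 1e-7) genes in
  effector-less loci, clustered at 0.4/word 2, screened across all loci,
  with guilt-by-association partners,
* **statistics** — per-family counts, co-occurrence/UpSet configurations,
  activator fractions, and a binomial GLM relating effector absence to
  multi-locus genomes (`logit P(effector) = b0 + b1 * multi_locus`; for
  this binary design `exp(b1)` equals the 2×2 cross-product odds ratio).

Profiles are position-specific scoring matrices with empirical Gumbel
E-value calibration — a deliberate, documented stand-in for profile-HMM
scanning that preserves E-value threshold semantics at desk scale (see the
methods vignette, `vignettes/census-methods.Rmd`). A synthetic-genome
generator plants every signal (motifs, effectors, candidates, the
inter-locus association) with truth labels, so the whole pipeline is
testable offline.

## Worked example

```r
library(cas10census)

ds  <- generate_dataset(synth_config(n_genomes = 25, seed = 42))
res <- run_pipeline(dataset = ds, out_dir = NULL)
#> [ingest] 176 records
#> [profiles] 20 records
#> [cas10_census] 32 records
#> [hybrid_filter] 32 records
#> [effector_typing] 35 records
#> [candidate_discovery] 1 records
#> [cora_analysis] 5 records
#> [statistics] 32 records

res$counts
#> # A tibble: 9 × 2
#>   family n_loci
#>   <chr>   <int>
#> 1 Csx1       13
#> 2 Cami1       5
#> 3 CorA        5
#> 4 Can1-2      4
#> 5 Csm6        3
#> 6 Cam1        2
#> 7 CalpL       1
#> 8 Csx23       1
#> 9 NucC        1

res$glm
#> Binomial GLM (logit link), n = 32
#>   coefficient = -0.9361 (SE 0.9961)
#>   odds ratio  = 0.392
#>   Z = -0.940, P = 0.347
```

25 synthetic genomes yield 32 type III loci after hybrid filtering; 35
effector instances are typed (`res$counts` sums family-locus memberships),
and the GLM estimates the planted negative association between effector
presence and multi-locus genomes — at this small n the direction is right
(odds ratio 0.392, i.e. effector-lacking loci are 1/0.392 ≈ 2.6× enriched
in multi-locus genomes) but not significant; the acceptance analysis below
checks the estimator's calibration properly at n = 2000. Passing
`out_dir =` writes every stage table (census TSV/JSON, counts,
co-occurrence edges, UpSet configurations, GLM JSON, Newick trees), an
effective-config YAML, a run log and an md5 MANIFEST; reruns with the same
inputs, config and seed are byte-identical. `autoplot(res$counts)`,
`plot_cooccurrence()` and `plot_upset_configurations()` give quick ggplot
views; `tidy()`/`glance()` tidy the GLM fit. A command-line wrapper lives
at `inst/scripts/run_census_pipeline.R`.

The published census count tables for the ten effector families (1113
loci, 908 effector instances) ship in `inst/extdata/` and rebuild through
`reference_census()` for the count-arithmetic checks.

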